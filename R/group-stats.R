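#' Jackknife estimate of the percentage of symmetric synapses
#'
#' The plug-in percentage over n disectors is
#' `q = 100 * sum(N_s) / sum(N)`, with `N_i` the dissected synapses and
#' `N_i^s` the dissected symmetric synapses in disector i. The leave-one-out
#' estimates are `q_i = 100 * sum(N_s[-i]) / sum(N[-i])`, their mean is
#' `q_bar`, and the jackknife variance is
#' `sigma_q^2 = (n - 1) / n * sum((q_i - q_bar)^2)`.
#'
#' `q` and `q_bar` are reported separately: for a ratio estimator the
#' leave-one-out mean does not equal the plug-in ratio exactly (they coincide
#' only for homogeneous disectors), so forcing them equal would hide a real,
#' if small, discrepancy.
#'
#' @param n_sym per-disector dissected symmetric counts `N_i^s`.
#' @param n_total per-disector total dissected counts `N_i`.
#' @return Object of class `jackknife_percent`: `q`, `q_i`, `q_bar`,
#'   `sigma_q2`, `sd_q`, `n_disectors`.
#' @examples
#' percent_symmetric_jackknife(n_sym = c(2, 2), n_total = c(10, 6))
#' @export
percent_symmetric_jackknife <- function(n_sym, n_total) {
  if (length(n_sym) != length(n_total))
    stop_input("`n_sym` and `n_total` must have equal length")
  n <- length(n_total)
  if (n < 2) stop_input("need at least two disectors")
  if (any(n_sym < 0) || any(n_total < 0) || any(n_sym > n_total))
    stop_input("counts must satisfy 0 <= n_sym <= n_total")
  tot_s <- sum(n_sym); tot <- sum(n_total)
  if (tot == 0) stop_input("all disectors are empty")
  loo_tot <- tot - n_total
  if (any(loo_tot == 0))
    stop_input("every leave-one-out subset must contain dissected synapses")
  q <- 100 * tot_s / tot
  q_i <- 100 * (tot_s - n_sym) / loo_tot
  q_bar <- mean(q_i)
  sigma_q2 <- (n - 1) / n * sum((q_i - q_bar)^2)
  structure(list(q = q, q_i = q_i, q_bar = q_bar, sigma_q2 = sigma_q2,
                 sd_q = sqrt(sigma_q2), n_disectors = n),
            class = "jackknife_percent")
}

#' @export
print.jackknife_percent <- function(x, ...) {
  cat(sprintf("Percent symmetric: q = %.2f%% (jackknife mean %.2f%%, sd %.2f, n = %d disectors)\n",
              x$q, x$q_bar, x$sd_q, x$n_disectors))
  invisible(x)
}

#' Bootstrap comparison of two groups of animals
#'
#' Simulates `n_sim` experiments in which each animal's summary value (e.g.
#' percent symmetric synapses) is drawn from a Gaussian with that animal's
#' observed mean and standard deviation, and reports the fraction of
#' simulated experiments in which the group-B mean falls below the group-A
#' mean (and its complement). For continuous draws the two one-sided
#' fractions computed from the same draws sum exactly to 1, so swapping the
#' groups maps p to 1 - p.
#'
#' @param mean_a,sd_a per-animal means and standard deviations of group A.
#' @param mean_b,sd_b per-animal means and standard deviations of group B.
#' @param n_sim number of simulated experiments (>= 1).
#' @param seed RNG seed (draws are deterministic under it).
#' @return List: `p_b_below_a`, `p_a_below_b`, `n_sim`, `mean_diff` (mean of
#'   simulated B - A differences).
#' @export
bootstrap_group_comparison <- function(mean_a, sd_a, mean_b, sd_b,
                                       n_sim = 1e6, seed = NULL) {
  if (n_sim < 1) stop_input("`n_sim` must be at least 1")
  if (length(mean_a) < 1 || length(mean_b) < 1)
    stop_input("each group needs at least one animal")
  check_positive(c(sd_a, sd_b), "group sds", strict = FALSE)
  if (length(sd_a) != length(mean_a) || length(sd_b) != length(mean_b))
    stop_input("means and sds must have matching lengths")
  with_seed(seed, {
    sim_group <- function(m, s) {
      draws <- matrix(rnorm(n_sim * length(m)), nrow = n_sim)
      draws <- sweep(draws, 2, s, `*`)
      draws <- sweep(draws, 2, m, `+`)
      rowMeans(draws)
    }
    ma <- sim_group(mean_a, sd_a)
    mb <- sim_group(mean_b, sd_b)
    diff <- mb - ma
    list(p_b_below_a = mean(diff < 0),
         p_a_below_b = mean(diff > 0) + 0.5 * mean(diff == 0),
         n_sim = n_sim, mean_diff = mean(diff))
  })
}

#' Random-intercept mixed-model group comparison
#'
#' Fits, by maximum likelihood, the model
#' `y_im = beta_baseline + beta_group + b_m + eps_im`, with a fixed effect per
#' non-baseline group, a Gaussian random intercept `b_m` per animal, and iid
#' Gaussian residuals. Fixed effects are reported relative to the baseline
#' group with their standard errors and Wald p-values for `beta != 0`.
#' Estimation is delegated to [lme4::lmer()]; degenerate fits (zero residual
#' variation) and `include_random = FALSE` fall back to ordinary least
#' squares, which is the limit of the model at zero random-effect variance.
#'
#' @param data data frame of observations.
#' @param response,group,bird column names of the response, the treatment
#'   group and the animal identity.
#' @param baseline baseline group level (default: first level).
#' @param include_random fit the random intercept (`TRUE`) or plain OLS.
#' @return Object of class `lme_group_fit`: `beta`, `se`, `p`, `df`,
#'   `var_bird`, `var_resid`, `ranef`, `n_obs`, `method`.
#' @export
lme_fit <- function(data, response, group, bird, baseline = NULL,
                    include_random = TRUE) {
  data <- as.data.frame(data)
  for (nm in c(response, group, bird))
    if (!nm %in% names(data)) stop_input(sprintf("column `%s` not found", nm))
  g <- factor(data[[group]])
  if (!is.null(baseline)) {
    if (!baseline %in% levels(g)) stop_input("baseline level not present")
    g <- stats::relevel(g, ref = baseline)
  }
  df_fit <- data.frame(y = data[[response]], g = g, m = factor(data[[bird]]))
  if (any(!is.finite(df_fit$y))) stop_input("non-finite response values")
  if (nlevels(df_fit$g) > 1 && any(table(unique(df_fit[c("g", "m")])$g) < 1))
    stop_input("singular design: empty group")
  one_group <- nlevels(droplevels(df_fit$g)) < 2
  fit_ols <- function() {
    fm <- if (one_group) lm(y ~ 1, data = df_fit) else lm(y ~ g, data = df_fit)
    # a zero-residual fit is legitimate here (degenerate data); silence the
    # "essentially perfect fit" advisory from summary.lm
    se <- suppressWarnings(sqrt(diag(vcov(fm))))
    list(beta = coef(fm), se = se,
         var_bird = 0, var_resid = sum(fm$residuals^2) / nrow(df_fit),
         ranef = setNames(rep(0, nlevels(df_fit$m)), levels(df_fit$m)),
         method = "OLS")
  }
  degenerate <- var(df_fit$y) == 0
  res <- if (!include_random || degenerate || nlevels(df_fit$m) < 2) fit_ols() else {
    tryCatch({
      fml <- if (one_group) y ~ (1 | m) else y ~ g + (1 | m)
      fm <- suppressWarnings(suppressMessages(
        lme4::lmer(fml, data = df_fit, REML = FALSE)))
      vc <- lme4::VarCorr(fm)
      list(beta = lme4::fixef(fm), se = sqrt(diag(as.matrix(vcov(fm)))),
           var_bird = as.numeric(vc$m[1]),
           var_resid = attr(vc, "sc")^2,
           ranef = setNames(lme4::ranef(fm)$m[, 1], rownames(lme4::ranef(fm)$m)),
           method = "ML (lmer)")
    }, error = function(e) fit_ols())
  }
  names(res$beta) <- sub("^g", "", names(res$beta))
  names(res$beta)[1] <- levels(df_fit$g)[1]
  names(res$se) <- names(res$beta)
  z <- res$beta / res$se
  p <- 2 * pnorm(-abs(z))
  structure(list(beta = res$beta, se = res$se, p = p,
                 df = nrow(df_fit) - length(res$beta),
                 var_bird = res$var_bird, var_resid = res$var_resid,
                 ranef = res$ranef, n_obs = nrow(df_fit),
                 baseline = levels(df_fit$g)[1], method = res$method),
            class = "lme_group_fit")
}

#' @export
print.lme_group_fit <- function(x, ...) {
  cat(sprintf("Random-intercept group model (%s), %d observations, df = %d\n",
              x$method, x$n_obs, x$df))
  cat(sprintf("  baseline: %s\n", x$baseline))
  for (i in seq_along(x$beta)) {
    cat(sprintf("  beta[%s] = %.4g (SE %.3g, p = %.3g)\n",
                names(x$beta)[i], x$beta[i], x$se[i], x$p[i]))
  }
  cat(sprintf("  var(bird) = %.4g, var(resid) = %.4g\n", x$var_bird, x$var_resid))
  invisible(x)
}

#' Mixed-model comparison of percent symmetric synapses
#'
#' Partitions each animal's disectors into `n_partitions` interleaved groups,
#' computes the plug-in percent-symmetric estimate within each partition, and
#' fits the random-intercept group model to the per-partition estimates
#' (`n_partitions` observations per animal).
#'
#' @param table data frame with columns `bird_id`, `group`, `n_sym`,
#'   `n_total` (one row per disector).
#' @param n_partitions partitions per animal (default 4).
#' @param baseline baseline group level.
#' @return An [lme_fit()] result; the per-partition table is attached as
#'   attribute `"partitions"`.
#' @export
lme_percent_symmetric <- function(table, n_partitions = 4, baseline = NULL) {
  table <- as.data.frame(table)
  need <- c("bird_id", "group", "n_sym", "n_total")
  if (!all(need %in% names(table)))
    stop_input("`table` needs columns bird_id, group, n_sym, n_total")
  parts <- do.call(rbind, lapply(split(table, table$bird_id), function(tb) {
    k <- (seq_len(nrow(tb)) - 1L) %% n_partitions
    do.call(rbind, lapply(split(tb, k), function(sub) {
      data.frame(bird_id = sub$bird_id[1], group = sub$group[1],
                 q = 100 * sum(sub$n_sym) / max(sum(sub$n_total), 1),
                 n_total = sum(sub$n_total))
    }))
  }))
  rownames(parts) <- NULL
  fit <- lme_fit(parts, response = "q", group = "group", bird = "bird_id",
                 baseline = baseline)
  attr(fit, "partitions") <- parts
  fit
}

#' Regional volume from serial section outlines
#'
#' Per-section volume is `V_sec = n * p * d` (pixel count x pixel area x
#' section thickness); the regional volume is the sum over sections. The
#' per-animal value is the average of the left and right hemisphere volumes
#' (see `bilateral`).
#'
#' @param pixel_counts per-section pixel counts inside the region outline.
#' @param pixel_area pixel area `p` in um^2.
#' @param thickness section thickness `d` in um.
#' @return List with `V_sec_um3` (per section), `V_total_um3` and
#'   `V_total_mm3`.
#' @examples
#' hvc_volume(5e5, pixel_area = 1, thickness = 100)$V_total_mm3  # 0.05
#' @export
hvc_volume <- function(pixel_counts, pixel_area, thickness) {
  if (length(pixel_counts) < 1) stop_input("no sections supplied")
  check_positive(pixel_area, "pixel_area")
  check_positive(thickness, "thickness")
  if (any(pixel_counts < 0)) stop_input("pixel counts must be non-negative")
  v_sec <- pixel_counts * pixel_area * thickness
  list(V_sec_um3 = v_sec, V_total_um3 = sum(v_sec),
       V_total_mm3 = sum(v_sec) / 1e9)
}

#' @rdname hvc_volume
#' @param left,right hemisphere volumes (any common unit).
#' @export
hvc_bilateral <- function(left, right) {
  (left + right) / 2
}

#' Relative change between two percentages
#'
#' `100 * (comparison - reference) / reference`; e.g. a rise from 19% to 27%
#' is a 42% relative increase.
#'
#' @param reference reference value (non-zero).
#' @param comparison comparison value.
#' @return Relative change in percent.
#' @examples
#' percent_change(19, 27)  # 42.1
#' @export
percent_change <- function(reference, comparison) {
  if (any(reference == 0)) stop_input("`reference` must be non-zero")
  100 * (comparison - reference) / reference
}
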