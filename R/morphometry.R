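#' Log-normal summary of synapse sizes
#'
#' Synapse physical volumes are summarised on the log scale: with
#' `W_i = log(V_i)`, `mu = mean(W_i)` and `sigma2 = var(W_i)`, the average
#' synapse size is `V_bar = exp(mu)` (the log-normal median, i.e. the
#' geometric mean) and its standard error is `SE = sqrt(var_linear / N)` with
#' `var_linear = exp(2 mu + sigma2) (exp(sigma2) - 1)`, the linear-scale
#' log-normal variance.
#'
#' Goodness of fit of `W_i` to a normal distribution is assessed two ways:
#' a Kolmogorov-Smirnov test against the fitted `N(mu, sigma2)` (whose null
#' distribution is optimistic because the parameters are estimated from the
#' same data) and the Lilliefors-corrected version of the same statistic.
#' Both p-values are reported; neither is interpreted for the caller.
#'
#' @param volumes positive synapse volumes (nm^3), length >= 2.
#' @return Object of class `size_stats`: `n`, `mu`, `sigma2`, `V_bar`,
#'   `var_linear`, `SE`, `ks_stat`, `ks_p`, `lillie_p`.
#' @examples
#' set.seed(1)
#' lognormal_stats(rlnorm(100, meanlog = 13.5, sdlog = 0.8))
#' @export
lognormal_stats <- function(volumes) {
  v <- as.numeric(volumes)
  if (length(v) < 2) stop_input("need at least two volumes")
  if (any(!is.finite(v)) || any(v <= 0))
    stop_input("volumes must be positive and finite")
  w <- log(v)
  mu <- mean(w)
  sigma2 <- var(w)
  var_linear <- exp(2 * mu + sigma2) * (exp(sigma2) - 1)
  ks_stat <- ks_p <- lillie_p <- NA_real_
  if (sigma2 > 0) {
    ks <- suppressWarnings(ks.test(w, "pnorm", mean = mu, sd = sqrt(sigma2)))
    ks_stat <- unname(ks$statistic)
    ks_p <- ks$p.value
    if (length(w) >= 4) lillie_p <- nortest::lillie.test(w)$p.value
  }
  structure(list(n = length(v), mu = mu, sigma2 = sigma2,
                 V_bar = exp(mu), var_linear = var_linear,
                 SE = sqrt(var_linear / length(v)),
                 ks_stat = ks_stat, ks_p = ks_p, lillie_p = lillie_p),
            class = "size_stats")
}

#' @export
print.size_stats <- function(x, ...) {
  cat(sprintf("Log-normal size statistics (N = %d)\n", x$n))
  cat(sprintf("  mu = %.4f, sigma^2 = %.4f\n", x$mu, x$sigma2))
  cat(sprintf("  V_bar = exp(mu) = %.4g, SE = %.4g\n", x$V_bar, x$SE))
  cat(sprintf("  KS vs fitted normal: D = %.4f, p = %.3g (Lilliefors p = %.3g)\n",
              x$ks_stat, x$ks_p, x$lillie_p))
  invisible(x)
}

#' Probability that a flat synapse can evade the cutting planes
#'
#' Models a synapse as an oriented disk of diameter `feret` and thickness
#' `cleft`. Its extent along the cutting axis is
#' `e = feret * sin(phi) + cleft * cos(phi)`, where `phi` is the angle between
#' the disk normal and the cutting axis; under uniformly random orientations
#' `cos(phi)` is uniform on `[0, 1]`. The function returns the probability
#' that `e < spacing`, i.e. that the object is thin enough to fit entirely
#' between two consecutive cutting planes. This is the *at-risk* (worst-case)
#' probability -- an object with `e < spacing` is actually missed only if it
#' is also positioned inside an inter-plane gap -- matching the spirit of an
#' "at most" miss bound.
#'
#' Closed form: `e < h` is equivalent to the quadratic
#' `(D^2 + c^2) u^2 - 2 h c u + (h^2 - D^2) > 0` in `u = cos(phi)` (on the
#' branch where `h - c u > 0`), with roots
#' `u = (h c +/- D sqrt(D^2 + c^2 - h^2)) / (D^2 + c^2)`.
#'
#' @param feret disk diameter D in nm (> 0); vectors are recycled.
#' @param cleft disk thickness c in nm (> 0).
#' @param spacing cutting-plane spacing h in nm (> 0).
#' @param method `"closed"` (exact) or `"mc"` (Monte-Carlo over orientations,
#'   for cross-checking).
#' @param n_mc Monte-Carlo sample size.
#' @param seed RNG seed for the Monte-Carlo mode.
#' @return Probability in `[0, 1]` (vectorised over the geometry arguments).
#' @examples
#' miss_probability(feret = 200, cleft = 20, spacing = 70)  # 0.0326
#' @export
miss_probability <- function(feret, cleft, spacing,
                             method = c("closed", "mc"),
                             n_mc = 2e5, seed = NULL) {
  method <- match.arg(method)
  check_positive(feret, "feret")
  check_positive(cleft, "cleft")
  check_positive(spacing, "spacing")
  n <- max(length(feret), length(cleft), length(spacing))
  D <- rep_len(feret, n); cc <- rep_len(cleft, n); h <- rep_len(spacing, n)
  if (method == "mc") {
    return(with_seed(seed, {
      vapply(seq_len(n), function(i) {
        u <- runif(n_mc)
        mean(D[i] * sqrt(1 - u^2) + cc[i] * u < h[i])
      }, numeric(1))
    }))
  }
  p <- numeric(n)
  for (i in seq_len(n)) p[i] <- miss_closed(D[i], cc[i], h[i])
  p
}

miss_closed <- function(D, cc, h) {
  if (min(D, cc) >= h) return(0)          # extent >= min(D, c) everywhere
  if (sqrt(D^2 + cc^2) <= h) return(1)    # extent <= sqrt(D^2 + c^2) everywhere
  A <- D^2 + cc^2
  s <- D * sqrt(A - h^2)
  u_lo <- (h * cc - s) / A
  u_hi <- (h * cc + s) / A
  p <- 0
  # branch near u = 0 (flat-on-edge): extent ~ D < h
  if (D < h) p <- p + min(max(u_lo, 0), 1)
  # branch near u = 1 (flat-lying): extent ~ c < h
  if (cc < h) p <- p + max(0, 1 - min(u_hi, 1))
  min(max(p, 0), 1)
}

#' Population-level miss probability
#'
#' Averages [miss_probability()] over a sample (or model) of the joint
#' Feret/cleft distribution, giving the expected fraction of a synapse
#' population at risk of slipping between consecutive cutting planes.
#'
#' @param feret,cleft vectors of per-object geometry (nm), recycled to a
#'   common length.
#' @param spacing cutting-plane spacing (nm).
#' @return Scalar probability.
#' @export
miss_probability_population <- function(feret, cleft, spacing) {
  mean(miss_probability(feret, cleft, spacing))
}

#' Cleft-thickness threshold for missable synapses
#'
#' A flat synapse lying parallel to the imaging plane has z-extent equal to
#' its cleft thickness; it can evade a plane grid of spacing `h` only if its
#' cleft is thinner than about `h / 3` once typical tilt is accounted for.
#' Returns `h / 3` (23.3 nm at the standard 70-nm spacing).
#'
#' @param spacing cutting-plane spacing in nm (> 0).
#' @return Threshold in nm.
#' @examples
#' classify_threshold(70)  # 23.33
#' @export
classify_threshold <- function(spacing) {
  check_positive(spacing, "spacing")
  spacing / 3
}
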