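#' Feret diameter as the minimum-bounding-sphere diameter
#'
#' Computes the diameter of the exact minimum enclosing sphere of a 3D point
#' set with Welzl's expected-linear-time randomized algorithm (move-to-front
#' formulation with support sets of at most four points). Note this follows
#' the convention used in the synapse-size literature this package targets:
#' the "Feret diameter" is the minimum-bounding-sphere diameter, *not* the
#' conventional maximum caliper width.
#'
#' The result is translation/rotation invariant and monotone under point
#' addition; every input point lies inside or on the returned sphere.
#'
#' @param points numeric matrix (n x 3) or data frame of point coordinates;
#'   a two-column input is treated as planar (z = 0).
#' @param detail return the centre and radius as well.
#' @return The diameter (same units as the coordinates); with
#'   `detail = TRUE`, a list with `diameter`, `radius`, `center`, `support`.
#' @examples
#' feret_diameter(rbind(c(0, 0, 0), c(1, 0, 0)))  # 1
#' @export
feret_diameter <- function(points, detail = FALSE) {
  p <- as.matrix(points)
  if (length(p) == 0 || nrow(p) == 0) stop_input("empty point set")
  if (ncol(p) == 2) p <- cbind(p, 0)
  if (ncol(p) != 3) stop_input("`points` must have 2 or 3 columns")
  storage.mode(p) <- "double"
  p <- unique(p)
  # deterministic shuffle (Welzl's expected-linear bound needs random order)
  ord <- with_seed(20071121L, sample.int(nrow(p)))
  p <- p[ord, , drop = FALSE]
  ball <- welzl_mtf(p)
  if (!detail) return(2 * ball$r)
  list(diameter = 2 * ball$r, radius = ball$r, center = ball$c,
       support = ball$support)
}

# Move-to-front Welzl in three dimensions: four nested passes, each pinning
# one more support point, so recursion depth is bounded by the dimension.
welzl_mtf <- function(p) {
  n <- nrow(p)
  ball <- list(c = p[1, ], r = 0, support = p[1, , drop = FALSE])
  for (i in seq_len(n)) {
    if (!in_ball(ball, p[i, ])) {
      ball <- mb_with(p[seq_len(i - 1L), , drop = FALSE], p[i, , drop = FALSE])
    }
  }
  ball
}

mb_with <- function(p, fixed) {
  ball <- ball_of(fixed)
  if (nrow(fixed) == 4L || nrow(p) == 0L) return(ball)
  for (i in seq_len(nrow(p))) {
    if (!in_ball(ball, p[i, ])) {
      ball <- mb_with(p[seq_len(i - 1L), , drop = FALSE],
                      rbind(fixed, p[i, ]))
    }
  }
  ball
}

in_ball <- function(ball, q) {
  sum((q - ball$c)^2) <= ball$r^2 * (1 + 1e-12) + 1e-300
}

# Smallest sphere having all of `s` (1..4 points) on its boundary; degenerate
# (affinely dependent) supports fall back to the minimal ball of a subset.
ball_of <- function(s) {
  k <- nrow(s)
  if (k == 1L) return(list(c = s[1, ], r = 0, support = s))
  if (k == 2L) {
    ctr <- (s[1, ] + s[2, ]) / 2
    return(list(c = ctr, r = sqrt(sum((s[1, ] - ctr)^2)), support = s))
  }
  a <- sweep(s[-1, , drop = FALSE], 2, s[1, ])     # (k-1) x 3
  rhs <- rowSums(a^2) / 2
  g <- a %*% t(a)
  qrg <- qr(g)
  if (qrg$rank < nrow(a)) {
    # affinely dependent support: best ball determined by a proper subset
    best <- NULL
    for (drop in seq_len(k)) {
      cand <- ball_of(s[-drop, , drop = FALSE])
      if (all(apply(s, 1, function(q) in_ball(cand, q))) &&
          (is.null(best) || cand$r < best$r)) best <- cand
    }
    return(best %||% ball_of(s[-k, , drop = FALSE]))
  }
  lam <- solve(qrg, rhs)
  ctr <- s[1, ] + drop(t(a) %*% lam)
  list(c = ctr, r = sqrt(sum((s[1, ] - ctr)^2)), support = s)
}
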