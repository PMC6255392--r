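# Independent oracles and fixture builders used across the test suite.

# ---- fixture builders -------------------------------------------------------

# Object table in the ground-truth layout, with explicit geometry.
mk_synapses <- function(x, y, z, feret, cleft, nx = 0, ny = 0, nz = 1,
                        type = "asym") {
  n <- max(length(x), length(y), length(z), length(feret), length(cleft))
  nrm <- cbind(rep_len(nx, n), rep_len(ny, n), rep_len(nz, n))
  nrm <- nrm / sqrt(rowSums(nrm^2))
  data.frame(id = seq_len(n), type = rep_len(type, n),
             x_um = rep_len(x, n), y_um = rep_len(y, n), z_um = rep_len(z, n),
             volume_nm3 = pi / 4 * rep_len(feret, n)^2 * rep_len(cleft, n),
             feret_nm = rep_len(feret, n), cleft_nm = rep_len(cleft, n),
             nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3])
}

# ---- minimum enclosing sphere oracles ---------------------------------------

# Exhaustive brute force: the minimum enclosing sphere is determined by a
# support set of <= 4 points; enumerate all candidate spheres and keep the
# smallest one containing every point.
brute_min_sphere <- function(p) {
  p <- unique(as.matrix(p))
  n <- nrow(p)
  contains_all <- function(ctr, r) all(sqrt(colSums((t(p) - ctr)^2)) <= r + 1e-9)
  best_r <- Inf; best_c <- p[1, ]
  consider <- function(ctr, r) {
    if (!is.null(ctr) && r < best_r && contains_all(ctr, r)) {
      best_r <<- r; best_c <<- ctr
    }
  }
  if (n == 1) return(list(center = p[1, ], radius = 0))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    ctr <- (p[i, ] + p[j, ]) / 2
    consider(ctr, sqrt(sum((p[i, ] - ctr)^2)))
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in seq.int(i + 1, n - 1)) for (k in seq.int(j + 1, n)) {
      cc <- circumcenter3(p[i, ], p[j, ], p[k, ])
      if (!is.null(cc)) consider(cc, sqrt(sum((p[i, ] - cc)^2)))
    }
  }
  if (n >= 4) {
    idx <- utils::combn(n, 4)
    for (col in seq_len(ncol(idx))) {
      s <- p[idx[, col], ]
      cc <- circumcenter4(s)
      if (!is.null(cc)) consider(cc, sqrt(sum((s[1, ] - cc)^2)))
    }
  }
  list(center = best_c, radius = best_r)
}

# circumcenter of a triangle in 3D via the cross-product formula
circumcenter3 <- function(p1, p2, p3) {
  a <- p2 - p1; b <- p3 - p1
  axb <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
  den <- 2 * sum(axb^2)
  if (den < 1e-300) return(NULL)
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  p1 + (sum(b^2) * cross(axb, a) + sum(a^2) * cross(b, axb)) / den
}

circumcenter4 <- function(s) {
  m <- rbind(s[2, ] - s[1, ], s[3, ] - s[1, ], s[4, ] - s[1, ])
  if (abs(det(m)) < 1e-12) return(NULL)
  # solve (p_i - p_1) . c = (|p_i|^2 - |p_1|^2) / 2
  rhs <- (rowSums(s[-1, , drop = FALSE]^2) - sum(s[1, ]^2)) / 2
  drop(solve(m, rhs))
}

# KKT optimality certificate for a minimum enclosing ball: every point is
# inside, and the centre lies in the convex hull of the boundary (support)
# points. Necessary and sufficient for the (unique) minimum enclosing ball.
certify_min_sphere <- function(p, center, radius, tol = 1e-7) {
  p <- unique(as.matrix(p))
  d <- sqrt(colSums((t(p) - center)^2))
  if (any(d > radius * (1 + tol) + tol)) return(FALSE)
  if (radius <= tol) return(TRUE)
  s <- p[d >= radius * (1 - tol) - tol, , drop = FALSE]
  if (nrow(s) == 0) return(FALSE)
  in_hull(center, s, tol = 1e-7 * max(radius, 1))
}

# is q in conv(rows of s)?  least-squares over the simplex via exhaustive
# barycentric solves on affinely independent subsets (|s| small)
in_hull <- function(q, s, tol = 1e-7) {
  k <- nrow(s)
  for (m in seq_len(min(k, 4))) {
    subs <- utils::combn(k, m)
    for (col in seq_len(ncol(subs))) {
      v <- s[subs[, col], , drop = FALSE]
      a <- rbind(t(v), rep(1, m))            # 4 x m
      lam <- tryCatch(qr.solve(a, c(q, 1), tol = 1e-12), error = function(e) NULL)
      if (is.null(lam)) next
      if (all(lam >= -tol) &&
          sqrt(sum((drop(t(v) %*% lam) - q)^2)) <= tol) return(TRUE)
    }
  }
  FALSE
}

# ---- disector counting oracle -----------------------------------------------

# Direct per-object membership test, written top-down from the definition:
# an object is dissected when its top surface lies inside the disector slab
# [ref*t, lookup*t), it is visible in the reference slab (bottom below the
# end of the reference section), and its circular profile is admitted by the
# counting frame (overlaps the frame, touches neither the left nor the
# bottom edge segment).
oracle_count_disector <- function(syn, pair, thickness_nm) {
  t_um <- thickness_nm / 1000
  u <- abs(syn$nz)
  ext_um <- (syn$feret_nm * sqrt(pmax(0, 1 - u^2)) + syn$cleft_nm * u) / 1000
  z_top <- syn$z_um + ext_um / 2
  z_bot <- syn$z_um - ext_um / 2
  top_in_slab <- z_top >= pair$ref_section * t_um &
                 z_top < pair$lookup_section * t_um
  seen_in_ref <- z_bot < (pair$ref_section + 1) * t_um
  r <- syn$feret_nm / 2000
  x0 <- pair$frame_x; y0 <- pair$frame_y; w <- pair$frame_size
  qx <- pmin(pmax(syn$x_um, x0), x0 + w)
  qy <- pmin(pmax(syn$y_um, y0), y0 + w)
  overlaps <- (syn$x_um - qx)^2 + (syn$y_um - qy)^2 <= r^2
  seg_dist <- function(px, py, ax, ay, bx, by) {
    tt <- pmin(pmax(((px - ax) * (bx - ax) + (py - ay) * (by - ay)) /
                     ((bx - ax)^2 + (by - ay)^2), 0), 1)
    sqrt((px - (ax + tt * (bx - ax)))^2 + (py - (ay + tt * (by - ay)))^2)
  }
  hits_left <- seg_dist(syn$x_um, syn$y_um, x0, y0, x0, y0 + w) <= r
  hits_bottom <- seg_dist(syn$x_um, syn$y_um, x0, y0, x0 + w, y0) <= r
  counted <- top_in_slab & seen_in_ref & overlaps & !hits_left & !hits_bottom
  list(q_total = sum(counted),
       q_asym = sum(counted & syn$type == "asym"),
       q_sym = sum(counted & syn$type == "sym"),
       ids = syn$id[counted])
}

# ---- random-intercept ML oracle ---------------------------------------------

# Profile likelihood for y = X beta + b_m + eps, b_m ~ N(0, lam * sigma2),
# eps ~ N(0, sigma2). For fixed lam, beta is GLS and sigma2 has a closed
# form; lam is optimised on a 1-D grid + golden search. Independent of lme4.
oracle_lme_ml <- function(y, X, bird) {
  bird <- as.factor(bird)
  n <- length(y)
  blocks <- split(seq_len(n), bird)
  fit_given <- function(lam) {
    # V = I + lam * J within blocks; V^-1 = I - lam/(1+lam*nj) * J
    wX <- X; wy <- y
    logdet <- 0
    XtViX <- matrix(0, ncol(X), ncol(X)); XtViy <- numeric(ncol(X))
    yViy <- 0
    for (ii in blocks) {
      nj <- length(ii)
      a <- lam / (1 + lam * nj)
      Xj <- X[ii, , drop = FALSE]; yj <- y[ii]
      ViX <- Xj - a * matrix(colSums(Xj), nj, ncol(X), byrow = TRUE)
      Viy <- yj - a * sum(yj)
      XtViX <- XtViX + t(Xj) %*% ViX
      XtViy <- XtViy + t(Xj) %*% Viy
      yViy <- yViy + sum(yj * Viy)
      logdet <- logdet + log(1 + lam * nj)
    }
    beta <- solve(XtViX, XtViy)
    q <- yViy - 2 * sum(beta * XtViy) + sum(beta * (XtViX %*% beta))
    sigma2 <- q / n
    dev <- n * log(2 * pi * sigma2) + logdet + n
    list(beta = drop(beta), sigma2 = sigma2, lam = lam, dev = dev)
  }
  obj <- function(loglam) fit_given(exp(loglam))$dev
  # coarse grid then fine 1-D optimisation (lam = 0 boundary included)
  grid <- seq(-12, 8, by = 0.25)
  dev0 <- fit_given(0)$dev
  devs <- vapply(grid, obj, numeric(1))
  if (min(devs) >= dev0 - 1e-10) return(c(fit_given(0), list(dev0 = dev0)))
  i <- which.min(devs)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(obj, c(lo, hi), tol = 1e-12)
  fit_given(exp(opt$minimum))
}

# ---- misc -------------------------------------------------------------------

# z-extent of an explicit 3D point-cloud disk (rim + faces), used as a
# geometry oracle for the analytic extent formula
disk_cloud_extent <- function(feret, cleft, normal, n_rim = 720) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * normal) * normal; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  th <- seq(0, 2 * pi, length.out = n_rim)
  rim <- (feret / 2) * (outer(cos(th), e1) + outer(sin(th), e2))
  pts <- rbind(sweep(rim, 2, (cleft / 2) * normal, `+`),
               sweep(rim, 2, (cleft / 2) * normal, `-`))
  max(pts[, 3]) - min(pts[, 3])
}
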