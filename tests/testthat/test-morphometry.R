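test_that("log-normal stats reproduce the closed-form identities", {
  # all volumes equal
  st <- lognormal_stats(rep(5000, 10))
  expect_equal(st$mu, log(5000))
  expect_equal(st$sigma2, 0)
  expect_equal(st$V_bar, 5000)
  expect_equal(st$SE, 0)
  # mu = 0, sigma2 = 1, N = 100: var = e (e - 1), SE = sqrt(var / 100)
  w <- rnorm(100)
  w <- (w - mean(w)) / sd(w)               # exact sample mu = 0, sigma2 = 1
  st2 <- lognormal_stats(exp(w))
  expect_equal(st2$mu, 0, tolerance = 1e-12)
  expect_equal(st2$sigma2, 1, tolerance = 1e-12)
  expect_equal(st2$var_linear, exp(1) * (exp(1) - 1), tolerance = 1e-10)
  expect_equal(st2$var_linear, 4.6708, tolerance = 1e-4)
  expect_equal(st2$SE, sqrt(exp(1) * (exp(1) - 1) / 100), tolerance = 1e-10)
  expect_equal(st2$SE, 0.2161, tolerance = 1e-3)
  expect_error(lognormal_stats(c(1, -1, 2)), "positive")
  expect_error(lognormal_stats(100), "at least two")
})

test_that("V_bar estimates the log-normal median, and SE matches a bootstrap", {
  set.seed(10)
  mu <- 13; sig <- 0.9
  v <- rlnorm(300, mu, sig)
  st <- lognormal_stats(v)
  # consistency: V_bar tracks exp(mu) (the median), not the linear mean
  expect_lt(abs(st$mu - mu), 3 * sig / sqrt(300))
  expect_lt(st$V_bar, mean(v))             # exp(mu) < exp(mu + sig^2/2)
  # in the moderate-sigma regime the linear-variance SE formula approximates
  # the sampling error of exp(mu_hat); bootstrap oracle at N = 300
  set.seed(11)
  v2 <- rlnorm(300, 13, 0.25)
  st2 <- lognormal_stats(v2)
  boot <- replicate(800, exp(mean(log(sample(v2, replace = TRUE)))))
  expect_lt(abs(st2$SE - sd(boot)) / sd(boot), 0.15)
})

test_that("mu and sigma2 estimates are consistent as N grows", {
  set.seed(12)
  errs <- vapply(c(100, 1000, 10000), function(n) {
    v <- rlnorm(n, 13, 0.8)
    st <- lognormal_stats(v)
    abs(st$mu - 13) + abs(st$sigma2 - 0.64)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.05)
})

test_that("goodness-of-fit p-values behave sensibly", {
  set.seed(2)
  good <- rlnorm(200, 13, 0.8)
  bad <- exp(runif(200, 12, 14))           # log-uniform, clearly not normal
  expect_gt(lognormal_stats(good)$lillie_p, 0.01)
  expect_lt(lognormal_stats(bad)$lillie_p, 0.01)
  expect_true(is.finite(lognormal_stats(good)$ks_stat))
})

test_that("feret_diameter handles degenerate and simple sets", {
  expect_equal(feret_diameter(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(feret_diameter(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  # equilateral triangle: circumdiameter = side / sqrt(3) * 2
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(feret_diameter(tri), 2 / sqrt(3), tolerance = 1e-9)
  # regular tetrahedron of edge 1: circumradius sqrt(3/8)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(8)
  expect_equal(feret_diameter(tet), 2 * sqrt(3 / 8), tolerance = 1e-9)
  expect_error(feret_diameter(matrix(numeric(0), 0, 3)), "empty")
})

test_that("feret_diameter equals brute-force enumeration on small sets", {
  set.seed(30)
  for (i in 1:60) {
    n <- sample(2:10, 1)
    p <- matrix(rnorm(3 * n), ncol = 3)
    if (i %% 3 == 0) p[, 3] <- 0                    # coplanar cases
    if (i %% 5 == 0) p <- round(p * 2) / 2          # gridded, degenerate cases
    want <- brute_min_sphere(p)
    expect_equal(feret_diameter(p), 2 * want$radius, tolerance = 1e-9)
  }
})

test_that("feret_diameter satisfies the minimum-ball optimality certificate", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(2:50, 1)
    p <- matrix(rnorm(3 * n, sd = sample(c(0.5, 2, 50), 1)), ncol = 3)
    got <- feret_diameter(p, detail = TRUE)
    expect_true(certify_min_sphere(p, got$center, got$radius))
  }
})

test_that("feret_diameter is invariant and monotone", {
  set.seed(32)
  p <- matrix(rnorm(60), ncol = 3)
  d0 <- feret_diameter(p)
  # translation
  expect_equal(feret_diameter(sweep(p, 2, c(5, -3, 11), `+`)), d0,
               tolerance = 1e-9)
  # rotation
  th <- 0.73
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(feret_diameter(p %*% rot), d0, tolerance = 1e-9)
  # monotone under point addition
  expect_gte(feret_diameter(rbind(p, c(0.1, 0.1, 0.1))) + 1e-12, d0)
  expect_gte(feret_diameter(rbind(p, c(50, 0, 0))), d0)
})

test_that("miss probability matches its closed form and Monte-Carlo", {
  # thick or wide objects can never fit between planes
  expect_equal(miss_probability(200, 80, 70), 0)
  expect_equal(miss_probability(60, 200, 50), 0)
  # tiny objects always fit
  expect_equal(miss_probability(30, 10, 70), 1)
  # the printed geometry: D = 200, c = 20, h = 70
  p <- miss_probability(200, 20, 70)
  expect_equal(p, 0.0326, tolerance = 1e-2)
  # against the quadratic root quoted for this geometry
  u <- max(Re(polyroot(c(-35100, -2800, 40400))))
  expect_equal(p, 1 - u, tolerance = 1e-9)
  # Monte-Carlo cross-check over orientations
  pm <- miss_probability(200, 20, 70, method = "mc", n_mc = 4e5, seed = 1)
  expect_lt(abs(pm - p), 3 * sqrt(p * (1 - p) / 4e5))
  # and a case with both branches active (D < h and c < h)
  p2 <- miss_probability(60, 30, 70)
  p2m <- miss_probability(60, 30, 70, method = "mc", n_mc = 4e5, seed = 2)
  expect_lt(abs(p2m - p2), 3 * sqrt(p2 * (1 - p2) / 4e5) + 1e-4)
})

test_that("miss probability is monotone in geometry", {
  d_grid <- seq(90, 400, by = 10)
  p_d <- miss_probability(d_grid, 20, 70)
  expect_true(all(diff(p_d) <= 1e-12))        # decreasing in D
  c_grid <- seq(5, 65, by = 5)
  p_c <- miss_probability(200, c_grid, 70)
  expect_true(all(diff(p_c) <= 1e-12))        # decreasing in c (c < h)
  h_grid <- seq(30, 150, by = 10)
  p_h <- miss_probability(200, 20, h_grid)
  expect_true(all(diff(p_h) >= -1e-12))       # increasing in spacing
})

test_that("miss probability agrees with sectioning of synthetic objects", {
  # objects with fixed geometry, random orientations and positions
  set.seed(44)
  n <- 40000
  nrm <- matrix(rnorm(3 * n), ncol = 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  syn <- mk_synapses(x = runif(n, 0, 50), y = runif(n, 0, 50),
                     z = runif(n, 1, 3), feret = 200, cleft = 20,
                     nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3])
  syn$id <- seq_len(n)
  stk <- section_tissue(syn, 70, convention = "plane", n_sections = 60)
  p_at_risk <- miss_probability(200, 20, 70)
  # fraction whose z-extent fits inside one inter-plane gap = at-risk bound
  frac_fit <- mean(stk$objects$z_extent_nm < 70)
  expect_lt(abs(frac_fit - p_at_risk), 3 * sqrt(p_at_risk / n))
  # objects actually leaving no footprint: positive, but bounded by the
  # at-risk probability (they must ALSO land inside a gap)
  missed <- sum(!(syn$id %in% stk$footprints$id))
  expect_gt(missed, 0)
  expect_lt(missed / n, p_at_risk)
})

test_that("population miss over the printed geometry brackets the reported bound", {
  set.seed(45)
  cleft <- runif(20000, 20, 40)
  p_pop <- miss_probability_population(200, cleft, 70)
  expect_gte(p_pop, 0.005)
  expect_lte(p_pop, 0.035)
})

test_that("classify_threshold returns one third of the plane spacing", {
  expect_equal(round(classify_threshold(70), 1), 23.3)
  expect_equal(classify_threshold(210), 70)
  expect_error(classify_threshold(0), "positive")
})
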