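make_stack <- function(syn, n_sections, field = c(20, 20), thickness = 70) {
  stk <- section_tissue(syn, thickness, n_sections = n_sections)
  stk$field_dims_um <- c(field, n_sections * thickness / 1000)
  stk
}

test_that("grid tiling produces the expected candidate frames", {
  syn <- mk_synapses(1, 1, 0.1, feret = 200, cleft = 30)
  stk <- make_stack(syn, n_sections = 3, field = c(80, 80))
  spec <- disector_grid_spec(frame_size = 5, guard_xy = 0, guard_z = 0,
                             ref_step = 1)
  grid <- build_disector_grid(stk, spec)
  expect_identical(nrow(grid), 256L)   # 16 x 16 tiling, one section pair
  expect_identical(unique(grid$lookup_section - grid$ref_section), 2L)
  # frames tile without overlap
  expect_identical(anyDuplicated(grid[c("frame_x", "frame_y", "ref_section")]), 0L)
})

test_that("requesting n disectors selects exactly n, deterministically", {
  syn <- mk_synapses(1, 1, 0.1, feret = 200, cleft = 30)
  stk <- make_stack(syn, n_sections = 3, field = c(80, 80))
  spec <- disector_grid_spec(frame_size = 5, guard_xy = 0, guard_z = 0,
                             ref_step = 1, n_disectors = 96)
  g1 <- build_disector_grid(stk, spec, seed = 5)
  g2 <- build_disector_grid(stk, spec, seed = 5)
  g3 <- build_disector_grid(stk, spec, seed = 6)
  expect_identical(nrow(g1), 96L)
  expect_identical(g1, g2)
  expect_false(identical(g1$frame_x, g3$frame_x) &&
               identical(g1$ref_section, g3$ref_section))
  expect_error(build_disector_grid(stk, disector_grid_spec(n_disectors = 1e5,
               guard_xy = 0, guard_z = 0, ref_step = 1)), "candidates")
})

test_that("degenerate stacks and oversized frames are rejected", {
  syn <- mk_synapses(1, 1, 0.1, feret = 200, cleft = 30)
  stk0 <- make_stack(syn, n_sections = 1)
  expect_error(build_disector_grid(stk0, disector_grid_spec()), "sections")
  stk <- make_stack(syn, n_sections = 10, field = c(4, 4))
  expect_error(build_disector_grid(stk, disector_grid_spec(frame_size = 5)),
               "larger than")
})

test_that("the disector rule counts tops, not profiles", {
  pair <- data.frame(disector_id = 1, ref_section = 2, lookup_section = 4,
                     frame_x = 2, frame_y = 2, frame_size = 5)
  # present in reference only, well inside the frame -> counted
  a <- mk_synapses(4, 4, 0.175, feret = 100, cleft = 30, nx = 1, nz = 0)
  stk <- make_stack(a, n_sections = 8)
  expect_identical(count_disector(stk, pair)$q_total, 1L)
  # spanning reference AND look-up -> not dissected
  b <- mk_synapses(4, 4, 0.2, feret = 600, cleft = 30, nx = 1, nz = 0)
  stk_b <- make_stack(b, n_sections = 8)
  expect_identical(count_disector(stk_b, pair)$q_total, 0L)
  # present only in the look-up -> not counted (unidirectional) but counted
  # when bidirectional counting is enabled
  cc <- mk_synapses(4, 4, 0.315, feret = 100, cleft = 30, nx = 1, nz = 0)
  stk_c <- make_stack(cc, n_sections = 8)
  expect_identical(count_disector(stk_c, pair)$q_total, 0L)
  expect_identical(count_disector(stk_c, pair, bidirectional = TRUE)$q_total, 1L)
  expect_error(count_disector(stk, data.frame(ref_section = 2,
    lookup_section = 4, frame_x = 2, frame_y = 2, frame_size = -1)),
    "malformed")
})

test_that("inclusion and exclusion edges follow the unbiased frame rule", {
  pair <- data.frame(ref_section = 1, lookup_section = 3,
                     frame_x = 5, frame_y = 5, frame_size = 5)
  probe <- function(x, y, r = 0.1) {
    syn <- mk_synapses(x, y, 0.105, feret = 2 * r * 1000, cleft = 30,
                       nx = 1, nz = 0)
    stk <- make_stack(syn, n_sections = 6)
    count_disector(stk, pair)$q_total
  }
  expect_identical(probe(7.5, 7.5), 1L)        # interior
  expect_identical(probe(10.05, 7.5), 1L)      # overlaps right (inclusion) edge
  expect_identical(probe(10.1, 7.5), 1L)       # tangent to inclusion edge
  expect_identical(probe(7.5, 10.1), 1L)       # tangent to top (inclusion)
  expect_identical(probe(5.05, 7.5), 0L)       # touches left (exclusion) edge
  expect_identical(probe(5.1, 7.5), 0L)        # tangent to exclusion edge
  expect_identical(probe(7.5, 5.05), 0L)       # touches bottom (exclusion)
  expect_identical(probe(5.05, 5.05), 0L)      # exclusion corner
  expect_identical(probe(4.8, 7.5), 0L)        # outside through the left edge
})

test_that("counts match the brute-force membership oracle on random stacks", {
  for (s in 1:20) {
    spec <- tissue_spec(box_dims = c(12, 12, 3), seed = s)
    tis <- generate_tissue(spec)
    stk <- section_tissue(tis, 70)
    grid <- build_disector_grid(stk, disector_grid_spec(guard_xy = 0.5,
                                                        guard_z = 2,
                                                        ref_step = 4))
    got <- count_disectors(stk, grid)
    for (i in seq_len(nrow(grid))) {
      want <- oracle_count_disector(stk$objects, grid[i, ], 70)
      expect_identical(got$q_total[i], want$q_total)
      expect_identical(got$q_asym[i], want$q_asym)
      expect_identical(got$q_sym[i], want$q_sym)
    }
    # per-type additivity
    expect_identical(got$q_asym + got$q_sym, got$q_total)
  }
})

test_that("tiling frames count every qualifying object exactly once", {
  # with frames tiling the whole plane, the total count equals the number of
  # z-qualifying objects, for any in-plane grid offset (no edge double
  # counting, no loss)
  spec <- tissue_spec(box_dims = c(14, 14, 2), seed = 33)
  tis <- generate_tissue(spec)
  stk <- section_tissue(tis, 70)
  syn <- stk$objects
  t_um <- 0.07
  ref <- 10; lookup <- 12
  qualifying <- sum(syn$z1_um >= ref * t_um & syn$z1_um < lookup * t_um &
                    syn$z0_um < (ref + 1) * t_um)
  w <- 5
  for (off in list(c(0, 0), c(1.3, 0.4), c(-2.1, 3.7), c(0.77, -0.77))) {
    xs <- seq(-10, 20, by = w) + off[1]
    ys <- seq(-10, 20, by = w) + off[2]
    total <- 0L
    for (x0 in xs) for (y0 in ys) {
      pair <- data.frame(ref_section = ref, lookup_section = lookup,
                         frame_x = x0, frame_y = y0, frame_size = w)
      total <- total + count_disector(stk, pair)$q_total
    }
    expect_identical(total, as.integer(qualifying))
  }
})

test_that("density arithmetic matches the printed scale", {
  # 96 disectors of 5 x 5 um x 140 nm with 188 dissected synapses
  counts <- data.frame(frame_size = 5, ref_section = 0, lookup_section = 2,
                       q_asym = c(rep(2, 73), rep(0, 23)),
                       q_sym = c(rep(0, 54), rep(1, 42)))
  stopifnot(sum(counts$q_asym) + sum(counts$q_sym) == 188)
  est <- estimate_density(counts, section_spacing = 70, factors = 1)
  expect_equal(est$density_total, 188 / 336 * 1e9, tolerance = 1e-12)
  expect_gt(est$density_total, 5e8)
  expect_lt(est$density_total, 8e8)
  # zero counts give zero density; calibration rescales by Rcum
  z <- estimate_density(data.frame(frame_size = 5, ref_section = 0,
                                   lookup_section = 2, q_asym = 0, q_sym = 0),
                        section_spacing = 70)
  expect_equal(z$density_total, 0)
  f <- deformation_factors(Re = 1.0675, RX = 1.014, RY = 0.821, RZ = 0.985)
  est_c <- estimate_density(counts, section_spacing = 70, factors = f)
  expect_equal(est_c$density_total, est$density_total * f$Rcum)
  expect_error(estimate_density(counts[0, ]), "at least one")
})

test_that("density estimation is unbiased on synthetic tissue", {
  # generator truth 7e8/mm^3; mean over seeds approaches it
  r <- density_recovery_experiment(tissue_spec(box_dims = c(16, 16, 5.6)),
                                   disector_grid_spec(), seeds = 1:12)
  expect_lt(abs(r$mean_signed_pct), 4)
  expect_lt(r$mean_abs_pct, 8)
})
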