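test_that("effective dispersal composes from natal and mate components", {
  expect_equal(sigma_from_components(1.3, 0), 1.3)
  expect_equal(sigma_f_for_target(1, 1), sqrt(0.5))
  # benchmark prior endpoints with sigma_m = 1
  expect_equal(sigma_f_for_target(0.73, 1), 0.1814, tolerance = 1e-3)
  expect_equal(sigma_f_for_target(3.08, 1), 2.9977, tolerance = 1e-3)
  expect_equal(sigma_from_components(sigma_f_for_target(2, 1), 1), 2)
  # Monte-Carlo: per-axis RMS distance to a uniformly chosen parent
  set.seed(10)
  n <- 2e5
  sf <- 0.9; sm <- 1.4
  mother_dx <- rnorm(n, 0, sf)
  mate_dx <- rnorm(n, 0, sm) # father's offset from the mother, per axis
  to_mother <- mother_dx
  to_father <- mother_dx - mate_dx
  pick_father <- runif(n) < 0.5
  d <- ifelse(pick_father, to_father, to_mother)
  expect_equal(sqrt(mean(d^2)), sigma_from_components(sf, sm), tolerance = 0.02)
})

test_that("map values interpolate bilinearly with edge clamping", {
  m <- flat_map(6L, sigma = 1.5, K = 8)
  m$dispersal$values[2, 3] <- 2.0
  m$dispersal$values[3, 3] <- 3.0
  # at a cell center: that cell's value ((2,3) centers at (1.5, 2.5))
  expect_equal(unname(interpolate_map_at(m, 1.5, 2.5)["sigma"]), 2.0)
  # midpoint between two horizontally adjacent centers: arithmetic mean
  expect_equal(unname(interpolate_map_at(m, 2.0, 2.5)["sigma"]), 2.5)
  # constant channel stays constant anywhere
  expect_equal(unname(interpolate_map_at(m, 3.217, 4.9)["K"]), 8)
  expect_error(interpolate_map_at(m, 6.5, 1), "outside")
})

test_that("survival probability is a decreasing competition response", {
  expect_equal(survival_probability(0, 5), 1)
  cc <- default_comp_cost(4)
  expect_equal(survival_probability(5 / cc, 5), 0.5)
  etas <- seq(0, 50, by = 5)
  p <- survival_probability(etas, 8)
  expect_true(all(diff(p) < 0))
  expect_error(survival_probability(1, 0), "K <= 0")
})

test_that("interaction strength matches the truncated kernel in density units", {
  # isolated individual
  expect_equal(local_interaction_strength(data.frame(x = 1, y = 1), 1), 0)
  # two co-located individuals: each feels the kernel maximum 1/(2 pi s^2)
  eta <- local_interaction_strength(data.frame(x = c(2, 2), y = c(3, 3)), 0.8)
  expect_equal(eta, rep(1 / (2 * pi * 0.8^2), 2))
  # uniform random field: mean eta ~ 0.9889 * intensity (kernel mass within
  # the 3-SD truncation); averaged over fields to tame spatial correlation
  rho <- 12; w <- 20
  ratios <- vapply(1:4, function(s) {
    set.seed(s)
    pop <- uniform_population(rho * w * w, w)
    eta <- local_interaction_strength(pop, 1)
    interior <- pop$x > 3 & pop$x < w - 3 & pop$y > 3 & pop$y < w - 3
    mean(eta[interior]) / ((rho * w * w - 1) / w^2 * 0.9889)
  }, numeric(1L))
  expect_equal(mean(ratios), 1, tolerance = 0.02)
})

test_that("initial population matches mean K and stays in the habitat", {
  m <- flat_map(5L, K = 10)
  set.seed(2)
  pop <- initial_population(m)
  expect_equal(nrow(pop), 250L)
  w <- 8L
  m2 <- flat_map(w, K = 10)
  mask <- matrix(FALSE, w, w); mask[1:4, ] <- TRUE
  m2 <- apply_habitat_mask(m2, mask)
  pop2 <- initial_population(m2, n = 300L)
  expect_true(all(pop2$x <= 4))
  m3 <- flat_map(5L, K = 10, k_range = c(1e-6, 10))
  m3$density$values[] <- 1e-6
  expect_error(initial_population(m3), "zero")
})

test_that("simulations are seed-deterministic and record a stationary population", {
  m <- flat_map(12L, sigma = 1.5, K = 8)
  p <- sim_params(n_cycles = 220L, burn_in = 60L)
  set.seed(123)
  s1 <- run_simulation(m, p, record_ancestry = FALSE)
  set.seed(123)
  s2 <- run_simulation(m, p, record_ancestry = FALSE)
  expect_identical(s1$population, s2$population)
  expect_identical(s1$realized$density, s2$realized$density)
  # stationarity: post-burn-in census means agree between the two halves
  post <- s1$pop_size[61:220]
  h1 <- mean(post[seq_len(80)]); h2 <- mean(post[81:160])
  expect_lt(abs(h1 - h2) / h1, 0.1)
  # realized density within the calibrated relation to input K
  ratio <- mean(m$density$values / s1$realized$density)
  expect_gt(ratio, 1.0)
  expect_lt(ratio, 1.3)
  # realized dispersal in the vicinity of the input sigma
  rel <- mean(s1$realized$dispersal, na.rm = TRUE) / 1.5
  expect_gt(rel, 0.85)
  expect_lt(rel, 1.1)
})

test_that("an uninhabitable parameter combination goes extinct with an error", {
  # a carrying capacity far below the achievable density, with map-wide
  # competition, collapses the population immediately
  m <- flat_map(6L, sigma = 0.73, K = 0.001, k_range = c(1e-4, 40))
  p <- sim_params(n_cycles = 50L, burn_in = 10L, sigma_c = 3)
  set.seed(1)
  expect_error(run_simulation(m, p, n_init = 200L), "extinct at cycle")
})

test_that("realized maps from an explicit event log match hand computation", {
  # one offspring with displacement (1,0) to the mother and (0,1) to the
  # father: pooled per-axis RMS over the 4 axis components = sqrt(2/4)
  ev <- data.frame(cycle = 300,
                   natal_x = 2.5, natal_y = 3.5,
                   mother_dx = 1, mother_dy = 0,
                   father_dx = 0, father_dy = 1)
  rm <- record_realized_maps(ev, census = NULL, grid_size = 5L, burn_in = 250L)
  expect_equal(rm$dispersal[3, 4], sqrt((1 + 0 + 0 + 1) / 4))
  expect_equal(rm$counts[3, 4], 4)
  expect_true(is.na(rm$dispersal[1, 1]))
  # constant population of N in area A gives density N / A everywhere
  cen <- expand.grid(cycle = 301:303, x = seq(0.5, 4.5), y = seq(0.5, 4.5))
  rm2 <- record_realized_maps(ev[0, ], census = cen, grid_size = 5L,
                              burn_in = 300L)
  expect_true(all(rm2$density == 1))
  # events at or before burn-in are excluded
  ev2 <- rbind(ev, ev); ev2$cycle <- c(100, 301)
  rm3 <- record_realized_maps(ev2, census = NULL, grid_size = 5L,
                              burn_in = 250L)
  expect_equal(rm3$counts[3, 4], 4)
})

test_that("density shows an edge deficit when dispersal loss dominates", {
  # at large sigma_f the boundary discard of offspring outweighs the lower
  # competition felt at the edge, depressing the outermost ring
  m <- flat_map(12L, sigma = 3.0, K = 10)
  p <- sim_params(n_cycles = 260L, burn_in = 100L)
  set.seed(77)
  s <- run_simulation(m, p)
  d <- s$realized$density
  ring <- c(d[1, ], d[12, ], d[, 1], d[, 12])
  interior <- d[3:10, 3:10]
  expect_lt(mean(ring), mean(interior))
})

test_that("recorded ancestry is structurally consistent", {
  sim <- shared_ancestry_sim()
  anc <- sim$ancestry
  ed <- anc$edges
  expect_true(all(ed$left < ed$right))
  expect_true(all(ed$left >= 0 & ed$right <= anc$genome_length))
  n_ind <- length(anc$birth_cycle)
  expect_true(all(ed$parent >= 0 & ed$parent < 2 * n_ind))
  expect_true(all(ed$child >= 0 & ed$child < 2 * n_ind))
  # every transmitted copy descends from a strictly older parent
  expect_true(all(anc$birth_cycle[ed$parent %/% 2 + 1] <
                    anc$birth_cycle[ed$child %/% 2 + 1]))
  # founders have no parents recorded; later individuals always do
  founders <- anc$birth_cycle == 0
  expect_true(all(anc$mother[founders] == -1))
  expect_true(all(anc$mother[!founders] >= 0))
  # final-cycle survivors' ids map into the ancestry tables
  expect_true(all(sim$population$id < n_ind))
})
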