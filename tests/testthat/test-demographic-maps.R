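test_that("boundary polynomials interpolate their points exactly", {
  expect_equal(fit_boundary_polynomial(list(x = c(0, 1), y = c(0, 1))),
               c(0, 1))
  # quadratic through (0,0), (0.5,1), (1,0): y = 4x - 4x^2
  expect_equal(fit_boundary_polynomial(list(x = c(0, 0.5, 1), y = c(0, 1, 0))),
               c(0, 4, -4))
  set.seed(1)
  for (deg in 1:3) {
    pts <- list(x = sample(seq(0, 50, by = 0.7), deg + 1), y = runif(deg + 1, 0, 50))
    cf <- fit_boundary_polynomial(pts)
    expect_equal(demomap:::eval_polynomial(cf, pts$x), pts$y, tolerance = 1e-8)
  }
  expect_error(fit_boundary_polynomial(list(x = c(1, 1), y = c(0, 2))),
               "duplicate x")
})

test_that("cells are assigned to segments by the below-curve rule", {
  # horizontal line y = 25 on a 50-wide map: 25 rows of centers below
  labels <- assign_segments(50L, c(25), max_segments = 3L)
  expect_equal(as.integer(sort(table(labels))), c(1250L, 1250L))
  # curve entirely below the habitat: a single segment
  labels <- assign_segments(20L, c(-5), max_segments = 3L)
  expect_equal(max(labels), 1L)
})

test_that("segment labels agree with an independent flood fill and respect the cap", {
  w <- 50L
  # cubic exiting through the bottom edge splits "below" into 2 components
  curve <- fit_boundary_polynomial(list(x = c(5, 25, 30, 45),
                                        y = c(40, -10, -12, 35)))
  centers <- seq_len(w) - 0.5
  below <- outer(demomap:::eval_polynomial(curve, centers), centers, `>`)
  oracle <- flood_fill_components(below)
  expect_equal(max(oracle), 3L)
  labels <- assign_segments(w, curve, max_segments = 3L)
  expect_equal(max(labels), 3L)
  # identical partition up to label names
  expect_equal(length(unique(paste(oracle, labels))), 3L)
  # cap at 2: merged into nearest kept component, still a valid partition
  capped <- assign_segments(w, curve, max_segments = 2L)
  expect_equal(max(capped), 2L)
})

test_that("segment values honour the range construction", {
  prior <- map_prior(4, 40, "density")
  set.seed(11)
  v1 <- draw_segment_values(prior, 1L)
  expect_length(v1, 1L)
  expect_true(v1 >= 4 && v1 <= 40)
  for (i in 1:50) {
    v2 <- draw_segment_values(prior, 2L)
    expect_length(unique(v2), 2L)
    expect_true(all(v2 >= 4 & v2 <= 40))
    v3 <- draw_segment_values(prior, 3L)
    mid <- sort(v3)[2L]
    expect_gt(mid, min(v3))
    expect_lt(mid, max(v3))
  }
})

test_that("channel draws stay in range with at most max_segments values", {
  prior <- map_prior(0.73, 3.08, "dispersal")
  set.seed(5)
  for (i in 1:200) {
    ch <- draw_channel(prior, 12L, max_segments = 3L)
    expect_lte(length(unique(as.vector(ch$values))), 3L)
    expect_true(all(ch$values >= 0.73 & ch$values <= 3.08))
  }
  # forced flat draw
  ch <- draw_channel(prior, 12L, degree = 0L)
  expect_equal(length(unique(as.vector(ch$values))), 1L)
})

test_that("a quarter of draws are flat and flat values are log-uniform", {
  prior <- map_prior(4, 40, "density")
  set.seed(99)
  draws <- replicate(10000, {
    ch <- draw_channel(prior, 5L, max_segments = 3L)
    if (ch$degree == 0L) ch$values[1L, 1L] else NA_real_
  })
  # a degree-zero draw is constant across all cells
  flat_ch <- draw_channel(prior, 5L, degree = 0L)
  expect_length(unique(as.vector(flat_ch$values)), 1L)
  frac_flat <- mean(!is.na(draws))
  expect_gt(frac_flat, 0.24)
  expect_lt(frac_flat, 0.26)
  ks <- stats::ks.test(log(draws[!is.na(draws)]),
                       "punif", log(4), log(40))
  expect_gt(ks$p.value, 0.01)
})

test_that("dihedral transforms preserve values and compose as a group", {
  set.seed(3)
  m <- draw_demographic_map(map_prior(0.73, 3.08), map_prior(4, 40, "density"),
                            10L, transform = FALSE)
  expect_equal(apply_dihedral_transform(m, 0L), m)
  r90twice <- apply_dihedral_transform(apply_dihedral_transform(m, 1L), 1L)
  expect_equal(r90twice$dispersal$values,
               apply_dihedral_transform(m, 2L)$dispersal$values)
  for (e in 0:7) {
    tr <- apply_dihedral_transform(m, e)
    expect_equal(sort(as.vector(tr$density$values)),
                 sort(as.vector(m$density$values)))
    expect_equal(mean(tr$dispersal$values), mean(m$dispersal$values))
  }
})

test_that("the habitat mask zeroes both channels and masks transforms too", {
  set.seed(8)
  w <- 10L
  m <- draw_demographic_map(map_prior(0.73, 3.08), map_prior(4, 40, "density"), w)
  mask <- matrix(runif(w * w) < 0.6, w, w)
  mask[1, 1] <- TRUE
  mm <- apply_habitat_mask(m, mask)
  expect_true(all(mm$dispersal$values[!mask] == 0))
  expect_true(all(mm$density$values[!mask] == 0))
  expect_equal(mean(mm$density$values > 0), mean(mask))
  # all-true mask leaves values unchanged
  same <- apply_habitat_mask(m, matrix(TRUE, w, w))
  expect_equal(same$dispersal$values, m$dispersal$values)
  expect_error(apply_habitat_mask(m, matrix(FALSE, w, w)), "no habitable")
  # transform moves the mask with the channels
  tr <- apply_dihedral_transform(mm, 5L)
  expect_true(all(tr$dispersal$values[!tr$habitat_mask] == 0))
})

test_that("viability correction raises offending cells to the threshold", {
  w <- 6L
  fit <- viability_fit(slope = -0.5, intercept = log(2), boost = 1.25)
  m <- flat_map(w, sigma = 0.8, K = 9, sigma_range = c(0.1, 10),
                k_range = c(0.5, 50))
  # threshold at K = 9: exp(-0.5 * log 9 + log 2) = 2/3 < 0.8: no change
  set.seed(2)
  out <- viability_correct(m, fit)
  expect_equal(out$dispersal$values, m$dispersal$values)
  expect_equal(out$density$values, m$density$values)
  # K = 1 gives threshold 2 > 0.8: offending
  m2 <- flat_map(w, sigma = 0.8, K = 1, sigma_range = c(0.1, 10),
                 k_range = c(0.5, 50))
  set.seed(1)
  repeat {
    out2 <- viability_correct(m2, fit)
    if (attr(out2, "boosted_channel") == "dispersal") break
  }
  expect_equal(out2$dispersal$values[1, 1],
               exp(-0.5 * log(1) + log(2)) * 1.25)
  repeat {
    out3 <- viability_correct(m2, fit)
    if (attr(out3, "boosted_channel") == "density") break
  }
  # K solved from sigma = exp(m log K + b): K = exp((log s - b)/m), boosted
  expect_equal(out3$density$values[1, 1],
               exp((log(0.8) - log(2)) / -0.5) * 1.25)
  # monotone: boosted channel never decreases
  expect_true(all(out3$density$values >= m2$density$values))
  expect_true(all(out2$dispersal$values >= m2$dispersal$values))
})

test_that("maps round-trip through the CSV dialect and render to PNG", {
  set.seed(21)
  w <- 9L
  m <- draw_demographic_map(map_prior(0.73, 3.08), map_prior(4, 40, "density"), w)
  mask <- matrix(runif(w * w) < 0.7, w, w); mask[3, 3] <- TRUE
  m <- apply_habitat_mask(m, mask)
  prefix <- file.path(tempdir(), "roundtrip")
  write_demographic_map(m, prefix, seed = 21L)
  back <- read_demographic_map(prefix)
  expect_equal(back$dispersal$values, m$dispersal$values, tolerance = 1e-9)
  expect_equal(back$density$values, m$density$values, tolerance = 1e-9)
  expect_equal(back$habitat_mask, m$habitat_mask)
  png_path <- file.path(tempdir(), "map.png")
  render_map_png(m, png_path)
  img <- png::readPNG(png_path)
  expect_equal(dim(img)[1:2], c(w, w))
  # red channel encodes K on the northern-first raster
  expect_equal(img[w, 1, 1] > 0, m$density$values[1, 1] > 4)
  # mask round trip through CSV
  mpath <- paste0(prefix, "_mask.csv")
  expect_equal(read_habitat_mask(mpath), m$habitat_mask)
})

test_that("map arrays convert back and forth", {
  set.seed(31)
  m <- draw_demographic_map(map_prior(0.73, 3.08), map_prior(4, 40, "density"), 7L)
  a <- map_to_array(m)
  expect_equal(dim(a), c(7L, 7L, 2L))
  m2 <- array_to_map(a, sigma_prior = m$dispersal$prior, k_prior = m$density$prior)
  expect_equal(map_to_array(m2), a)
})
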