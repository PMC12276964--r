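test_that("pair enumeration covers and subsets the pair universe", {
  expect_equal(100 * 99 / 2, 4950)
  set.seed(1)
  full <- enumerate_pairs(3L, 3L)
  expect_equal(full$pairs[order(full$pairs[, 2], full$pairs[, 1]), ],
               cbind(c(1L, 1L, 2L), c(2L, 3L, 3L)))
  expect_error(enumerate_pairs(100L, 4951L), "exceeds")
  sub <- enumerate_pairs(100L, 450L, 100L)
  expect_equal(nrow(sub$pairs), 450L)
  expect_equal(sum(sub$active), 100L)
  expect_true(all(sub$pairs[, 1] < sub$pairs[, 2]))
  expect_false(anyDuplicated(sub$pairs) > 0)
  # exhaustive draws always produce valid distinct pairs
  for (r in 1:50) {
    pr <- enumerate_pairs(30L, 435L)$pairs
    expect_false(anyDuplicated(pr) > 0)
    expect_true(all(pr[, 1] >= 1 & pr[, 2] <= 30 & pr[, 1] < pr[, 2]))
  }
})

test_that("the genotype branch shares weights across pairs", {
  set.seed(2)
  model <- build_model(20L, tiny_model_config())
  g <- matrix(sample(0:2, 8 * 20, TRUE), 8, 20)
  pairs <- rbind(c(1L, 2L), c(3L, 4L), c(1L, 2L)) # duplicated pair
  X <- demomap:::pair_tensor(g, pairs)
  G <- demomap:::geno_forward(model, X)$G
  expect_equal(ncol(G), 6L) # configured feature count
  expect_equal(G[1, ], G[3, ]) # identical pairs, identical features
  expect_false(isTRUE(all.equal(G[1, ], G[2, ])))
  # constant input collapses every pair to the same features
  Xz <- X * 0
  Gz <- demomap:::geno_forward(model, Xz)$G
  expect_equal(Gz[1, ], Gz[2, ])
})

test_that("the locations table has the documented redundant layout", {
  pl <- matrix(runif(12), 3, 4)
  tab <- build_locations_table(2L, pl)
  expect_equal(dim(tab), c(12L, 7L))
  expect_equal(tab[, 7], rep(2, 12)) # raw width feature
  # cell-major then pair: first k rows share the first cell center
  expect_equal(tab[1:3, 1], rep(0.5 / 2, 3))
  expect_equal(tab[1:3, 3:6], pl / 2)
})

test_that("spatial scores are nonnegative with one score per feature", {
  set.seed(3)
  model <- build_model(20L, tiny_model_config())
  tab <- build_locations_table(3L, matrix(runif(20), 5, 4))
  S <- demomap:::loc_forward(model, tab)$S
  expect_true(min(S) >= 0)
  expect_equal(ncol(S), model$config$features)
  # zero score weights leave the combiner to its bias terms
  m0 <- model
  m0$params$loc1_w[] <- 0; m0$params$loc1_b[] <- 0
  m0$params$loc2_w[] <- 0; m0$params$loc2_b[] <- 0
  G <- matrix(rnorm(5 * 6), 5, 6)
  Y0 <- demomap:::combiner_forward(m0, G, demomap:::loc_forward(m0, tab)$S, 3L)$Y
  bias_only <- demomap:::combiner_forward(
    m0, G * 0, matrix(0, 45, 6), 3L)$Y
  expect_equal(Y0, bias_only)
})

test_that("the batched combiner equals the literal per-cell loop", {
  set.seed(4)
  for (rep in 1:5) {
    cfg <- tiny_model_config(features = 4L)
    model <- build_model(20L, cfg)
    w <- 3L; k <- 5L
    G <- matrix(rnorm(k * 4), k, 4)
    S <- matrix(abs(rnorm(w * w * k * 4)), w * w * k, 4)
    batched <- demomap:::combiner_forward(model, G, S, w)$Y
    naive <- combine_reference(model, G, S, w)
    expect_equal(batched, naive, tolerance = 1e-10)
    # fused C++ kernel agrees with both
    p <- model$params
    fused <- demomap:::.comb_fused(
      matrix(0, w * w * k, 7), G, matrix(0, w * w, 2),
      rep(1L, w * w), p$loc1_w, p$loc1_b, p$loc2_w, p$loc2_b,
      p$comb_w, p$comb_b, p$f1_w, p$f1_b, p$f2_w, p$f2_b, w, FALSE)
    # (zero locations make S all relu(bias); compare through the R path)
    S0 <- demomap:::loc_forward(model, matrix(0, w * w * k, 7))$S
    expect_equal(fused$Y, demomap:::combiner_forward(model, G, S0, w)$Y,
                 tolerance = 1e-10)
    # permuting pairs (rows of G with matching S slices) leaves output alone
    perm <- sample(k)
    Sp <- S
    for (i in seq_len(w * w)) {
      Sp[(i - 1) * k + seq_len(k), ] <- S[(i - 1) * k + perm, ]
    }
    permuted <- demomap:::combiner_forward(model, G[perm, ], Sp, w)$Y
    expect_equal(permuted, batched, tolerance = 1e-10)
  }
})

test_that("all-zero scores for a cell make its output genotype-independent", {
  set.seed(5)
  cfg <- tiny_model_config(features = 4L)
  model <- build_model(20L, cfg)
  w <- 2L; k <- 3L
  S <- matrix(abs(rnorm(w * w * k * 4)), w * w * k, 4)
  S[seq_len(k), ] <- 0 # first cell sees no genotype signal
  G1 <- matrix(rnorm(k * 4), k, 4)
  G2 <- matrix(rnorm(k * 4), k, 4)
  y1 <- demomap:::combiner_forward(model, G1, S, w)$Y
  y2 <- demomap:::combiner_forward(model, G2, S, w)$Y
  expect_equal(y1[1, ], y2[1, ])
  expect_false(isTRUE(all.equal(y1[2, ], y2[2, ])))
})

test_that("prediction is map-shaped, seeded, and size-invariant in parameters", {
  set.seed(6)
  ds <- fake_genotype_dataset(n = 8L, m = 30L, w = 5L)
  model <- build_model(30L, tiny_model_config())
  set.seed(9); y1 <- predict_map(model, ds, width = 5L, k_init = 10L)
  expect_equal(dim(y1), c(5L, 5L, 2L))
  set.seed(9); y2 <- predict_map(model, ds, width = 5L, k_init = 10L)
  expect_identical(y1, y2)
  # same parameters serve any pair count and map size
  y3 <- predict_map(model, ds, width = 7L, k_init = 20L)
  expect_equal(dim(y3), c(7L, 7L, 2L))
  set.seed(1); m_a <- build_model(30L, tiny_model_config())
  set.seed(2); m_b <- build_model(30L, tiny_model_config())
  expect_equal(n_parameters(m_a), n_parameters(m_b))
  expect_error(predict_map(model, fake_genotype_dataset(m = 40L), 5L),
               "built for")
})

test_that("gradients match finite differences through both branches", {
  set.seed(7)
  cfg <- tiny_model_config()
  model <- build_model(20L, cfg)
  ds <- fake_genotype_dataset(n = 6L, m = 20L, w = 3L)
  tf <- structure(list(center = c(0, 0), scale = c(1, 1)),
                  class = "target_transform")
  target <- array(abs(rnorm(18)) + 0.5, c(3, 3, 2))
  td <- prepare_training_dataset(ds, target, tf, 3L, k_init = 5L)
  lg <- demomap:::loss_and_grads(model, td)
  loss_of <- function(params) {
    m2 <- model; m2$params <- params
    demomap:::dataset_loss(m2, td)
  }
  eps <- 1e-6
  set.seed(8)
  for (nm in names(model$params)) {
    idx <- sample(seq_along(model$params[[nm]]),
                  min(3, length(model$params[[nm]])))
    for (t in idx) {
      pp <- model$params; pp[[nm]][t] <- pp[[nm]][t] + eps
      pm <- model$params; pm[[nm]][t] <- pm[[nm]][t] - eps
      fd <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(lg$grads[[nm]][t], fd, tolerance = 1e-4)
    }
  }
})

test_that("masked pairs contribute forward signal but no branch-one gradient", {
  set.seed(10)
  cfg <- tiny_model_config()
  model <- build_model(20L, cfg)
  ds <- fake_genotype_dataset(n = 6L, m = 20L, w = 3L)
  tf <- structure(list(center = c(0, 0), scale = c(1, 1)),
                  class = "target_transform")
  target <- array(abs(rnorm(18)) + 0.5, c(3, 3, 2))
  td <- prepare_training_dataset(ds, target, tf, 3L, k_init = 6L,
                                 k_extract = 2L)
  grads <- demomap:::loss_and_grads(model, td)$grads
  # stop-gradient semantics: the branch-one gradient equals the finite
  # difference of a loss in which the masked pairs' features are frozen
  # constants while the forward pass still uses every pair
  tn <- demomap:::td_tensors(model, td)
  G0 <- demomap:::geno_forward(model, tn$X)$G
  frozen_loss <- function(params) {
    m2 <- model; m2$params <- params
    G <- demomap:::geno_forward(m2, tn$X)$G
    G[!td$pairs$active, ] <- G0[!td$pairs$active, ]
    lf <- demomap:::loc_forward(m2, td$tab)
    Y <- demomap:::combiner_forward(m2, G, lf$S, td$width)$Y
    sum((Y - td$target)^2) / (2 * nrow(td$target))
  }
  eps <- 1e-6
  set.seed(11)
  for (nm in c("conv1_w", "geno_w", "geno_b")) {
    for (t in sample(seq_along(model$params[[nm]]), 3)) {
      pp <- model$params; pp[[nm]][t] <- pp[[nm]][t] + eps
      pm <- model$params; pm[[nm]][t] <- pm[[nm]][t] - eps
      fd <- (frozen_loss(pp) - frozen_loss(pm)) / (2 * eps)
      expect_equal(grads[[nm]][t], fd, tolerance = 1e-3)
    }
  }
  # with no mask the gradients differ: masked pairs do carry information
  grads_full <- demomap:::model_backward(
    model,
    demomap:::model_forward(model, tn$X, td$tab, td$width, want_cache = TRUE)$cache,
    (demomap:::model_forward(model, tn$X, td$tab, td$width)$Y - td$target) /
      nrow(td$target),
    active = NULL)
  expect_false(isTRUE(all.equal(grads_full$conv1_w, grads$conv1_w)))
})
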