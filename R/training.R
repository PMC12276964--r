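# Target preprocessing, masked MSE loss, plateau learning-rate scheduling,
# Adam, and the training loop.

#' Fit the target transform on training maps
#'
#' Map values are log transformed and the dispersal and density channels are
#' independently centered and scaled, using statistics of the training maps
#' only (habitable cells).
#'
#' @param maps List of `w x w x 2` arrays (or `demographic_map`s) of
#'   training targets on the natural scale.
#' @param mask Optional logical `w x w` habitat mask shared by the maps.
#' @return Object of class `target_transform` with per-channel `center` and
#'   `scale`.
#' @export
fit_target_transform <- function(maps, mask = NULL) {
  arrs <- lapply(maps, function(m) {
    if (inherits(m, "demographic_map")) map_to_array(m) else m
  })
  center <- numeric(2L); scale <- numeric(2L)
  for (ch in 1:2) {
    vals <- unlist(lapply(arrs, function(a) {
      v <- a[, , ch]
      if (!is.null(mask)) v <- v[mask]
      v
    }))
    if (any(vals <= 0)) {
      stop("nonpositive habitable map value; cannot log transform",
           call. = FALSE)
    }
    lv <- log(vals)
    center[ch] <- mean(lv)
    scale[ch] <- stats::sd(lv)
    if (!is.finite(scale[ch]) || scale[ch] <= 0) scale[ch] <- 1
  }
  structure(list(center = center, scale = scale), class = "target_transform")
}

#' Apply the target transform
#'
#' @param transform A [fit_target_transform()] result.
#' @param a `w x w x 2` array on the natural scale.
#' @param mask Optional habitat mask; masked cells are set to 0.
#' @return Transformed array (log, centered, scaled per channel).
#' @export
apply_target_transform <- function(transform, a, mask = NULL) {
  out <- a
  for (ch in 1:2) {
    v <- a[, , ch]
    if (is.null(mask)) {
      out[, , ch] <- (log(v) - transform$center[ch]) / transform$scale[ch]
    } else {
      r <- matrix(0, nrow(v), ncol(v))
      r[mask] <- (log(v[mask]) - transform$center[ch]) / transform$scale[ch]
      out[, , ch] <- r
    }
  }
  out
}

#' Invert the target transform
#'
#' @param transform A [fit_target_transform()] result.
#' @param a Transformed `w x w x 2` array.
#' @return Array on the natural scale.
#' @export
invert_target_transform <- function(transform, a) {
  out <- a
  for (ch in 1:2) {
    out[, , ch] <- exp(a[, , ch] * transform$scale[ch] + transform$center[ch])
  }
  out
}

#' Masked mean squared error over both map channels
#'
#' Without a mask this is `sum((Y - Yhat)^2) / (2 w^2)`; with a mask the
#' denominator is twice the number of habitable cells and masked cells are
#' excluded from the sum.
#'
#' @param y_true,y_est `w x w x 2` arrays (or `w^2 x 2` matrices) on a common
#'   scale.
#' @param mask Optional logical `w x w` habitat mask.
#' @return The scalar loss.
#' @export
masked_mse <- function(y_true, y_est, mask = NULL) {
  yt <- matrix(y_true, ncol = 2L)
  ye <- matrix(y_est, ncol = 2L)
  stopifnot(dim(yt) == dim(ye))
  keep <- if (is.null(mask)) rep(TRUE, nrow(yt)) else as.vector(mask)
  if (!any(keep)) stop("mask excludes every cell", call. = FALSE)
  sum((yt[keep, ] - ye[keep, ])^2) / (2 * sum(keep))
}

# ---- plateau learning-rate scheduler --------------------------------------

#' Plateau-based learning-rate scheduler state
#'
#' The learning rate is halved whenever `halve_after` consecutive epochs
#' pass without reduction of the validation loss, and training stops once
#' `stop_after` epochs pass without reduction.
#'
#' @param lr Initial learning rate.
#' @param halve_after Epochs of plateau before each halving (default 10).
#' @param stop_after Epochs of plateau before stopping (default 100).
#' @param min_delta Minimum decrease that counts as an improvement
#'   (default 0: any strict reduction).
#' @param baseline Starting best loss (default `Inf`).
#' @return Scheduler state list.
#' @export
plateau_scheduler <- function(lr = 1e-4, halve_after = 10L, stop_after = 100L,
                              min_delta = 0, baseline = Inf) {
  list(lr = lr, halve_after = as.integer(halve_after),
       stop_after = as.integer(stop_after), min_delta = min_delta,
       best = baseline, since_best = 0L, improved = FALSE, stop = FALSE,
       halvings = 0L)
}

#' Advance the scheduler by one epoch
#'
#' @param state Scheduler state from [plateau_scheduler()] or a previous
#'   step.
#' @param val_loss Validation loss observed this epoch.
#' @return Updated state; fields `improved`, `lr`, and `stop` reflect the
#'   epoch's outcome.
#' @export
scheduler_step <- function(state, val_loss) {
  if (val_loss < state$best - state$min_delta) {
    state$best <- val_loss
    state$since_best <- 0L
    state$improved <- TRUE
  } else {
    state$since_best <- state$since_best + 1L
    state$improved <- FALSE
    if (state$since_best >= state$stop_after) {
      state$stop <- TRUE
    } else if (state$since_best %% state$halve_after == 0L) {
      state$lr <- state$lr / 2
      state$halvings <- state$halvings + 1L
    }
  }
  state
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}

# ---- training data preparation --------------------------------------------

#' Assemble a training dataset
#'
#' Bundles a genotype dataset with its (transformed) target map and a fixed
#' pair subset for the forward pass.
#'
#' @param dataset A `genotype_dataset`.
#' @param target `w x w x 2` array on the natural scale (the simulation
#'   input map).
#' @param transform A fitted [fit_target_transform()].
#' @param width Map width.
#' @param k_init,k_extract Pair-subset sizes.
#' @param mask Optional habitat mask.
#' @return A `training_dataset` list.
#' @export
prepare_training_dataset <- function(dataset, target, transform, width,
                                     k_init = 100L, k_extract = k_init,
                                     mask = NULL) {
  n <- length(dataset$individual_ids)
  k_init <- min(k_init, n * (n - 1) / 2)
  pairs <- enumerate_pairs(n, k_init, min(k_extract, k_init))
  locs <- as.matrix(dataset$locations[, c("x", "y")])
  pl <- cbind(locs[pairs$pairs[, 1L], , drop = FALSE],
              locs[pairs$pairs[, 2L], , drop = FALSE])
  structure(list(
    genotypes = dataset$genotypes,
    locs = locs,
    tab = build_locations_table(width, pl),
    pairs = pairs,
    k_init = k_init, k_extract = min(k_extract, k_init),
    target = matrix(apply_target_transform(transform, target, mask),
                    ncol = 2L),
    mask = mask, width = width,
    scratch = new.env(parent = emptyenv())), class = "training_dataset")
}

# draw a fresh random pair subset (training-time augmentation; mirrors the
# random subsets used at prediction time)
redraw_pairs <- function(td, phased, kernel) {
  n <- nrow(td$locs)
  td$pairs <- enumerate_pairs(n, td$k_init, td$k_extract)
  pl <- cbind(td$locs[td$pairs$pairs[, 1L], , drop = FALSE],
              td$locs[td$pairs$pairs[, 2L], , drop = FALSE])
  td$tab <- build_locations_table(td$width, pl)
  td$scratch <- new.env(parent = emptyenv())
  td$scratch$X <- pair_tensor(td$genotypes, td$pairs$pairs, phased)
  td$scratch$M1 <- conv_im2col(td$scratch$X, kernel)
  td
}

# pair tensor and first-layer im2col depend only on the dataset, so they are
# computed once and memoized on the dataset's scratch environment
td_tensors <- function(model, td) {
  env <- td$scratch
  if (is.null(env$X)) {
    env$X <- pair_tensor(td$genotypes, td$pairs$pairs, model$config$phased)
    env$M1 <- conv_im2col(env$X, model$layers[[1L]]$kernel)
  }
  env
}

fused_args <- function(model, td, G, keep, want_grads) {
  p <- model$params
  .comb_fused(td$tab, G, td$target, as.integer(keep),
              p$loc1_w, p$loc1_b, p$loc2_w, p$loc2_b,
              p$comb_w, p$comb_b, p$f1_w, p$f1_b, p$f2_w, p$f2_b,
              td$width, want_grads)
}

loss_and_grads <- function(model, td) {
  tn <- td_tensors(model, td)
  gf <- geno_forward(model, tn$X, M1 = tn$M1)
  keep <- if (is.null(td$mask)) rep(TRUE, td$width^2) else as.vector(td$mask)
  cf <- fused_args(model, td, gf$G, keep, TRUE)
  dG <- cf$dG
  dG[!td$pairs$active, ] <- 0 # stop-gradient on masked pairs
  grads <- geno_backward(model, tn$X, gf$cache, dG)
  for (nm in c("loc1_w", "loc1_b", "loc2_w", "loc2_b", "comb_w", "comb_b",
               "f1_w", "f1_b", "f2_w", "f2_b")) {
    g <- cf[[nm]]
    grads[[nm]] <- if (is.matrix(model$params[[nm]])) g else as.numeric(g)
  }
  list(loss = cf$loss, grads = grads)
}

dataset_loss <- function(model, td) {
  tn <- td_tensors(model, td)
  gf <- geno_forward(model, tn$X, M1 = tn$M1)
  keep <- if (is.null(td$mask)) rep(TRUE, td$width^2) else as.vector(td$mask)
  fused_args(model, td, gf$G, keep, FALSE)$loss
}

#' Training configuration
#'
#' @param batch_size Datasets per optimization step (default 10).
#' @param learning_rate Initial Adam learning rate (default 1e-4).
#' @param validation_fraction Fraction of datasets held out for validation
#'   (default 0.2).
#' @param plateau_halve Epochs without validation improvement before the
#'   learning rate is halved (default 10).
#' @param plateau_stop Epochs without validation improvement before
#'   training stops (default 100).
#' @param max_epochs Hard cap on epochs (default 1000).
#' @param min_delta Minimum decrease counting as improvement (default 0).
#' @param resample_pairs Redraw each training dataset's random pair subset
#'   every epoch (training-time augmentation mirroring the random pair
#'   subsets used at prediction time; default `FALSE`).
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 10L, learning_rate = 1e-4,
                         validation_fraction = 0.2, plateau_halve = 10L,
                         plateau_stop = 100L, max_epochs = 1000L,
                         min_delta = 0, resample_pairs = FALSE) {
  stopifnot(validation_fraction > 0, validation_fraction < 1)
  structure(as.list(environment()), class = "train_config")
}

#' Train a map-estimation model
#'
#' Adam optimization of the masked MSE between predicted and preprocessed
#' target maps, with an 80/20 train/validation split, plateau-based
#' learning-rate halving, plateau-based stopping, and restoration of the
#' best-validation weights.
#'
#' @param model A `map_model`.
#' @param datasets List of `training_dataset`s (see
#'   [prepare_training_dataset()]).
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with the trained `model` and a `history` data frame
#'   (epoch, train and validation loss, learning rate).
#' @export
train <- function(model, datasets, config = train_config(), verbose = FALSE) {
  stopifnot(length(datasets) >= 2L)
  n <- length(datasets)
  n_val <- max(1L, round(config$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  train_idx <- setdiff(seq_len(n), val_idx)
  sched <- plateau_scheduler(config$learning_rate, config$plateau_halve,
                             config$plateau_stop, config$min_delta)
  opt <- adam_init(model$params)
  best_params <- model$params
  history <- data.frame()
  for (epoch in seq_len(config$max_epochs)) {
    if (isTRUE(config$resample_pairs)) {
      for (di in train_idx) {
        datasets[[di]] <- redraw_pairs(datasets[[di]], model$config$phased,
                                       model$layers[[1L]]$kernel)
      }
    }
    order_idx <- sample(train_idx)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
    epoch_loss <- 0
    for (batch in batches) {
      acc <- NULL
      bl <- 0
      for (di in batch) {
        lg <- loss_and_grads(model, datasets[[di]])
        bl <- bl + lg$loss
        if (is.null(acc)) {
          acc <- lg$grads
        } else {
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + lg$grads[[nm]]
        }
      }
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(batch)
      if (!all(vapply(acc, function(g) all(is.finite(g)), logical(1L)))) {
        stop(sprintf("training diverged (non-finite gradients) at epoch %d",
                     epoch), call. = FALSE)
      }
      st <- adam_step(model$params, acc, opt, sched$lr)
      model$params <- st$params
      opt <- st$state
      epoch_loss <- epoch_loss + bl
    }
    epoch_loss <- epoch_loss / length(train_idx)
    val_loss <- mean(vapply(datasets[val_idx], function(td) {
      dataset_loss(model, td)
    }, numeric(1L)))
    if (!is.finite(val_loss)) {
      stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
           call. = FALSE)
    }
    sched <- scheduler_step(sched, val_loss)
    if (sched$improved) best_params <- model$params
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = epoch_loss,
                                val_loss = val_loss, lr = sched$lr))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                      epoch, epoch_loss, val_loss, sched$lr))
    }
    if (sched$stop) break
  }
  model$params <- best_params
  list(model = model, history = history, val_idx = val_idx)
}

#' Resample additional training datasets from stored simulations
#'
#' Draws `draws` independent sample sets per simulation (sampling with
#' replacement across draws, each draw without replacement within the
#' population) and synthesizes a genotype dataset for each, so one
#' simulation yields several training datasets that share a target map.
#'
#' @param sims List of `sim_result`s with recorded ancestry.
#' @param draws Sample sets per simulation.
#' @param scheme A [sampling_scheme()].
#' @param config A [genotype_config()].
#' @param recap A [recap_config()].
#' @param seed Base seed for genotype synthesis.
#' @return List (one element per simulation) of lists of `genotype_dataset`s.
#' @export
augment_resample <- function(sims, draws, scheme, config,
                             recap = recap_config(), seed = 1L) {
  lapply(seq_along(sims), function(si) {
    sim <- sims[[si]]
    sets <- lapply(seq_len(draws), function(d) {
      draw_sample(sim$population, scheme, sim$map$width)$id
    })
    synthesize_genotypes(sim, sets, config, recap,
                         seed = seed + si * 1000L)
  })
}
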