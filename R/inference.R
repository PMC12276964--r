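# Back-transformed prediction with replicate averaging, accuracy metrics,
# and the parametric bootstrap.

#' Ensemble map prediction
#'
#' Runs `R` forward passes with independent random pair subsets,
#' back-transforms each to the natural scale, and averages per cell. Masked
#' cells are set to `NA` in the point estimate.
#'
#' @param model A trained `map_model`.
#' @param dataset A `genotype_dataset`.
#' @param width Map width.
#' @param transform The fitted [fit_target_transform()] used in training.
#' @param R Number of replicates (the reference analysis uses 100).
#' @param k_init Pairs per replicate forward pass.
#' @param mask Optional habitat mask.
#' @return Object of class `map_estimate`: `point` (`w x w x 2`),
#'   `replicates` (`R` x w x w x 2), and `mask`.
#' @export
ensemble_predict <- function(model, dataset, width, transform, R = 100L,
                             k_init = 100L, mask = NULL) {
  if (R < 1) stop("R must be at least 1", call. = FALSE)
  reps <- array(0, c(R, width, width, 2L))
  for (r in seq_len(R)) {
    y <- predict_map(model, dataset, width, k_init = k_init)
    reps[r, , , ] <- invert_target_transform(transform, y)
  }
  point <- apply(reps, c(2L, 3L, 4L), mean)
  if (!is.null(mask)) {
    for (ch in 1:2) {
      p <- point[, , ch]; p[!mask] <- NA_real_; point[, , ch] <- p
    }
  }
  structure(list(point = point, replicates = reps, mask = mask,
                 R = R), class = "map_estimate")
}

#' @export
print.map_estimate <- function(x, ...) {
  cat(sprintf("map_estimate: %dx%d grid, %d replicates\n",
              dim(x$point)[1L], dim(x$point)[2L], x$R))
  cat(sprintf("  mean sigma %.3g, mean density %.3g\n",
              mean(x$point[, , 1L], na.rm = TRUE),
              mean(x$point[, , 2L], na.rm = TRUE)))
  invisible(x)
}

#' Mean relative absolute error per channel
#'
#' Per-cell `|estimate - truth| / truth`, averaged over evaluated cells:
#' habitable cells with positive truth; dispersal cells with no recorded
#' events (`NA` truth) are excluded.
#'
#' @param true_map,est_map `w x w x 2` arrays on the natural scale.
#' @param mask Optional habitat mask.
#' @return Named vector `c(dispersal = ..., density = ...)`.
#' @export
mrae <- function(true_map, est_map, mask = NULL) {
  out <- numeric(2L)
  for (ch in 1:2) {
    tv <- true_map[, , ch]; ev <- est_map[, , ch]
    keep <- !is.na(tv) & !is.na(ev)
    if (!is.null(mask)) keep <- keep & mask
    if (any(tv[keep] <= 0)) {
      stop("nonpositive true value on an evaluated cell", call. = FALSE)
    }
    out[ch] <- mean(abs(ev[keep] - tv[keep]) / tv[keep])
  }
  names(out) <- c("dispersal", "density")
  out
}

#' Squared Pearson correlation between true and estimated maps
#'
#' @param true_map,est_map `w x w x 2` arrays.
#' @param mask Optional habitat mask.
#' @return Named vector of per-channel r-squared (`NA` when either map has
#'   zero variance over the evaluated cells).
#' @export
map_correlation <- function(true_map, est_map, mask = NULL) {
  out <- numeric(2L)
  for (ch in 1:2) {
    tv <- true_map[, , ch]; ev <- est_map[, , ch]
    keep <- !is.na(tv) & !is.na(ev)
    if (!is.null(mask)) keep <- keep & mask
    if (sum(keep) < 3L) stop("need at least 3 evaluated cells", call. = FALSE)
    if (stats::sd(tv[keep]) == 0 || stats::sd(ev[keep]) == 0) {
      out[ch] <- NA_real_
    } else {
      out[ch] <- stats::cor(tv[keep], ev[keep])^2
    }
  }
  names(out) <- c("dispersal", "density")
  out
}

#' Habitat geometry from land area and land fraction
#'
#' Given the land area inside a square study map and the fraction of the
#' square it covers, returns the full square's area and width.
#'
#' @param land_area Land area (km^2).
#' @param land_fraction Fraction of the square covered by land, in (0, 1].
#' @return Named vector `c(total_area = ..., width = ...)`.
#' @export
habitat_geometry <- function(land_area, land_fraction) {
  if (land_area <= 0 || land_fraction <= 0 || land_fraction > 1) {
    stop("land_area must be positive and land_fraction in (0, 1]",
         call. = FALSE)
  }
  total <- land_area / land_fraction
  c(total_area = total, width = sqrt(total))
}

#' Parametric bootstrap confidence maps
#'
#' Simulates `B` new datasets under the point-estimate map, re-estimates a
#' map from each, and reports per-cell empirical 2.5% and 97.5% quantiles
#' (linear interpolation between order statistics) plus interval width
#' relative to the point estimate. Replicates whose simulation goes extinct
#' are redrawn with a fresh seed (the count is reported).
#'
#' @param point `w x w x 2` point-estimate map on the natural scale.
#' @param estimate_fn Function `(map_array, seed) -> w x w x 2` estimate:
#'   the full simulate/sample/genotype/predict cycle under the fitted map.
#' @param B Number of bootstrap replicates (the reference analysis uses
#'   100).
#' @param level Confidence level (default 0.95).
#' @param mask Optional habitat mask; masked cells are `NA`.
#' @param seed Base seed for replicate simulations.
#' @return Object of class `bootstrap_result` with `lower`, `upper`,
#'   `relative_width` (`w x w x 2`), the replicate stack, and the number of
#'   redrawn replicates.
#' @export
parametric_bootstrap <- function(point, estimate_fn, B = 100L, level = 0.95,
                                 mask = NULL, seed = 1L) {
  w <- dim(point)[1L]
  reps <- array(NA_real_, c(B, w, w, 2L))
  redraws <- 0L
  next_seed <- seed
  for (b in seq_len(B)) {
    repeat {
      est <- tryCatch(estimate_fn(point, next_seed), error = function(e) {
        if (grepl("extinct", conditionMessage(e))) NULL else stop(e)
      })
      next_seed <- next_seed + 1L
      if (!is.null(est)) break
      redraws <- redraws + 1L
    }
    reps[b, , , ] <- est
  }
  alpha <- (1 - level) / 2
  lower <- apply(reps, c(2L, 3L, 4L), stats::quantile, probs = alpha,
                 type = 7, names = FALSE)
  upper <- apply(reps, c(2L, 3L, 4L), stats::quantile, probs = 1 - alpha,
                 type = 7, names = FALSE)
  relw <- (upper - lower) / point
  if (!is.null(mask)) {
    blank <- function(a) {
      for (ch in 1:2) {
        v <- a[, , ch]; v[!mask] <- NA_real_; a[, , ch] <- v
      }
      a
    }
    lower <- blank(lower); upper <- blank(upper); relw <- blank(relw)
  }
  structure(list(lower = lower, upper = upper, relative_width = relw,
                 replicates = reps, redraws = redraws, level = level),
            class = "bootstrap_result")
}

#' Metrics report for an estimated map
#'
#' @param true_map,est_map `w x w x 2` arrays on the natural scale.
#' @param mask Optional habitat mask.
#' @param path Optional JSON output path.
#' @return List with per-channel MRAE, r-squared, and the number of
#'   evaluated cells.
#' @export
metrics_report <- function(true_map, est_map, mask = NULL, path = NULL) {
  err <- mrae(true_map, est_map, mask)
  r2 <- map_correlation(true_map, est_map, mask)
  keep <- !is.na(true_map[, , 1L]) & !is.na(est_map[, , 1L])
  if (!is.null(mask)) keep <- keep & mask
  rep <- list(mrae_dispersal = unname(err[1L]), mrae_density = unname(err[2L]),
              r2_dispersal = unname(r2[1L]), r2_density = unname(r2[2L]),
              n_cells_evaluated = sum(keep))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  }
  rep
}
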