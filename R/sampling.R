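#' Sampling scheme for choosing individuals from a simulated population
#'
#' Three strategies: `uniform` draws individuals uniformly at random from
#' those alive (heterogeneous density then gives spatially unbalanced
#' samples), `grid` draws a fixed number per cell of a sampling grid, and
#' `fixed` draws one individual near each of a set of target coordinates
#' (radius-doubling search), mirroring an empirical sampling design.
#'
#' @param mode `"uniform"`, `"grid"`, or `"fixed"`.
#' @param n Sample size (uniform mode).
#' @param grid_size,per_cell Grid mode: `grid_size^2` cells with `per_cell`
#'   individuals each (`n = grid_size^2 * per_cell`).
#' @param target_coords Fixed mode: data frame or matrix of target `x`, `y`.
#' @param initial_radius_fraction Fixed mode: starting search radius as a
#'   fraction of the map width (default 0.02).
#' @param nearest Fixed mode: take the nearest in-radius candidate instead
#'   of a uniform draw among in-radius candidates.
#' @return Object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(mode = c("uniform", "grid", "fixed"), n = NULL,
                            grid_size = NULL, per_cell = NULL,
                            target_coords = NULL,
                            initial_radius_fraction = 0.02, nearest = FALSE) {
  mode <- match.arg(mode)
  if (mode == "uniform") stopifnot(!is.null(n), n >= 2)
  if (mode == "grid") {
    stopifnot(!is.null(grid_size), !is.null(per_cell), grid_size >= 1,
              per_cell >= 1)
    n <- grid_size^2 * per_cell
  }
  if (mode == "fixed") {
    stopifnot(!is.null(target_coords))
    target_coords <- as.data.frame(target_coords)
    n <- nrow(target_coords)
  }
  structure(list(mode = mode, n = as.integer(n), grid_size = grid_size,
                 per_cell = per_cell, target_coords = target_coords,
                 initial_radius_fraction = initial_radius_fraction,
                 nearest = nearest),
            class = "sampling_scheme")
}

#' Uniform sampling of individuals
#'
#' @param pop Data frame with columns `id`, `x`, `y`.
#' @param n Number of distinct individuals to draw.
#' @return `pop` rows for the sampled individuals.
#' @export
sample_uniform <- function(pop, n) {
  if (nrow(pop) < n) {
    stop(sprintf("population (%d) smaller than sample size (%d)",
                 nrow(pop), n), call. = FALSE)
  }
  pop[sample.int(nrow(pop), n), , drop = FALSE]
}

#' Grid-stratified sampling of individuals
#'
#' Divides the habitat `[0, w]^2` into `grid_size^2` equal cells and draws
#' `per_cell` individuals uniformly from each.
#'
#' @param pop Data frame with columns `id`, `x`, `y`.
#' @param grid_size Cells per side of the sampling grid.
#' @param per_cell Individuals per cell.
#' @param width Habitat width `w` (defaults to the extent of `pop`).
#' @return Sampled rows of `pop` (`grid_size^2 * per_cell` of them).
#' @export
sample_grid <- function(pop, grid_size, per_cell, width = ceiling(max(pop$x, pop$y))) {
  cw <- width / grid_size
  ci <- pmin(floor(pop$x / cw), grid_size - 1)
  cj <- pmin(floor(pop$y / cw), grid_size - 1)
  out <- vector("list", grid_size^2)
  k <- 0L
  for (j in seq_len(grid_size) - 1L) {
    for (i in seq_len(grid_size) - 1L) {
      inside <- which(ci == i & cj == j)
      if (length(inside) < per_cell) {
        stop(sprintf("sampling cell (%d, %d) holds %d < %d individuals",
                     i + 1L, j + 1L, length(inside), per_cell), call. = FALSE)
      }
      k <- k + 1L
      out[[k]] <- pop[sample(inside, per_cell), , drop = FALSE]
    }
  }
  do.call(rbind, out)
}

#' Sampling near fixed target locations
#'
#' For each target coordinate in input order, draws one not-yet-taken
#' individual within the current radius (uniformly among candidates, or the
#' nearest when `nearest = TRUE`); the radius starts at
#' `initial_radius_fraction * width` and doubles until a candidate is found.
#'
#' @param pop Data frame with columns `id`, `x`, `y`.
#' @param target_coords Data frame or matrix with `x`, `y` rows.
#' @param width Habitat width `w`.
#' @param initial_radius_fraction Starting radius as a fraction of `width`.
#' @param nearest Take the nearest candidate instead of a uniform draw.
#' @return Sampled rows of `pop`, one per target, all distinct, in target
#'   order.
#' @export
sample_near_locations <- function(pop, target_coords, width,
                                  initial_radius_fraction = 0.02,
                                  nearest = FALSE) {
  targets <- as.data.frame(target_coords)
  if (nrow(pop) < nrow(targets)) {
    stop("fewer individuals than target locations", call. = FALSE)
  }
  taken <- logical(nrow(pop))
  picks <- integer(nrow(targets))
  for (t in seq_len(nrow(targets))) {
    r <- initial_radius_fraction * width
    d2 <- (pop$x - targets$x[t])^2 + (pop$y - targets$y[t])^2
    repeat {
      cand <- which(!taken & d2 <= r^2)
      if (length(cand)) break
      r <- 2 * r
    }
    pick <- if (nearest) cand[which.min(d2[cand])]
            else cand[sample.int(length(cand), 1L)]
    taken[pick] <- TRUE
    picks[t] <- pick
  }
  pop[picks, , drop = FALSE]
}

#' Draw a sample according to a sampling scheme
#'
#' @param pop Data frame with columns `id`, `x`, `y`.
#' @param scheme A [sampling_scheme()].
#' @param width Habitat width `w`.
#' @return Sampled rows of `pop`.
#' @export
draw_sample <- function(pop, scheme, width) {
  switch(scheme$mode,
    uniform = sample_uniform(pop, scheme$n),
    grid = sample_grid(pop, scheme$grid_size, scheme$per_cell, width),
    fixed = sample_near_locations(pop, scheme$target_coords, width,
                                  scheme$initial_radius_fraction,
                                  scheme$nearest))
}

#' Write sample locations as CSV
#'
#' @param sample_set Data frame with `id`, `x`, `y`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_locations_csv <- function(sample_set, path) {
  utils::write.csv(data.frame(individual_id = sample_set$id,
                              x = sample_set$x, y = sample_set$y),
                   path, row.names = FALSE)
  invisible(path)
}
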