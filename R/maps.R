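#' Prior range for one demographic map channel
#'
#' A channel prior is the closed range `(p_min, p_max)` from which map values
#' for one demographic parameter are drawn. Flat maps draw a single
#' log-uniform value from this range; segmented maps draw a value range `r`
#' and a map minimum inside it (see [draw_segment_values()]).
#'
#' @param p_min,p_max Positive channel bounds, `0 < p_min < p_max`. Units are
#'   distance per generation for the dispersal channel and individuals per
#'   unit area for the density channel.
#' @param channel Either `"dispersal"` (sigma) or `"density"` (carrying
#'   capacity K).
#' @return An object of class `map_prior`.
#' @export
map_prior <- function(p_min, p_max, channel = c("dispersal", "density")) {
  channel <- match.arg(channel)
  stopifnot(is.numeric(p_min), is.numeric(p_max), length(p_min) == 1L,
            length(p_max) == 1L, p_min > 0, p_max > p_min)
  structure(list(p_min = p_min, p_max = p_max, channel = channel),
            class = "map_prior")
}

#' Benchmark channel priors
#'
#' The log-uniform ranges used throughout the benchmark configuration:
#' (0.73, 3.08) for dispersal sigma and (4, 40) for carrying capacity K.
#'
#' @return Named list with elements `dispersal` and `density`.
#' @export
benchmark_priors <- function() {
  list(dispersal = map_prior(0.73, 3.08, "dispersal"),
       density = map_prior(4, 40, "density"))
}

log_uniform <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Interpolating polynomial through boundary points
#'
#' Fits the unique polynomial of degree `length(points$x) - 1` passing through
#' the given points, used as the boundary curve between map segments.
#'
#' @param points A list or data.frame with numeric `x` and `y` of equal
#'   length (degree + 1 points). `x` values must be pairwise distinct.
#' @return Numeric coefficient vector in ascending powers
#'   (`c0 + c1*x + c2*x^2 + ...`).
#' @export
fit_boundary_polynomial <- function(points) {
  x <- points$x
  y <- points$y
  stopifnot(length(x) == length(y), length(x) >= 1L)
  if (anyDuplicated(x)) {
    stop("duplicate x-coordinates among boundary points; resample the points",
         call. = FALSE)
  }
  deg <- length(x) - 1L
  V <- outer(x, 0:deg, `^`)
  as.numeric(solve(V, y))
}

eval_polynomial <- function(coefs, x) {
  out <- numeric(length(x))
  for (k in seq_along(coefs)) out <- out + coefs[k] * x^(k - 1L)
  out
}

# 4-connected component labelling of a logical matrix; returns an integer
# matrix with labels 1..n over TRUE and FALSE cells alike (components are
# computed separately within the TRUE field and within the FALSE field).
label_components <- function(field) {
  w1 <- nrow(field); w2 <- ncol(field)
  labels <- matrix(0L, w1, w2)
  current <- 0L
  for (start in seq_along(field)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    val <- field[start]
    while (length(queue)) {
      cell <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((cell - 1L) %% w1) + 1L
      j <- ((cell - 1L) %/% w1) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1L]; jj <- j + d[2L]
        if (ii >= 1L && ii <= w1 && jj >= 1L && jj <= w2) {
          idx <- ii + (jj - 1L) * w1
          if (labels[idx] == 0L && field[idx] == val) {
            labels[idx] <- current
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  labels
}

#' Assign grid cells to map segments from a boundary curve
#'
#' Each cell of a `w` x `w` grid is first classified by whether its center
#' `(i - 0.5, j - 0.5)` falls below the curve `y = P(x)`; 4-connected
#' components of that binary field become the segments. If more than
#' `max_segments` components arise, components are ordered by size and every
#' extra component is merged into the kept component with the nearest
#' centroid.
#'
#' @param width Grid width `w` (cells per side).
#' @param curve Polynomial coefficients from [fit_boundary_polynomial()].
#' @param max_segments Maximum number of distinct segments to keep.
#' @return Integer `w` x `w` matrix of segment labels `1..n_segments`,
#'   indexed `[ix, iy]` with x along rows; label 1 is the largest segment.
#' @export
assign_segments <- function(width, curve, max_segments = 3L) {
  stopifnot(width >= 2L, max_segments >= 1L)
  centers <- seq_len(width) - 0.5
  below <- outer(eval_polynomial(curve, centers), centers, `>`) # y_c < P(x_c)
  labels <- label_components(below)
  sizes <- sort(table(labels), decreasing = TRUE)
  order_ids <- as.integer(names(sizes))
  keep <- order_ids[seq_len(min(max_segments, length(order_ids)))]
  relabel <- integer(length(order_ids))
  relabel[keep] <- seq_along(keep)
  if (length(order_ids) > length(keep)) {
    cx <- tapply(row(labels) - 0.5, labels, mean)
    cy <- tapply(col(labels) - 0.5, labels, mean)
    for (extra in setdiff(order_ids, keep)) {
      d2 <- (cx[as.character(keep)] - cx[as.character(extra)])^2 +
        (cy[as.character(keep)] - cy[as.character(extra)])^2
      relabel[extra] <- relabel[keep[which.min(d2)]]
    }
  }
  matrix(relabel[labels], width, width)
}

#' Draw values for map segments
#'
#' A flat map (one segment) receives a single log-uniform value from the
#' prior range. For segmented maps, the on-map value range `r` is drawn
#' uniformly from the prior range (resampled until `r < p_max - p_min`), the
#' map minimum `v_min` log-uniformly from `(p_min, p_max - r)`; two segments
#' receive `v_min` and `v_min + r`, and any further segments receive uniform
#' values strictly inside `(v_min, v_min + r)`. Values are returned in a
#' random assignment order.
#'
#' @param prior A [map_prior()].
#' @param n_segments Number of segments (>= 1).
#' @return Numeric vector of length `n_segments`, all within the prior range.
#' @export
draw_segment_values <- function(prior, n_segments) {
  stopifnot(inherits(prior, "map_prior"), n_segments >= 1L)
  if (n_segments == 1L) {
    return(log_uniform(1L, prior$p_min, prior$p_max))
  }
  repeat {
    r <- stats::runif(1L, prior$p_min, prior$p_max)
    if (r < prior$p_max - prior$p_min) break
  }
  v_min <- log_uniform(1L, prior$p_min, prior$p_max - r)
  vals <- c(v_min, v_min + r)
  if (n_segments > 2L) {
    vals <- c(vals, stats::runif(n_segments - 2L, v_min, v_min + r))
  }
  sample(vals)
}

#' Draw a random segmented map channel
#'
#' Draws a polynomial boundary of random degree (uniform on 0..3; degree 0
#' gives a flat map), partitions the grid into segments, and assigns segment
#' values from the prior (see [draw_segment_values()]).
#'
#' @param prior A [map_prior()].
#' @param width Grid width `w`.
#' @param max_segments Maximum number of distinct segments (default 3).
#' @param degree Optional fixed polynomial degree (0..3) instead of a random
#'   draw; mainly for testing.
#' @return A `map_channel` object: list with `width`, `values` (`w` x `w`
#'   matrix, `[ix, iy]`), `segment_labels`, the drawn `degree`, and `prior`.
#' @export
draw_channel <- function(prior, width, max_segments = 3L, degree = NULL) {
  stopifnot(width >= 2L, max_segments >= 1L)
  if (is.null(degree)) degree <- sample(0:3, 1L)
  stopifnot(degree %in% 0:3)
  if (degree == 0L || max_segments == 1L) {
    labels <- matrix(1L, width, width)
  } else {
    repeat {
      pts <- list(x = stats::runif(degree + 1L, 0, width),
                  y = stats::runif(degree + 1L, 0, width))
      if (!anyDuplicated(pts$x)) break
    }
    curve <- fit_boundary_polynomial(pts)
    labels <- assign_segments(width, curve, max_segments)
  }
  n_seg <- max(labels)
  vals <- draw_segment_values(prior, n_seg)
  structure(list(width = width,
                 values = matrix(vals[labels], width, width),
                 segment_labels = labels,
                 degree = degree,
                 prior = prior),
            class = "map_channel")
}

flat_channel <- function(prior, width, value) {
  structure(list(width = width,
                 values = matrix(value, width, width),
                 segment_labels = matrix(1L, width, width),
                 prior = prior),
            class = "map_channel")
}

#' Demographic map: stacked dispersal and density channels
#'
#' @param dispersal,density `map_channel` objects of equal width (sigma and
#'   K channels).
#' @param habitat_mask Optional logical `w` x `w` matrix; `TRUE` marks
#'   habitable cells. When present, non-habitat cells carry value zero in
#'   both channels.
#' @return Object of class `demographic_map`.
#' @export
demographic_map <- function(dispersal, density, habitat_mask = NULL) {
  stopifnot(inherits(dispersal, "map_channel"), inherits(density, "map_channel"),
            dispersal$width == density$width)
  m <- structure(list(dispersal = dispersal, density = density,
                      habitat_mask = NULL, width = dispersal$width),
                 class = "demographic_map")
  if (!is.null(habitat_mask)) m <- apply_habitat_mask(m, habitat_mask)
  m
}

#' @export
print.demographic_map <- function(x, ...) {
  cat(sprintf("demographic_map: %dx%d grid\n", x$width, x$width))
  cat(sprintf("  sigma in [%.3g, %.3g], K in [%.3g, %.3g]%s\n",
              min(x$dispersal$values[habitable(x)]),
              max(x$dispersal$values),
              min(x$density$values[habitable(x)]),
              max(x$density$values),
              if (is.null(x$habitat_mask)) "" else
                sprintf(", %.1f%% habitable", 100 * mean(x$habitat_mask))))
  invisible(x)
}

habitable <- function(map) {
  if (is.null(map$habitat_mask)) matrix(TRUE, map$width, map$width)
  else map$habitat_mask
}

#' Draw a complete random demographic map
#'
#' Dispersal and density channels are generated independently with
#' [draw_channel()]; a random dihedral (flip/rotation) element is applied
#' independently to each channel.
#'
#' @param sigma_prior,k_prior Channel priors ([map_prior()]).
#' @param width Grid width `w`.
#' @param max_segments Maximum segments per channel.
#' @param transform Apply random flips/rotations (default `TRUE`).
#' @return A `demographic_map`.
#' @export
draw_demographic_map <- function(sigma_prior, k_prior, width,
                                 max_segments = 3L, transform = TRUE) {
  ch_s <- draw_channel(sigma_prior, width, max_segments)
  ch_k <- draw_channel(k_prior, width, max_segments)
  if (transform) {
    ch_s <- transform_channel(ch_s, sample(0:7, 1L))
    ch_k <- transform_channel(ch_k, sample(0:7, 1L))
  }
  demographic_map(ch_s, ch_k)
}

# Apply dihedral element (0..7) to a matrix: elements 0..3 are rotations by
# 0/90/180/270 degrees, 4..7 the same rotations after a horizontal flip.
dihedral_matrix <- function(m, element) {
  stopifnot(element %in% 0:7)
  if (element >= 4L) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  k <- element %% 4L
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

transform_channel <- function(channel, element) {
  channel$values <- dihedral_matrix(channel$values, element)
  channel$segment_labels <- dihedral_matrix(channel$segment_labels, element)
  channel
}

#' Apply a dihedral-group transform to a demographic map
#'
#' One of the eight square symmetries (four rotations, optionally composed
#' with a flip) applied identically to both channels and the habitat mask.
#'
#' @param map A `demographic_map`.
#' @param element Integer 0..7 (0 is the identity); drawn uniformly when
#'   `NULL`.
#' @return The transformed `demographic_map`.
#' @export
apply_dihedral_transform <- function(map, element = NULL) {
  if (is.null(element)) element <- sample(0:7, 1L)
  map$dispersal <- transform_channel(map$dispersal, element)
  map$density <- transform_channel(map$density, element)
  if (!is.null(map$habitat_mask)) {
    map$habitat_mask <- dihedral_matrix(map$habitat_mask, element)
  }
  map
}

#' Viability fit relating carrying capacity to minimum stable dispersal
#'
#' Linear relation `log(sigma_min) = slope * log(K) + intercept` between the
#' local carrying capacity and the smallest dispersal rate that sustains a
#' stable population, estimated from pilot simulations (see
#' [calibrate_viability()]).
#'
#' @param slope,intercept Coefficients of the log-log linear fit.
#' @param boost Multiplier (>= 1) applied after raising offending values to
#'   the threshold; default 1.25.
#' @return Object of class `viability_fit`.
#' @export
viability_fit <- function(slope, intercept, boost = 1.25) {
  stopifnot(is.finite(slope), is.finite(intercept), boost >= 1)
  structure(list(slope = slope, intercept = intercept, boost = boost),
            class = "viability_fit")
}

#' Correct a demographic map for population viability
#'
#' Cells whose (sigma, K) combination falls below the viability threshold
#' `sigma_min = exp(slope * log(K) + intercept)` would not sustain a stable
#' population. One channel is chosen uniformly at random per map; offending
#' cells of that channel are raised to the threshold (solving the threshold
#' relation for sigma or for K) and then multiplied by the boost factor.
#'
#' @param map A `demographic_map`.
#' @param fit A [viability_fit()].
#' @param boost_noise If `TRUE`, the boost multiplier is drawn per map as
#'   `1 + Uniform(0, boost - 1)` instead of the fixed `boost`.
#' @return Corrected `demographic_map` with attribute `boosted_channel`.
#' @export
viability_correct <- function(map, fit, boost_noise = FALSE) {
  stopifnot(inherits(fit, "viability_fit"))
  boost <- if (boost_noise) 1 + stats::runif(1L, 0, fit$boost - 1) else fit$boost
  sig <- map$dispersal$values
  K <- map$density$values
  hab <- habitable(map)
  thresh <- exp(fit$slope * log(pmax(K, .Machine$double.xmin)) + fit$intercept)
  offending <- hab & (sig < thresh)
  channel <- sample(c("dispersal", "density"), 1L)
  if (any(offending)) {
    if (channel == "dispersal") {
      sig[offending] <- thresh[offending] * boost
      map$dispersal$values <- sig
    } else {
      K[offending] <- exp((log(sig[offending]) - fit$intercept) / fit$slope) * boost
      map$density$values <- K
    }
  }
  attr(map, "boosted_channel") <- channel
  map
}

#' Apply a habitat mask to a demographic map
#'
#' Out-of-habitat cells are set to zero in both channels; the mask is stored
#' so that downstream loss and error metrics exclude those cells.
#'
#' @param map A `demographic_map`.
#' @param mask Logical `w` x `w` matrix, `TRUE` = habitable. Must contain at
#'   least one habitable cell.
#' @return Masked `demographic_map`.
#' @export
apply_habitat_mask <- function(map, mask) {
  mask <- matrix(as.logical(mask), map$width, map$width)
  if (!any(mask)) stop("habitat mask has no habitable cells", call. = FALSE)
  stopifnot(nrow(mask) == map$width)
  map$dispersal$values[!mask] <- 0
  map$density$values[!mask] <- 0
  map$habitat_mask <- mask
  map
}

#' Convert a demographic map to a w x w x 2 array
#'
#' Channel 1 is dispersal (sigma), channel 2 density (K).
#' @param map A `demographic_map`.
#' @return Numeric array of dimension `c(w, w, 2)`.
#' @export
map_to_array <- function(map) {
  out <- array(0, c(map$width, map$width, 2L))
  out[, , 1L] <- map$dispersal$values
  out[, , 2L] <- map$density$values
  out
}

#' Build a demographic map from a w x w x 2 array
#'
#' Inverse of [map_to_array()]; channel priors are attached from ranges of
#' the array unless given.
#'
#' @param a Array `c(w, w, 2)`; channel 1 dispersal, channel 2 density.
#' @param mask Optional logical habitat mask.
#' @param sigma_prior,k_prior Optional [map_prior()]s to attach.
#' @return A `demographic_map`.
#' @export
array_to_map <- function(a, mask = NULL, sigma_prior = NULL, k_prior = NULL) {
  w <- dim(a)[1L]
  rng <- function(v, channel) {
    pos <- v[v > 0]
    map_prior(max(min(pos), .Machine$double.eps), max(pos) * (1 + 1e-9), channel)
  }
  if (is.null(sigma_prior)) sigma_prior <- rng(a[, , 1L], "dispersal")
  if (is.null(k_prior)) k_prior <- rng(a[, , 2L], "density")
  ch <- function(vals, prior) {
    structure(list(width = w, values = matrix(vals, w, w),
                   segment_labels = matrix(1L, w, w), prior = prior),
              class = "map_channel")
  }
  demographic_map(ch(a[, , 1L], sigma_prior), ch(a[, , 2L], k_prior),
                  habitat_mask = mask)
}
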