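#' Write one map channel as a CSV grid
#'
#' The dialect is `w` rows of `w` comma-separated decimals, row-major with
#' the northern (largest y) row first. A sidecar JSON
#' (`<path>.json`) records `w`, the prior range, the channel name, and an
#' optional seed.
#'
#' @param channel A `map_channel`.
#' @param path Output CSV path.
#' @param seed Optional integer recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(channel, path, seed = NULL) {
  w <- channel$width
  rows <- vapply(rev(seq_len(w)), function(iy) {
    paste(format(channel$values[, iy], trim = TRUE, scientific = FALSE,
                 digits = 15L),
          collapse = ",")
  }, character(1L))
  writeLines(rows, path)
  meta <- list(w = w, p_min = channel$prior$p_min, p_max = channel$prior$p_max,
               channel = channel$prior$channel, seed = seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read a map channel written by [write_map_csv()]
#'
#' @param path CSV path; the `<path>.json` sidecar must exist.
#' @return A `map_channel`.
#' @export
read_map_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  w <- length(rows)
  stopifnot(w == meta$w, all(lengths(rows) == w))
  values <- matrix(0, w, w)
  for (i in seq_len(w)) values[, w - i + 1L] <- as.numeric(rows[[i]])
  structure(list(width = w, values = values,
                 segment_labels = matrix(NA_integer_, w, w),
                 prior = map_prior(meta$p_min, meta$p_max, meta$channel)),
            class = "map_channel")
}

#' Write both channels of a demographic map
#'
#' Writes `<prefix>_dispersal.csv`, `<prefix>_density.csv` (plus JSON
#' sidecars) and, when a habitat mask is present, `<prefix>_mask.csv` of
#' 0/1 values in the same orientation.
#'
#' @param map A `demographic_map`.
#' @param prefix Output path prefix.
#' @param seed Optional seed recorded in the sidecars.
#' @return `prefix`, invisibly.
#' @export
write_demographic_map <- function(map, prefix, seed = NULL) {
  write_map_csv(map$dispersal, paste0(prefix, "_dispersal.csv"), seed)
  write_map_csv(map$density, paste0(prefix, "_density.csv"), seed)
  if (!is.null(map$habitat_mask)) {
    w <- map$width
    rows <- vapply(rev(seq_len(w)), function(iy) {
      paste(as.integer(map$habitat_mask[, iy]), collapse = ",")
    }, character(1L))
    writeLines(rows, paste0(prefix, "_mask.csv"))
  }
  invisible(prefix)
}

#' Read a demographic map written by [write_demographic_map()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `demographic_map`.
#' @export
read_demographic_map <- function(prefix) {
  disp <- read_map_csv(paste0(prefix, "_dispersal.csv"))
  dens <- read_map_csv(paste0(prefix, "_density.csv"))
  mask_path <- paste0(prefix, "_mask.csv")
  mask <- NULL
  if (file.exists(mask_path)) {
    rows <- strsplit(readLines(mask_path), ",", fixed = TRUE)
    w <- length(rows)
    mask <- matrix(FALSE, w, w)
    for (i in seq_len(w)) mask[, w - i + 1L] <- as.numeric(rows[[i]]) > 0
  }
  demographic_map(disp, dens, habitat_mask = mask)
}

#' Read a habitat mask from CSV or PNG
#'
#' CSV masks follow the grid dialect (0/1, northern row first); PNG masks are
#' 8-bit single-channel images where nonzero marks habitat.
#'
#' @param path Path to a `.csv` or `.png` mask of width `w`.
#' @return Logical `w` x `w` matrix (`[ix, iy]`, y increasing northward).
#' @export
read_habitat_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    w <- ncol(img)
    stopifnot(nrow(img) == w)
    mask <- matrix(FALSE, w, w)
    for (i in seq_len(w)) mask[, w - i + 1L] <- img[i, ] > 0
    return(mask)
  }
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  w <- length(rows)
  mask <- matrix(FALSE, w, w)
  for (i in seq_len(w)) mask[, w - i + 1L] <- as.numeric(rows[[i]]) > 0
  mask
}

#' Render a demographic map as an 8-bit PNG
#'
#' Red channel encodes carrying capacity and blue channel dispersal rate,
#' each scaled linearly over its channel's prior range; non-habitat cells
#' are black.
#'
#' @param map A `demographic_map`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_map_png <- function(map, path) {
  w <- map$width
  scale01 <- function(v, prior) {
    pmin(pmax((v - prior$p_min) / (prior$p_max - prior$p_min), 0), 1)
  }
  img <- array(0, c(w, w, 3L))
  red <- scale01(map$density$values, map$density$prior)
  blue <- scale01(map$dispersal$values, map$dispersal$prior)
  hab <- habitable(map)
  red[!hab] <- 0; blue[!hab] <- 0
  for (iy in seq_len(w)) {
    img[w - iy + 1L, , 1L] <- red[, iy]
    img[w - iy + 1L, , 3L] <- blue[, iy]
  }
  png::writePNG(img, path)
  invisible(path)
}
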