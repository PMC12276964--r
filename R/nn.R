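# Two-branch network mapping pairwise genotypes + locations to a w x w x 2
# demographic map. Implemented directly on BLAS matrix ops with hand-written
# backpropagation; tensors for k pairs are kept as (k, length, channels)
# arrays and convolutions run as im2col matrix products.

#' Model architecture configuration
#'
#' Defaults follow the reference architecture: repeated 1-D convolution
#' (kernel 7) and average-pooling (10) blocks along the SNP axis until the
#' sequence length is at most `min_len`, a flattening dense layer to
#' `features` genotype summaries per pair, a two-layer dense locations
#' branch ending in ReLU spatial scores (one score per genotype feature),
#' and a combiner that weights pair features by spatial scores, sums over
#' pairs, and maps through a dense stack to the two output channels.
#'
#' @param features Number of genotype summaries per pair (F, default 128).
#' @param conv_kernel Convolution kernel width along the SNP axis.
#' @param conv_channels Channel counts for successive conv blocks (the last
#'   entry repeats if more blocks are needed).
#' @param pool Average-pooling width.
#' @param min_len Stop adding conv/pool blocks once the length is <= this.
#' @param loc_hidden Hidden width of the locations branch.
#' @param comb_hidden Width H of the combiner weights `W` (F x H).
#' @param f_hidden Hidden width of the final dense stack `f`.
#' @param phased Expect 4 haplotype channels per pair instead of 2.
#' @param score_bias_init Initial bias of the final score layer; a positive
#'   value keeps all ReLU spatial scores active at initialization, zero (the
#'   default) initializes biases to zero like every other layer.
#' @return Object of class `model_config`.
#' @export
model_config <- function(features = 128L, conv_kernel = 7L,
                         conv_channels = c(32L, 64L), pool = 10L,
                         min_len = 64L, loc_hidden = 128L,
                         comb_hidden = 128L, f_hidden = 128L,
                         phased = FALSE, score_bias_init = 0) {
  structure(as.list(environment()), class = "model_config")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build a map-estimation model
#'
#' Parameter shapes depend only on the SNP count `m` (through the genotype
#' branch) and the architecture config - not on the number of pairs or the
#' map width, which enter only as tensor sizes at run time.
#'
#' @param m Number of SNPs each dataset carries.
#' @param config A [model_config()].
#' @return Object of class `map_model`: list with `params` (named list of
#'   weight matrices), `layers` (conv/pool plan), and `config`.
#' @export
build_model <- function(m, config = model_config()) {
  in_ch <- if (config$phased) 4L else 2L
  if (m < config$conv_kernel) {
    stop(sprintf("SNP count %d below the minimum the conv stack supports (%d)",
                 m, config$conv_kernel), call. = FALSE)
  }
  layers <- list()
  L <- m
  ch_prev <- in_ch
  i <- 0L
  repeat {
    i <- i + 1L
    ch <- config$conv_channels[min(i, length(config$conv_channels))]
    layers[[length(layers) + 1L]] <-
      list(type = "conv", kernel = config$conv_kernel, in_ch = ch_prev,
           out_ch = ch)
    L <- L - config$conv_kernel + 1L
    ch_prev <- ch
    if (L %/% config$pool >= 1L && L > config$min_len) {
      layers[[length(layers) + 1L]] <- list(type = "pool", p = config$pool)
      L <- L %/% config$pool
    }
    if (L <= config$min_len) break
  }
  flat_dim <- L * ch_prev
  params <- list()
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    if (ly$type == "conv") {
      params[[paste0("conv", li, "_w")]] <- glorot(ly$kernel * ly$in_ch, ly$out_ch)
      params[[paste0("conv", li, "_b")]] <- numeric(ly$out_ch)
    }
  }
  params$geno_w <- glorot(flat_dim, config$features)
  params$geno_b <- numeric(config$features)
  params$loc1_w <- glorot(7L, config$loc_hidden)
  params$loc1_b <- numeric(config$loc_hidden)
  params$loc2_w <- glorot(config$loc_hidden, config$features)
  params$loc2_b <- rep(as.numeric(config$score_bias_init), config$features)
  params$comb_w <- glorot(config$features, config$comb_hidden)
  params$comb_b <- numeric(config$comb_hidden)
  params$f1_w <- glorot(config$comb_hidden, config$f_hidden)
  params$f1_b <- numeric(config$f_hidden)
  # damped output layer: initial predictions start near the (standardized)
  # target mean, which conditions the early epochs
  params$f2_w <- glorot(config$f_hidden, 2L) * 0.1
  params$f2_b <- numeric(2L)
  structure(list(params = params, layers = layers, m = as.integer(m),
                 flat_dim = flat_dim, config = config),
            class = "map_model")
}

#' @export
print.map_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("map_model: %d SNPs, %d features/pair, %d parameters\n",
              x$m, x$config$features, np))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `map_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

# ---- tensor helpers -------------------------------------------------------

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

relu <- function(Z) {
  Z[Z < 0] <- 0
  Z
}

conv_im2col <- function(A, kernel) {
  d <- dim(A)
  k <- d[1L]; L <- d[2L]; C <- d[3L]
  Lout <- L - kernel + 1L
  M <- matrix(0, k * Lout, kernel * C)
  col <- 0L
  for (c in seq_len(C)) {
    for (t in seq_len(kernel)) {
      col <- col + 1L
      M[, col] <- A[, t:(t + Lout - 1L), c]
    }
  }
  M
}

conv_col2im <- function(dM, kernel, d, Lout) {
  k <- d[1L]; C <- d[3L]
  dA <- array(0, d)
  col <- 0L
  for (c in seq_len(C)) {
    for (t in seq_len(kernel)) {
      col <- col + 1L
      dA[, t:(t + Lout - 1L), c] <- dA[, t:(t + Lout - 1L), c] +
        matrix(dM[, col], k, Lout)
    }
  }
  dA
}

pool_fwd <- function(A, p) {
  d <- dim(A)
  Lp <- d[2L] %/% p
  B <- A[, seq_len(Lp * p), , drop = FALSE]
  dim(B) <- c(d[1L], p, Lp, d[3L])
  out <- array(0, c(d[1L], Lp, d[3L]))
  for (q in seq_len(p)) {
    sl <- B[, q, , , drop = FALSE]
    dim(sl) <- c(d[1L], Lp, d[3L])
    out <- out + sl
  }
  out / p
}

pool_bwd <- function(dOut, p, d_in) {
  d <- dim(dOut)
  Lp <- d[2L]
  dB <- array(0, c(d[1L], p, Lp, d[3L]))
  for (q in seq_len(p)) dB[, q, , ] <- dOut / p
  dim(dB) <- c(d[1L], p * Lp, d[3L])
  dA <- array(0, d_in)
  dA[, seq_len(p * Lp), ] <- dB
  dA
}

# ---- genotype branch ------------------------------------------------------

geno_forward <- function(model, X, M1 = NULL) {
  # X: (k, m, C) pair tensor; M1 optionally precomputes im2col of layer 1
  cache <- list(acts = list(), pre = list())
  A <- X
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    cache$acts[[li]] <- A
    if (ly$type == "conv") {
      M <- if (li == 1L && !is.null(M1)) M1 else conv_im2col(A, ly$kernel)
      Z <- add_bias(M %*% model$params[[paste0("conv", li, "_w")]],
                    model$params[[paste0("conv", li, "_b")]])
      cache$pre[[li]] <- list(M = M, Z = Z,
                              Lout = dim(A)[2L] - ly$kernel + 1L)
      A <- relu(Z)
      dim(A) <- c(dim(X)[1L], cache$pre[[li]]$Lout, ly$out_ch)
    } else {
      A <- pool_fwd(A, ly$p)
    }
  }
  k <- dim(X)[1L]
  flat <- A
  dim(flat) <- c(k, model$flat_dim)
  G <- add_bias(flat %*% model$params$geno_w, model$params$geno_b)
  cache$flat <- flat
  cache$final_dim <- dim(A)
  list(G = G, cache = cache)
}

geno_backward <- function(model, X, cache, dG) {
  grads <- list()
  grads$geno_w <- crossprod(cache$flat, dG)
  grads$geno_b <- colSums(dG)
  dA <- dG %*% t(model$params$geno_w)
  dim(dA) <- cache$final_dim
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    A_in <- cache$acts[[li]]
    if (ly$type == "conv") {
      pr <- cache$pre[[li]]
      dZ <- dA
      dim(dZ) <- c(nrow(pr$Z), ncol(pr$Z))
      dZ <- dZ * (pr$Z > 0)
      grads[[paste0("conv", li, "_w")]] <- crossprod(pr$M, dZ)
      grads[[paste0("conv", li, "_b")]] <- colSums(dZ)
      if (li == 1L) break # input gradient is never needed
      dM <- dZ %*% t(model$params[[paste0("conv", li, "_w")]])
      dA <- conv_col2im(dM, ly$kernel, dim(A_in), pr$Lout)
    } else {
      dA <- pool_bwd(dA, ly$p, dim(A_in))
    }
  }
  grads
}

# ---- locations branch -----------------------------------------------------

#' Locations table for the spatial-score branch
#'
#' One row per combination of grid cell and pair (cell-major, then pair),
#' seven columns: cell center x and y, the two individuals' coordinates,
#' and the map width. All coordinates are divided by `w`; the width itself
#' is passed through as a raw feature.
#'
#' @param w Map width (cells per side).
#' @param pair_locs Matrix (k x 4) of `x1, y1, x2, y2` sample coordinates
#'   per pair, in habitat units.
#' @return Numeric matrix (`w^2 * k` x 7).
#' @export
build_locations_table <- function(w, pair_locs) {
  k <- nrow(pair_locs)
  ix <- (seq_len(w * w) - 1L) %% w + 1L
  iy <- (seq_len(w * w) - 1L) %/% w + 1L
  centers <- cbind(ix - 0.5, iy - 0.5)
  tab <- cbind(centers[rep(seq_len(w * w), each = k), , drop = FALSE] / w,
               pair_locs[rep(seq_len(k), w * w), , drop = FALSE] / w,
               w)
  dimnames(tab) <- NULL
  tab
}

loc_forward <- function(model, tab) {
  Z1 <- add_bias(tab %*% model$params$loc1_w, model$params$loc1_b)
  H1 <- relu(Z1)
  Z2 <- add_bias(H1 %*% model$params$loc2_w, model$params$loc2_b)
  S <- relu(Z2)
  list(S = S, cache = list(tab = tab, Z1 = Z1, H1 = H1, Z2 = Z2))
}

loc_backward <- function(model, cache, dS) {
  dZ2 <- dS * (cache$Z2 > 0)
  grads <- list(loc2_w = crossprod(cache$H1, dZ2), loc2_b = colSums(dZ2))
  dH1 <- dZ2 %*% t(model$params$loc2_w)
  dZ1 <- dH1 * (cache$Z1 > 0)
  grads$loc1_w <- crossprod(cache$tab, dZ1)
  grads$loc1_b <- colSums(dZ1)
  grads
}

# ---- combiner (batched over all cells) ------------------------------------

combiner_forward <- function(model, G, S, w) {
  k <- nrow(G)
  Grep <- G[rep(seq_len(k), w * w), , drop = FALSE]
  TE <- S * Grep
  Z <- add_bias(TE %*% model$params$comb_w, model$params$comb_b)
  U <- relu(Z)
  cells <- rep(seq_len(w * w), each = k)
  # pair aggregation normalized by k so activations are invariant to the
  # pair-subset size (a constant rescaling of f's first layer)
  Csum <- rowsum(U, cells, reorder = FALSE) / k
  dimnames(Csum) <- NULL
  Zf1 <- add_bias(Csum %*% model$params$f1_w, model$params$f1_b)
  Hf1 <- relu(Zf1)
  Y <- add_bias(Hf1 %*% model$params$f2_w, model$params$f2_b)
  list(Y = Y,
       cache = list(G = G, S = S, Grep = Grep, TE = TE, Z = Z, U = U,
                    Csum = Csum, Zf1 = Zf1, Hf1 = Hf1, k = k, w = w))
}

combiner_backward <- function(model, cache, dY) {
  k <- cache$k; w <- cache$w
  grads <- list(f2_w = crossprod(cache$Hf1, dY), f2_b = colSums(dY))
  dHf1 <- dY %*% t(model$params$f2_w)
  dZf1 <- dHf1 * (cache$Zf1 > 0)
  grads$f1_w <- crossprod(cache$Csum, dZf1)
  grads$f1_b <- colSums(dZf1)
  dCsum <- dZf1 %*% t(model$params$f1_w)
  dU <- dCsum[rep(seq_len(w * w), each = k), , drop = FALSE] / k
  dZ <- dU * (cache$Z > 0)
  grads$comb_w <- crossprod(cache$TE, dZ)
  grads$comb_b <- colSums(dZ)
  dTE <- dZ %*% t(model$params$comb_w)
  dS <- dTE * cache$Grep
  dGrep <- dTE * cache$S
  dG <- rowsum(dGrep, rep(seq_len(k), w * w), reorder = FALSE)
  list(grads = grads, dS = dS, dG = dG)
}

#' Reference per-cell combiner (naive loops)
#'
#' Literal implementation of the per-cell combination
#' `y_i = f( sum_j ReLU( (G * S_i) W + b )_j )` with explicit loops over
#' cells and pairs, used as the oracle the batched implementation must
#' reproduce.
#'
#' @param model A `map_model`.
#' @param G Pair-feature matrix (k x F).
#' @param S Spatial scores (`w^2 * k` x F), cell-major then pair.
#' @param w Map width.
#' @return Matrix (`w^2` x 2) of per-cell outputs.
#' @export
combine_reference <- function(model, G, S, w) {
  p <- model$params
  k <- nrow(G)
  Y <- matrix(0, w * w, 2L)
  for (i in seq_len(w * w)) {
    Si <- S[(i - 1L) * k + seq_len(k), , drop = FALSE]
    acc <- numeric(ncol(p$comb_w))
    for (j in seq_len(k)) {
      zj <- (G[j, ] * Si[j, ]) %*% p$comb_w + p$comb_b
      acc <- acc + pmax(zj, 0)
    }
    acc <- acc / k
    h <- pmax(acc %*% p$f1_w + p$f1_b, 0)
    Y[i, ] <- h %*% p$f2_w + p$f2_b
  }
  Y
}

# ---- pair handling --------------------------------------------------------

#' Draw a random pair subset
#'
#' Samples `k_init` unordered pairs of distinct individuals without
#' replacement and flags a random `k_extract` of them as gradient-active in
#' the genotype branch (the rest still contribute to the forward pass but
#' are masked from branch-one optimization).
#'
#' @param n Number of individuals.
#' @param k_init Number of pairs entering the forward pass.
#' @param k_extract Number of gradient-active pairs (`<= k_init`).
#' @return List with `pairs` (k_init x 2 index matrix, each row sorted) and
#'   `active` (logical k_init).
#' @export
enumerate_pairs <- function(n, k_init, k_extract = k_init) {
  total <- n * (n - 1) / 2
  if (k_init > total) {
    stop(sprintf("k_init = %d exceeds the %d available pairs", k_init, total),
         call. = FALSE)
  }
  stopifnot(k_extract >= 1, k_extract <= k_init)
  idx <- sample.int(total, k_init)
  # unrank unordered pairs (i < j) from linear index, column-by-column
  j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  i <- idx - (j - 1) * (j - 2) / 2
  # guard against floating-point edge cases of the inverse triangular root
  over <- i < 1
  j[over] <- j[over] - 1L
  i[over] <- idx[over] - (j[over] - 1) * (j[over] - 2) / 2
  under <- i > j - 1
  j[under] <- j[under] + 1L
  i[under] <- idx[under] - (j[under] - 1) * (j[under] - 2) / 2
  pairs <- cbind(as.integer(i), as.integer(j))
  active <- logical(k_init)
  active[sample.int(k_init, k_extract)] <- TRUE
  list(pairs = pairs, active = active)
}

pair_tensor <- function(genotypes, pairs, phased = FALSE) {
  k <- nrow(pairs)
  if (phased) {
    m <- ncol(genotypes)
    X <- array(0, c(k, m, 4L))
    for (c in 1:2) {
      rows <- 2L * (pairs[, c] - 1L)
      X[, , 2L * c - 1L] <- genotypes[rows + 1L, , drop = FALSE]
      X[, , 2L * c] <- genotypes[rows + 2L, , drop = FALSE]
    }
  } else {
    X <- array(0, c(k, ncol(genotypes), 2L))
    X[, , 1L] <- genotypes[pairs[, 1L], , drop = FALSE]
    X[, , 2L] <- genotypes[pairs[, 2L], , drop = FALSE]
  }
  X
}

# ---- full forward / backward ----------------------------------------------

model_forward <- function(model, X, tab, w, want_cache = FALSE, M1 = NULL) {
  gf <- geno_forward(model, X, M1 = M1)
  lf <- loc_forward(model, tab)
  cf <- combiner_forward(model, gf$G, lf$S, w)
  out <- list(Y = cf$Y)
  if (want_cache) out$cache <- list(geno = gf$cache, loc = lf$cache,
                                    comb = cf$cache, X = X)
  out
}

model_backward <- function(model, cache, dY, active = NULL) {
  cb <- combiner_backward(model, cache$comb, dY)
  grads <- cb$grads
  lg <- loc_backward(model, cache$loc, cb$dS)
  grads[names(lg)] <- lg
  dG <- cb$dG
  if (!is.null(active)) dG[!active, ] <- 0 # stop-gradient on masked pairs
  gg <- geno_backward(model, cache$X, cache$geno, dG)
  grads[names(gg)] <- gg
  grads
}

#' Predict a demographic map (preprocessed scale)
#'
#' Full forward pass over both branches and the combiner for one genotype
#' dataset, using a random subset of pairs.
#'
#' @param model A `map_model`.
#' @param dataset A `genotype_dataset`.
#' @param width Map width `w`.
#' @param k_init,k_extract Pair-subset sizes (see [enumerate_pairs()]).
#' @param pairs Optional pre-drawn pair set (overrides `k_init`).
#' @return `w` x `w` x 2 array on the preprocessed (transformed) scale.
#' @export
predict_map <- function(model, dataset, width, k_init = 100L,
                        k_extract = k_init, pairs = NULL) {
  n <- length(dataset$individual_ids)
  if (ncol(dataset$genotypes) != model$m) {
    stop(sprintf("dataset has %d SNPs but the model was built for %d",
                 ncol(dataset$genotypes), model$m), call. = FALSE)
  }
  if (is.null(pairs)) pairs <- enumerate_pairs(n, min(k_init, n * (n - 1) / 2),
                                               min(k_extract, k_init))
  X <- pair_tensor(dataset$genotypes, pairs$pairs, model$config$phased)
  locs <- as.matrix(dataset$locations[, c("x", "y")])
  pl <- cbind(locs[pairs$pairs[, 1L], , drop = FALSE],
              locs[pairs$pairs[, 2L], , drop = FALSE])
  tab <- build_locations_table(width, pl)
  Y <- model_forward(model, X, tab, width)$Y
  array(Y, c(width, width, 2L))
}
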