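# Shared fixtures, built in code.

flat_map <- function(w = 10L, sigma = 1.5, K = 8,
                     sigma_range = c(0.73, 3.08), k_range = c(4, 40)) {
  demographic_map(
    demomap:::flat_channel(map_prior(sigma_range[1], sigma_range[2]), w, sigma),
    demomap:::flat_channel(map_prior(k_range[1], k_range[2], "density"), w, K))
}

tiny_model_config <- function(features = 6L) {
  model_config(features = features, conv_channels = c(4L), pool = 3L,
               min_len = 5L, loc_hidden = 8L, comb_hidden = 7L, f_hidden = 9L)
}

fake_genotype_dataset <- function(n = 8L, m = 30L, w = 5L) {
  structure(list(
    genotypes = matrix(sample(0:2, n * m, replace = TRUE), n, m),
    positions = sort(stats::runif(m, 0, 1e6)),
    locations = data.frame(id = seq_len(n) - 1L,
                           x = stats::runif(n, 0, w),
                           y = stats::runif(n, 0, w)),
    individual_ids = seq_len(n) - 1L,
    phased = FALSE), class = "genotype_dataset")
}

uniform_population <- function(n, w) {
  data.frame(id = seq_len(n) - 1L, x = stats::runif(n, 0, w),
             y = stats::runif(n, 0, w))
}

# one small forward simulation with ancestry, shared across genotype tests
shared_sim_env <- new.env(parent = emptyenv())
shared_ancestry_sim <- function() {
  if (is.null(shared_sim_env$sim)) {
    set.seed(4242)
    map <- flat_map(w = 6L, sigma = 1.2, K = 7)
    shared_sim_env$sim <- run_simulation(
      map, sim_params(n_cycles = 60L, burn_in = 20L, genome_length = 1e7,
                      recomb_rate = 1e-8),
      record_ancestry = TRUE, record_realized = FALSE)
  }
  shared_sim_env$sim
}

# independent 4-connected component labelling (breadth-first), used as the
# oracle for assign_segments
flood_fill_components <- function(field) {
  w1 <- nrow(field); w2 <- ncol(field)
  lab <- matrix(0L, w1, w2)
  cur <- 0L
  for (j in seq_len(w2)) for (i in seq_len(w1)) {
    if (lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      c0 <- queue[[1L]]; queue <- queue[-1L]
      for (d in list(c(-1L,0L), c(1L,0L), c(0L,-1L), c(0L,1L))) {
        ii <- c0[1L] + d[1L]; jj <- c0[2L] + d[2L]
        if (ii >= 1L && ii <= w1 && jj >= 1L && jj <= w2 &&
            lab[ii, jj] == 0L && field[ii, jj] == field[i, j]) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}
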