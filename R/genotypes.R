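#' Recapitation configuration
#'
#' Backward-time epochs for the randomly mating coalescent that completes
#' the forward-simulated genealogies. The default (no epochs) uses a single
#' epoch with Ne equal to the final-cycle census size.
#'
#' @param epochs `NULL`, or a data frame with columns `ne` (> 0) and `start`
#'   (generations before sampling, first row must start at 0, rows ordered
#'   backward in time).
#' @param recomb_rate Recombination rate used during recapitation (per bp per
#'   generation).
#' @return Object of class `recap_config`.
#' @export
recap_config <- function(epochs = NULL, recomb_rate = 1e-8) {
  if (!is.null(epochs)) {
    stopifnot(is.data.frame(epochs), all(c("ne", "start") %in% names(epochs)),
              all(epochs$ne > 0), epochs$start[1] == 0,
              !is.unsorted(epochs$start))
  }
  structure(list(epochs = epochs, recomb_rate = recomb_rate),
            class = "recap_config")
}

#' Genotype synthesis configuration
#'
#' @param m_target Exact number of SNPs to emit (>= 1).
#' @param phased Emit per-haplotype 0/1 rows instead of diploid 0/1/2 counts.
#' @param mu_start Starting mutation rate for the doubling schedule
#'   (default 1e-15); the rate is doubled until at least `m_target` sites
#'   segregate in the sample, then sites are uniformly downsampled.
#' @return Object of class `genotype_config`.
#' @export
genotype_config <- function(m_target, phased = FALSE, mu_start = 1e-15) {
  stopifnot(m_target >= 1, mu_start > 0)
  structure(list(m_target = as.integer(m_target), phased = phased,
                 mu_start = mu_start),
            class = "genotype_config")
}

find_python <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("python with msprime/tskit is required for genotype synthesis",
         call. = FALSE)
  }
  py
}

bridge_script <- function() {
  path <- system.file("python", "genotype_bridge.py", package = "demomap")
  if (!nzchar(path)) stop("genotype bridge script not found", call. = FALSE)
  path
}

write_ancestry_inputs <- function(sim, dir) {
  anc <- sim$ancestry
  if (is.null(anc)) {
    stop("simulation was run without ancestry recording", call. = FALSE)
  }
  paths <- list(
    birth_cycle = file.path(dir, "birth_cycle.csv"),
    edges = file.path(dir, "edges.csv"),
    final = file.path(dir, "final.csv"))
  writeLines(as.character(anc$birth_cycle), paths$birth_cycle)
  data.table_write <- function(df, path) {
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  data.table_write(anc$edges, paths$edges)
  data.table_write(sim$population, paths$final)
  c(paths, list(n_cycles = anc$n_cycles, genome_length = anc$genome_length))
}

run_bridge <- function(job) {
  job_path <- tempfile(fileext = ".json")
  jsonlite::write_json(job, job_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  out <- suppressWarnings(system2(find_python(), c(bridge_script(), job_path),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("genotype bridge failed:\n", paste(out, collapse = "\n"),
         call. = FALSE)
  }
  invisible(out)
}

read_genotype_output <- function(prefix, sample_ids, sim, phased) {
  g <- as.matrix(utils::read.csv(paste0(prefix, "_genotypes.csv"),
                                 header = FALSE))
  dimnames(g) <- NULL
  pos <- as.numeric(readLines(paste0(prefix, "_positions.csv")))
  loc <- sim$population[match(sample_ids, sim$population$id), c("id", "x", "y")]
  rec <- recode_minor_allele(g, phased = phased)
  structure(list(genotypes = rec$counts, positions = pos,
                 flipped = rec$flipped, locations = loc,
                 individual_ids = sample_ids, phased = phased),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals x %d SNPs (%s)\n",
              length(x$individual_ids), ncol(x$genotypes),
              if (x$phased) "phased" else "diploid counts"))
  invisible(x)
}

#' Recode a genotype matrix to minor-allele counts
#'
#' Columns whose counted-allele frequency exceeds 0.5 are flipped so that
#' every stored column counts the minor allele. At a frequency of exactly
#' 0.5 the allele whose label orders first is counted; with the synthetic
#' ancestral/derived labels ("0" < "1") that is the ancestral allele.
#'
#' @param g Genotype matrix of derived-allele counts: n x m of 0/1/2
#'   (diploid) or 2n x m of 0/1 (phased).
#' @param phased Whether rows are haplotypes.
#' @return List with `counts` (recoded matrix) and `flipped` (logical per
#'   column).
#' @export
recode_minor_allele <- function(g, phased = FALSE) {
  ploidy_max <- if (phased) 1 else 2
  freq <- colMeans(g) / ploidy_max
  # input counts the derived ("1") allele; on a tie the lexicographically
  # first label ("0", ancestral) is counted, which also means flipping
  flip <- freq >= 0.5
  g[, flip] <- ploidy_max - g[, flip, drop = FALSE]
  list(counts = g, flipped = flip)
}

#' Complete forward ancestry with a randomly mating coalescent
#'
#' Simplifies the recorded ancestry to the requested individuals and
#' completes all uncoalesced roots with a coalescent-with-recombination
#' model ("recapitation"), so that every marginal tree has a single root.
#' The completed genealogy is stored as a tree-sequence file referenced by
#' the returned handle.
#'
#' @param sim A `sim_result` run with `record_ancestry = TRUE`.
#' @param individuals Individual ids (from `sim$population$id`) the
#'   genealogy must cover; defaults to the whole final population.
#' @param config A [recap_config()].
#' @param seed Integer seed for the coalescent.
#' @param dir Directory for the tree-sequence file (default a tempdir).
#' @return Object of class `recap_result` with the trees path, the covered
#'   individuals, the number of roots before completion, and the census size.
#' @export
recapitate <- function(sim, individuals = sim$population$id,
                       config = recap_config(), seed = 1L,
                       dir = tempfile("recap")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tin <- write_ancestry_inputs(sim, dir)
  trees <- file.path(dir, "recap.trees")
  job <- list(mode = "recap_only",
              tables = list(birth_cycle = tin$birth_cycle, edges = tin$edges,
                            final = tin$final, n_cycles = tin$n_cycles,
                            genome_length = tin$genome_length),
              recomb_rate = config$recomb_rate,
              epochs = epochs_payload(config),
              recap_seed = as.integer(seed),
              sample_sets = list(list(individuals = I(individuals))),
              trees_out = trees)
  run_bridge(job)
  info <- jsonlite::read_json(paste0(trees, ".json"), simplifyVector = TRUE)
  structure(list(trees = trees, union_individuals = info$union_individuals,
                 roots_before = info$roots_before, census = info$census,
                 sim = sim),
            class = "recap_result")
}

epochs_payload <- function(config) {
  if (is.null(config$epochs)) return(NULL)
  lapply(seq_len(nrow(config$epochs)), function(i) {
    list(ne = config$epochs$ne[i], start = config$epochs$start[i])
  })
}

#' Overlay mutations to an exact SNP count
#'
#' Adds neutral mutations to a completed genealogy under an infinite-sites
#' model, doubling the cumulative mutation rate from `mu_start` until at
#' least `m_target` sites segregate among the requested samples, then
#' uniformly downsampling to exactly `m_target` sites. Columns are recoded
#' to minor-allele counts.
#'
#' @param recap A `recap_result` from [recapitate()].
#' @param individuals Individual ids to genotype (must be covered by the
#'   recapitation).
#' @param config A [genotype_config()].
#' @param seed Integer seed for the mutation overlay and downsampling.
#' @return A `genotype_dataset`: minor-allele count matrix (`n x m` or
#'   `2n x m` phased), site positions, sample locations, and ids.
#' @export
overlay_snps <- function(recap, individuals, config, seed = 1L) {
  stopifnot(inherits(recap, "recap_result"), inherits(config, "genotype_config"))
  missing_ids <- setdiff(individuals, recap$union_individuals)
  if (length(missing_ids)) {
    stop("individuals not covered by the recapitation: ",
         paste(utils::head(missing_ids), collapse = ", "), call. = FALSE)
  }
  prefix <- tempfile("geno")
  job <- list(mode = "mutate", trees_in = recap$trees,
              union_individuals = I(recap$union_individuals),
              mu_start = config$mu_start, phased = config$phased,
              sample_sets = list(list(individuals = I(individuals),
                                      m_target = config$m_target,
                                      seed = as.integer(seed),
                                      out = prefix)))
  run_bridge(job)
  read_genotype_output(prefix, individuals, recap$sim, config$phased)
}

#' Synthesize genotype datasets for several sample sets in one pass
#'
#' Convenience pipeline: simplifies the ancestry to the union of all sample
#' sets, recapitates once, and overlays an independent mutation schedule per
#' sample set. One external process serves all sets, which is considerably
#' faster than repeated [recapitate()]/[overlay_snps()] calls.
#'
#' @param sim A `sim_result` with ancestry.
#' @param sample_sets List of individual-id vectors.
#' @param config A [genotype_config()].
#' @param recap A [recap_config()].
#' @param seed Integer seed; per-set seeds are derived from it.
#' @param m_targets Optional vector of per-set SNP counts overriding
#'   `config$m_target`.
#' @return List of `genotype_dataset` objects, one per sample set.
#' @export
synthesize_genotypes <- function(sim, sample_sets, config,
                                 recap = recap_config(), seed = 1L,
                                 m_targets = NULL) {
  dir <- tempfile("synth")
  dir.create(dir, recursive = TRUE)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  if (is.null(m_targets)) m_targets <- rep(config$m_target, length(sample_sets))
  stopifnot(length(m_targets) == length(sample_sets))
  tin <- write_ancestry_inputs(sim, dir)
  sets <- lapply(seq_along(sample_sets), function(k) {
    list(individuals = I(sample_sets[[k]]), m_target = as.integer(m_targets[k]),
         seed = as.integer(seed) + k, out = file.path(dir, paste0("set", k)))
  })
  job <- list(mode = "genotypes",
              tables = list(birth_cycle = tin$birth_cycle, edges = tin$edges,
                            final = tin$final, n_cycles = tin$n_cycles,
                            genome_length = tin$genome_length),
              recomb_rate = recap$recomb_rate,
              epochs = epochs_payload(recap),
              recap_seed = as.integer(seed),
              mu_start = config$mu_start, phased = config$phased,
              sample_sets = sets)
  run_bridge(job)
  lapply(seq_along(sample_sets), function(k) {
    read_genotype_output(file.path(dir, paste0("set", k)), sample_sets[[k]],
                         sim, config$phased)
  })
}

#' Write a genotype dataset as VCF 4.2 plus a locations CSV
#'
#' Sites are written as biallelic SNPs with the counted (minor) allele as
#' ALT, so the stored counts round-trip exactly through [read_vcf()].
#' Continuous site positions are discretized to distinct integer positions.
#'
#' @param dataset A `genotype_dataset` (diploid mode).
#' @param path Output VCF path; `<path>.locations.csv` is written alongside.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dataset, path) {
  stopifnot(inherits(dataset, "genotype_dataset"), !dataset$phased)
  g <- dataset$genotypes
  n <- nrow(g); m <- ncol(g)
  pos <- floor(sort(dataset$positions))
  if (length(pos) != m) pos <- seq_len(m) * 10
  pos <- pos + seq_len(m) # de-collide while keeping order
  ids <- paste0("ind", dataset$individual_ids)
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=demomap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(m), function(j) {
    paste(c("1", format(pos[j], scientific = FALSE), ".", "C", "A", ".",
            "PASS", ".", "GT", gt_code[g[, j] + 1L]), collapse = "\t")
  }, character(1L))
  writeLines(c(lines, body), path)
  utils::write.csv(
    data.frame(individual_id = ids, x = dataset$locations$x,
               y = dataset$locations$y),
    paste0(path, ".locations.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a VCF of biallelic SNPs with a locations table
#'
#' Drops indels, non-biallelic records, and sites with any missing genotype
#' (counts are reported via a message); remaining columns are recoded to
#' minor-allele counts. Sample names must match the locations table exactly.
#'
#' @param path VCF path.
#' @param locations_csv CSV with columns `individual_id`, `x`, `y`; default
#'   `<path>.locations.csv`.
#' @return A `genotype_dataset`.
#' @export
read_vcf <- function(path, locations_csv = paste0(path, ".locations.csv")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  has_missing <- apply(gt, 1L, function(r) any(is.na(r) | grepl("\\.", r)))
  keep <- is_snp & !has_missing
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("dropped %d site(s): %d non-biallelic/indel, %d with missing calls",
                    dropped, sum(!is_snp), sum(has_missing & is_snp)))
  }
  if (!any(keep)) stop("no usable biallelic complete sites in VCF", call. = FALSE)
  gt <- gt[keep, , drop = FALSE]
  loc <- utils::read.csv(locations_csv, stringsAsFactors = FALSE)
  samples <- colnames(gt)
  bad <- c(setdiff(samples, loc$individual_id), setdiff(loc$individual_id, samples))
  if (length(bad)) {
    stop("sample names mismatch between VCF and locations table: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  loc <- loc[match(samples, loc$individual_id), ]
  counts <- apply(gt, c(1L, 2L), function(s) {
    sum(as.integer(strsplit(s, "[/|]")[[1L]]))
  })
  counts <- t(counts) # n x m
  dimnames(counts) <- NULL
  # minor-allele recode with lexicographic tie-break on the allele letters
  ref <- ref[keep]; alt <- alt[keep]
  freq <- colMeans(counts) / 2
  flip <- freq > 0.5 | (freq == 0.5 & ref < alt)
  counts[, flip] <- 2L - counts[, flip, drop = FALSE]
  pos <- as.numeric(fix[keep, "POS"])
  structure(list(genotypes = counts, positions = pos, flipped = flip,
                 locations = data.frame(id = samples, x = loc$x, y = loc$y),
                 individual_ids = samples, phased = FALSE),
            class = "genotype_dataset")
}
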