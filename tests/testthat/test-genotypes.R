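# These tests exercise the coalescent completion and mutation overlay, which
# run through the bundled msprime/tskit bridge.

test_that("recapitation closes every genealogy and overlay hits the SNP count", {
  sim <- shared_ancestry_sim()
  set.seed(1)
  ids <- sample_uniform(sim$population, 10L)$id
  rec <- recapitate(sim, individuals = ids, seed = 3L)
  expect_s3_class(rec, "recap_result")
  expect_gt(rec$roots_before, 1) # forward forest really was incomplete
  for (m_target in c(17L, 120L)) {
    ds <- overlay_snps(rec, ids, genotype_config(m_target), seed = m_target)
    expect_equal(ncol(ds$genotypes), m_target)
    expect_equal(nrow(ds$genotypes), 10L)
    expect_true(all(ds$genotypes %in% 0:2))
    # every column is polymorphic and codes the minor allele
    cs <- colSums(ds$genotypes)
    expect_true(all(cs > 0))
    expect_true(all(colMeans(ds$genotypes) / 2 <= 0.5))
    # positions are distinct and inside the genome
    expect_false(anyDuplicated(ds$positions) > 0)
    expect_true(all(ds$positions >= 0 & ds$positions <= 1e7))
  }
  expect_error(overlay_snps(rec, c(ids, 999999L), genotype_config(10L)),
               "not covered")
})

test_that("exact SNP counts hold across seeds and targets", {
  sim <- shared_ancestry_sim()
  set.seed(2)
  sets <- replicate(10, sample_uniform(sim$population, 8L)$id,
                    simplify = FALSE)
  targets <- sample(10:400, 10)
  cfg_sets <- lapply(seq_along(sets), function(i) sets[[i]])
  for (i in seq_along(sets)) {
    ds <- synthesize_genotypes(sim, cfg_sets[i],
                               genotype_config(targets[i]),
                               seed = 100L + i)[[1L]]
    expect_equal(ncol(ds$genotypes), targets[i])
  }
})

test_that("minor-allele recoding flips majority columns and breaks ties to the first label", {
  g <- rbind(c(2, 2, 1), c(2, 1, 1), c(1, 2, 0), c(1, 2, 0), c(0, 0, 0))
  # derived frequencies: 0.6, 0.7, 0.2
  rec <- recode_minor_allele(g)
  expect_equal(rec$flipped, c(TRUE, TRUE, FALSE))
  expect_equal(rec$counts[, 1], 2 - g[, 1])
  expect_equal(rec$counts[, 3], g[, 3])
  expect_true(all(colMeans(rec$counts) / 2 <= 0.5))
  # exactly 0.5: the lexicographically first (ancestral "0") label is counted
  tie <- matrix(c(2, 2, 1, 1, 0, 0), ncol = 1)
  rec2 <- recode_minor_allele(tie)
  expect_true(rec2$flipped[1])
  expect_equal(rec2$counts[, 1], 2 - tie[, 1])
  # a 60-of-200 derived column is already minor and is left alone
  col <- matrix(c(rep(2, 10), rep(1, 40), rep(0, 50)), ncol = 1)
  expect_false(recode_minor_allele(col)$flipped[1])
})

test_that("recapitation coalescence times follow the configured Ne", {
  # a single sampled diploid leaves two lineages; under a randomly mating
  # coalescent their extra coalescence time is exponential with mean 2 Ne
  set.seed(3)
  map <- flat_map(w = 5L, sigma = 1.2, K = 6)
  sim <- run_simulation(map, sim_params(n_cycles = 20L, burn_in = 5L,
                                        genome_length = 1e4,
                                        recomb_rate = 0),
                        record_ancestry = TRUE, record_realized = FALSE)
  ids <- sample_uniform(sim$population, 1L)$id
  dir <- tempfile("coal"); dir.create(dir)
  tin <- demomap:::write_ancestry_inputs(sim, dir)
  out <- file.path(dir, "times.csv")
  ne <- 50
  job <- list(mode = "coal_times",
              tables = list(birth_cycle = tin$birth_cycle, edges = tin$edges,
                            final = tin$final, n_cycles = tin$n_cycles,
                            genome_length = tin$genome_length),
              recomb_rate = 0,
              epochs = list(list(ne = ne, start = 0)),
              recap_seed = 11L, reps = 400L,
              union_individuals = I(ids), out = out)
  demomap:::run_bridge(job)
  times <- as.numeric(readLines(out))
  extra <- times - tin$n_cycles
  # memorylessness: conditional on reaching recapitation, mean extra = 2 Ne
  expect_equal(mean(extra[extra > 0]), 2 * ne, tolerance = 0.2)
})

test_that("retained sites are a uniform subsample of the genome", {
  sim <- shared_ancestry_sim()
  set.seed(4)
  ids <- sample_uniform(sim$population, 10L)$id
  ds <- synthesize_genotypes(sim, list(ids), genotype_config(400L),
                             seed = 9L)[[1L]]
  deciles <- cut(ds$positions / 1e7, breaks = seq(0, 1, 0.1))
  expect_gt(stats::chisq.test(table(deciles))$p.value, 0.001)
})

test_that("VCF output round-trips exactly and filters bad records on read", {
  skip_if_not_installed("vcfR")
  sim <- shared_ancestry_sim()
  set.seed(5)
  ids <- sample_uniform(sim$population, 10L)$id
  ds <- synthesize_genotypes(sim, list(ids), genotype_config(50L),
                             seed = 21L)[[1L]]
  path <- file.path(tempdir(), "roundtrip.vcf")
  write_vcf(ds, path)
  back <- read_vcf(path)
  expect_equal(unname(back$genotypes), unname(ds$genotypes))
  expect_equal(back$locations$x, ds$locations$x)

  # hand-crafted VCF: one good site, one triallelic, one with a missing call,
  # one indel
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    paste(c("1", "100", ".", "A", "T", ".", "PASS", ".", "GT", "0/1", "1/1"),
          collapse = "\t"),
    paste(c("1", "200", ".", "A", "T,G", ".", "PASS", ".", "GT", "0/1", "0/2"),
          collapse = "\t"),
    paste(c("1", "300", ".", "A", "T", ".", "PASS", ".", "GT", "./.", "0/1"),
          collapse = "\t"),
    paste(c("1", "400", ".", "AC", "A", ".", "PASS", ".", "GT", "0/1", "0/0"),
          collapse = "\t"))
  crafted <- file.path(tempdir(), "crafted.vcf")
  writeLines(vcf_lines, crafted)
  loc <- file.path(tempdir(), "crafted.csv")
  utils::write.csv(data.frame(individual_id = c("s1", "s2"), x = 1:2, y = 3:4),
                   loc, row.names = FALSE)
  expect_message(got <- read_vcf(crafted, loc), "dropped 3")
  expect_equal(ncol(got$genotypes), 1L)
  expect_equal(got$positions, 100)
  # minor-allele recode of the kept column: ALT dosage (1,2) flips to (1,0)
  expect_equal(as.vector(got$genotypes), c(1L, 0L))

  # mismatched sample names fail loudly
  bad_loc <- file.path(tempdir(), "bad.csv")
  utils::write.csv(data.frame(individual_id = c("s1", "sX"), x = 1:2, y = 3:4),
                   bad_loc, row.names = FALSE)
  expect_error(read_vcf(crafted, bad_loc), "mismatch")

  # a VCF with no usable sites is an error
  none <- file.path(tempdir(), "none.vcf")
  writeLines(vcf_lines[-4], none)
  expect_error(suppressMessages(read_vcf(none, loc)), "no usable")
})
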