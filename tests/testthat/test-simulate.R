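test_that("count simulation is deterministic under a fixed seed", {
  cfg <- sim_count_config(n_samples = 40, n_genera = 30, seed = 7)
  expect_identical(simulate_counts(cfg), simulate_counts(cfg))
  cfg2 <- sim_count_config(n_samples = 40, n_genera = 30, seed = 8)
  expect_false(identical(simulate_counts(cfg)$counts,
                         simulate_counts(cfg2)$counts))
})

test_that("all-zero genus blocks are constructed exactly", {
  cfg <- sim_count_config(n_samples = 20, n_genera = 10,
                          zero_genus_fraction = 1, seed = 1)
  expect_true(all(simulate_counts(cfg)$counts == 0))

  cfg <- sim_count_config(n_samples = 100, n_genera = 200,
                          zero_genus_fraction = 0.3,
                          rare_genus_fraction = 0, seed = 3)
  s <- simulate_counts(cfg)
  expect_equal(sum(colSums(s$counts) == 0), 60)
})

test_that("invalid count configs name the offending field", {
  expect_error(sim_count_config(n_samples = 0), "n_samples")
  expect_error(sim_count_config(dispersion = 0), "dispersion")
  expect_error(sim_count_config(zero_genus_fraction = 1.2),
               "zero_genus_fraction")
  expect_error(sim_count_config(zero_genus_fraction = 0.7,
                                rare_genus_fraction = 0.5),
               "rare_genus_fraction")
})

test_that("rare genera respect the designed prevalence cap", {
  cfg <- sim_count_config(n_samples = 300, n_genera = 50,
                          zero_genus_fraction = 0.2,
                          rare_genus_fraction = 0.4,
                          rare_max_prevalence = 20, seed = 5)
  s <- simulate_counts(cfg)
  rare_cols <- 11:30  # layout: zero block, then rare block
  prev <- colSums(s$counts[, rare_cols] > 0)
  expect_true(all(prev < 20))
  expect_true(all(prev > 0))  # designed to be present, just sparse
})

test_that("without class or batch effects, class means differ only by noise", {
  cfg <- sim_count_config(n_samples = 400, n_genera = 30, n_classes = 2,
                          n_batches = 1, class_effect_genera = 0,
                          zero_genus_fraction = 0, rare_genus_fraction = 0,
                          library_size_class_spread = 0, seed = 42)
  s <- simulate_counts(cfg)
  cl <- s$metadata$class
  pvals <- apply(s$counts, 2, function(x) {
    stats::wilcox.test(x[cl == "C1"], x[cl == "C2"], exact = FALSE)$p.value
  })
  # nominal behaviour: rejection rate at 0.05 close to 0.05
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_gt(min(pvals), 1e-5)
})

test_that("genome simulation injects verbatim host contigs with coordinates", {
  cfg <- sim_genome_config(host_length = 10000, n_bacteria = 4,
                           bacterial_length = 3000,
                           contaminated_fraction = 1, contig_length = 500,
                           seed = 2)
  g <- simulate_genomes(cfg)
  expect_identical(simulate_genomes(cfg), g)
  expect_equal(nrow(g$contamination), 4)
  for (i in seq_len(4)) {
    ann <- g$contamination[i, ]
    contig <- substr(g$bacteria[[ann$genome_id]], ann$start + 1, ann$end)
    expect_equal(nchar(contig), 500)
    # verbatim substring of the host at the recorded donor coordinate
    expect_identical(contig, substr(g$host, ann$donor_start + 1,
                                    ann$donor_start + 500))
    expect_true(grepl(contig, g$host, fixed = TRUE))
  }
})

test_that("clean genomes share no 31-mers with the host", {
  cfg <- sim_genome_config(host_length = 2000, n_bacteria = 3,
                           bacterial_length = 1000,
                           contaminated_fraction = 0, contig_length = 100,
                           seed = 9)
  g <- simulate_genomes(cfg)
  expect_equal(nrow(g$contamination), 0)
  host_k <- canonical_kmers(g$host, 31)
  for (b in g$bacteria) {
    expect_length(intersect(host_k, canonical_kmers(b, 31)), 0)
  }
})

test_that("genome config rejects contigs longer than their targets", {
  expect_error(sim_genome_config(host_length = 100, contig_length = 200),
               "contig_length")
  expect_error(sim_genome_config(bacterial_length = 400,
                                 contig_length = 500), "contig_length")
})

test_that("error-free reads are exact substrings with recorded sources", {
  genomes <- c(host = strrep("ACGTTGCA", 300),
               bactA = paste(rep(c("GGA", "TTC", "CAG"), 250),
                             collapse = ""))
  reads <- simulate_reads(genomes, n_reads = 200, read_length = 50,
                          source_mix = c(host = 1), error_rate = 0,
                          seed = 3)
  expect_identical(simulate_reads(genomes, 200, 50, c(host = 1), 0, 3),
                   reads)
  expect_true(all(reads$true_source == "host"))
  expect_true(all(vapply(reads$sequence, grepl, logical(1),
                         x = genomes[["host"]], fixed = TRUE)))
  expect_false(anyDuplicated(reads$read_id) > 0)
})

test_that("source mixing follows the configured weights", {
  cfg <- sim_genome_config(host_length = 5000, n_bacteria = 1,
                           bacterial_length = 5000,
                           contaminated_fraction = 0, contig_length = 100,
                           seed = 1)
  g <- simulate_genomes(cfg)
  genomes <- c(host = g$host, g$bacteria)
  reads <- simulate_reads(genomes, n_reads = 10000, read_length = 60,
                          source_mix = c(host = 0.9, bact1 = 0.1),
                          seed = 17)
  frac <- mean(reads$true_source == "host")
  tol <- 3 * sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(frac - 0.9), tol)
  expect_error(simulate_reads(genomes, 10, 60, c(), seed = 1),
               "source_mix")
  expect_error(simulate_reads(genomes, 10, 9999, c(host = 1), seed = 1),
               "read_length")
})

test_that("substitution errors hit roughly the configured rate", {
  genome <- c(src = strrep("A", 2000))
  reads <- simulate_reads(genome, n_reads = 500, read_length = 100,
                          source_mix = c(src = 1), error_rate = 0.05,
                          seed = 4)
  mismatches <- sum(vapply(reads$sequence, function(s) {
    sum(strsplit(s, "")[[1]] != "A")
  }, numeric(1)))
  rate <- mismatches / (500 * 100)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 50000))
})
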