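chain_tax <- function() {
  build_taxonomy(data.frame(child = c("A", "B"), parent = c("root", "A")))
}

star_tax <- function() {
  build_taxonomy(data.frame(child = c("A", "B", "C"), parent = "root"))
}

test_that("taxonomy construction validates structure and answers LCA queries", {
  tx <- chain_tax()
  expect_equal(taxonomy_lca(tx, c("A", "B")), "A")
  expect_equal(path_to_root(tx, "B"), c("B", "A", "root"))

  tx <- star_tax()
  expect_equal(taxonomy_lca(tx, c("A", "B")), "root")
  expect_setequal(taxonomy_leaves(tx), c("A", "B", "C"))

  expect_error(build_taxonomy(data.frame(child = c("A", "A"),
                                         parent = c("r", "s"))),
               "more than one parent")
  expect_error(build_taxonomy(data.frame(child = c("A", "B"),
                                         parent = c("r1", "r2"))),
               "exactly one root")
  expect_error(build_taxonomy(data.frame(child = c("A", "B", "C"),
                                         parent = c("B", "C", "A"))),
               "root")
})

test_that("LCA matches the ancestor-set oracle on a random 50-node tree", {
  tx <- build_taxonomy(random_tree_edges(50, seed = 77))
  set.seed(78)
  for (rep in 1:40) {
    pair <- sample(tx$nodes, 2)
    expect_equal(taxonomy_lca(tx, pair),
                 oracle_lca(tx$parent, tx$depth, pair))
  }
})

test_that("k-mer canonicalization is strand independent", {
  s <- "ACGTACGTACGTACGTACGTACGTACGTACGTA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_setequal(canonical_kmers(s, 31), canonical_kmers(rc, 31))
  # N breaks windows
  with_n <- paste0(substr(s, 1, 10), "N", substr(s, 12, 33))
  expect_lt(length(canonical_kmers(with_n, 31)),
            length(canonical_kmers(s, 31)))
})

test_that("database construction counts and aggregates k-mers correctly", {
  tx <- star_tax()
  taxa <- c(gA = "A", gB = "B")

  one <- c(gA = strrep("ACGT", 8))  # length 32
  db <- build_kmer_db(one[1], taxa, tx, k = 31)
  expect_equal(nrow(db$entries), 1)  # both windows share a canonical form

  withr::with_seed(3, g100 <- c(gA = paste(
    sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")))
  db <- build_kmer_db(g100, taxa, tx, k = 31)
  expect_lte(nrow(db$entries), 70)   # L - k + 1, fewer if repeated
  expect_equal(nrow(db$entries), length(unique(canonical_kmers(g100[[1]],
                                                               31))))

  # a k-mer present in two sibling taxa maps to their parent
  shared <- strrep("AC", 20)
  genomes <- c(gA = paste0(shared, "GGGGGGGGGG"),
               gB = paste0("TTTTTTTTTT", shared))
  db <- build_kmer_db(genomes, taxa, tx, k = 31)
  shared_kmers <- intersect(canonical_kmers(genomes[["gA"]], 31),
                            canonical_kmers(genomes[["gB"]], 31))
  expect_gt(length(shared_kmers), 0)
  hit <- db$entries[db$entries$kmer %in% shared_kmers, ]
  expect_true(all(hit$taxon == "root"))

  expect_warning(build_kmer_db(c(gA = "ACGT", gB = genomes[["gB"]]),
                               taxa, tx, k = 31), "shorter than k")
})

test_that("single reads classify by path scoring with LCA tie-breaks", {
  tx <- star_tax()
  taxa <- c(gA = "A", gB = "B", gC = "C")
  withr::with_seed(11, {
    genomes <- vapply(1:3, function(i) paste(
      sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = ""),
      character(1))
  })
  names(genomes) <- c("gA", "gB", "gC")
  db <- build_kmer_db(genomes, taxa, tx, k = 31)

  read_a <- substr(genomes[["gA"]], 50, 110)
  expect_equal(classify_read(read_a, db, tx), "A")
  expect_true(is.na(classify_read(strrep("A", 40), db, tx)))
  expect_true(is.na(classify_read("ACGT", db, tx)))  # shorter than k

  # reverse-complement invariance
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read_a)))
  expect_equal(classify_read(rc, db, tx), "A")

  # hand-built tie: 5 k-mer hits to each of two sibling leaves
  seg_a <- substr(genomes[["gA"]], 1, 35)   # 5 windows
  seg_b <- substr(genomes[["gB"]], 1, 35)
  tie_read <- paste0(seg_a, seg_b)
  hits_a <- sum(canonical_kmers(tie_read, 31) %in%
                  canonical_kmers(genomes[["gA"]], 31))
  hits_b <- sum(canonical_kmers(tie_read, 31) %in%
                  canonical_kmers(genomes[["gB"]], 31))
  if (hits_a == hits_b) {
    expect_equal(classify_read(tie_read, db, tx), "root")
  }
})

test_that("set classification agrees with per-read classification", {
  tx <- build_taxonomy(data.frame(
    child = c("strep", "wadd", "s1", "s2"),
    parent = c("root", "root", "strep", "strep")))
  taxa <- c(g1 = "s1", g2 = "s2", g3 = "wadd")
  withr::with_seed(21, {
    genomes <- vapply(1:3, function(i) paste(
      sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""),
      character(1))
  })
  names(genomes) <- names(taxa)
  db <- build_kmer_db(genomes, taxa, tx, k = 31)
  expect_lte(nrow(db$entries), 1000)

  reads <- simulate_reads(genomes, n_reads = 150, read_length = 45,
                          source_mix = c(g1 = 1, g2 = 1, g3 = 1),
                          error_rate = 0.02, seed = 22)
  res <- classify_set(reads, db, tx)
  expect_equal(res$n_reads, 150)
  expect_equal(sum(res$taxon_counts$reads) + res$n_unclassified, 150)

  for (i in seq_len(nrow(reads))) {
    expect_identical(res$assignments$taxon[i],
                     classify_read(reads$sequence[i], db, tx))
  }
  # and against the naive path-enumeration oracle
  for (i in seq_len(50)) {
    expect_identical(res$assignments$taxon[i],
                     oracle_classify(reads$sequence[i], db, tx))
  }

  empty <- classify_set(reads[0, ], db, tx)
  expect_equal(sum(empty$taxon_counts$reads), 0)
  expect_equal(empty$n_unclassified, 0)

  pure <- simulate_reads(genomes["g1"], n_reads = 100, read_length = 45,
                         source_mix = c(g1 = 1), seed = 23)
  res_pure <- classify_set(pure, db, tx)
  expect_equal(res_pure$taxon_counts$reads[
    res_pure$taxon_counts$taxon == "s1"], 100)
})

test_that("adding a genome only moves k-mer entries rootward", {
  tx <- star_tax()
  taxa <- c(gA = "A", gB = "B")
  withr::with_seed(31, {
    base <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  })
  contaminated <- paste0(substr(base, 1, 100), strrep("ACGGT", 40))
  db1 <- build_kmer_db(c(gA = base), taxa, tx, k = 31)
  db2 <- build_kmer_db(c(gA = base, gB = contaminated), taxa, tx, k = 31)
  merged <- merge(as.data.frame(db1$entries), as.data.frame(db2$entries),
                  by = "kmer")
  depth <- tx$depth
  expect_true(all(depth[merged$taxon.y] <= depth[merged$taxon.x]))
})

test_that("contamination drives false positives that vanish with the host genome", {
  cfg <- sim_genome_config(host_length = 20000, n_bacteria = 4,
                           bacterial_length = 8000,
                           contaminated_fraction = 0.5,
                           contig_length = 300, seed = 41)
  gen <- simulate_genomes(cfg)
  reads <- simulate_reads(c(host = gen$host, gen$bacteria),
                          n_reads = 8000, read_length = 67,
                          source_mix = c(host = 1), error_rate = 0,
                          seed = 42)
  exp_ <- contamination_experiment(gen$host, gen$bacteria, reads)

  contaminated <- gen$contamination$genome_id
  clean <- setdiff(names(gen$bacteria), contaminated)
  fp <- exp_$without_host$fp_by_taxon
  expect_true(all(fp$false_positives[fp$taxon %in% contaminated] > 0))
  expect_true(all(fp$false_positives[fp$taxon %in% clean] == 0))
  expect_lt(exp_$with_host$fp_total, exp_$without_host$fp_total)

  # with the host present, host-only reads go to the host taxon
  asg <- exp_$with_host$result$assignments
  host_like <- asg$taxon[!is.na(asg$taxon)]
  expect_true(all(host_like %in% c("host", "root")))

  # no contamination, no errors: zero false positives in both arms
  cfg0 <- sim_genome_config(host_length = 5000, n_bacteria = 2,
                            bacterial_length = 3000,
                            contaminated_fraction = 0,
                            contig_length = 100, seed = 43)
  gen0 <- simulate_genomes(cfg0)
  reads0 <- simulate_reads(c(host = gen0$host, gen0$bacteria),
                           n_reads = 2000, read_length = 67,
                           source_mix = c(host = 1), seed = 44)
  exp0 <- contamination_experiment(gen0$host, gen0$bacteria, reads0)
  expect_equal(exp0$without_host$fp_total, 0)
  expect_equal(exp0$with_host$fp_total, 0)
  expect_true(exp0$infinite)
})
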