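#' Canonical k-mers of a sequence
#'
#' Returns the canonical form (lexicographic minimum of the k-mer and its
#' reverse complement) of every k-mer window of `seq`, in order. Windows
#' containing characters outside A/C/G/T (e.g. N) are skipped.
#'
#' @param seq A single DNA sequence string.
#' @param k K-mer length.
#' @return Character vector of canonical k-mers (possibly empty).
#' @export
canonical_kmers <- function(seq, k = 31L) {
  check_scalar(k, "k", 1, integerish = TRUE)
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  fwd <- substring(seq, starts, starts + k - 1L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rc_aligned <- rev(substring(rc, starts, starts + k - 1L))
  can <- pmin(fwd, rc_aligned)
  if (grepl("[^ACGT]", seq)) {
    can <- can[!grepl("[^ACGT]", fwd)]
  }
  can
}

# canonical k-mer table for a set of reads: data.table(read_id, kmer)
read_kmer_table <- function(reads, k) {
  lens <- nchar(reads$sequence)
  keep <- which(lens >= k)
  if (length(keep) == 0) {
    return(data.table::data.table(read_id = character(0),
                                  kmer = character(0)))
  }
  parts <- lapply(split(keep, lens[keep]), function(idx) {
    L <- nchar(reads$sequence[idx[1]])
    nk <- L - k + 1L
    seqs <- reads$sequence[idx]
    fwd <- substring(rep(seqs, each = nk),
                     rep(seq_len(nk), length(idx)),
                     rep(seq_len(nk) + k - 1L, length(idx)))
    rcs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
    rc_al <- substring(rep(rcs, each = nk),
                       rep(rev(seq_len(nk)), length(idx)),
                       rep(rev(seq_len(nk)) + k - 1L, length(idx)))
    dt <- data.table::data.table(
      read_id = rep(reads$read_id[idx], each = nk),
      kmer = pmin(fwd, rc_al),
      valid = !grepl("[^ACGT]", fwd)
    )
    dt[valid == TRUE, .(read_id, kmer)]
  })
  data.table::rbindlist(parts)
}

#' Build an exact k-mer LCA database
#'
#' Maps every canonical k-mer occurring in the input genomes to the lowest
#' common ancestor of the taxa of all genomes containing it - the index
#' structure of exact-match k-mer classifiers.
#'
#' @param genomes Named character vector of genome sequences.
#' @param genome_taxa Named character vector mapping genome name to taxon
#'   identifier (taxa must exist in `taxonomy`).
#' @param taxonomy A `taxonomy` from [build_taxonomy()].
#' @param k K-mer length (default 31).
#' @return A list of class `kmer_db` with `k`, `entries` (data.table
#'   `kmer` -> `taxon`, keyed by kmer), `genome_taxa`, and `skipped`
#'   (names of genomes shorter than `k`, skipped with a warning).
#' @export
build_kmer_db <- function(genomes, genome_taxa, taxonomy, k = 31L) {
  stopifnot(inherits(taxonomy, "taxonomy"),
            all(names(genomes) %in% names(genome_taxa)))
  taxa_used <- genome_taxa[names(genomes)]
  stopifnot(all(taxa_used %in% taxonomy$nodes))

  short <- names(genomes)[nchar(genomes) < k]
  if (length(short) > 0) {
    warning("skipping genome(s) shorter than k: ",
            paste(short, collapse = ", "), call. = FALSE)
  }
  use <- setdiff(names(genomes), short)
  pieces <- lapply(use, function(g) {
    data.table::data.table(kmer = unique(canonical_kmers(genomes[[g]], k)),
                           taxon = genome_taxa[[g]])
  })
  dt <- unique(data.table::rbindlist(pieces))
  # LCA aggregation; the (usually few) k-mers shared across taxa are the
  # only ones needing an LCA walk
  n_tax <- dt[, .N, by = kmer]
  shared <- n_tax[N > 1L, kmer]
  entries <- dt[!kmer %in% shared]
  if (length(shared) > 0) {
    lca_part <- dt[kmer %in% shared,
                   .(taxon = taxonomy_lca(taxonomy, taxon)), by = kmer]
    entries <- rbind(entries, lca_part)
  }
  data.table::setkey(entries, kmer)
  structure(list(k = as.integer(k), entries = entries,
                 genome_taxa = genome_taxa, skipped = short),
            class = "kmer_db")
}

# Kraken-style scoring: weight each root-to-leaf path by the total hits on
# its nodes; assign the deepest node of the maximal path, resolving ties by
# the LCA of the tied paths' deepest nodes.
score_hit_taxa <- function(hit_counts, taxonomy) {
  if (length(hit_counts) == 0 || sum(hit_counts) == 0) {
    return(NA_character_)
  }
  leaves <- taxonomy_leaves(taxonomy)
  w <- vapply(leaves, function(lf) {
    sum(hit_counts[intersect(names(hit_counts), path_to_root(taxonomy, lf))])
  }, numeric(1))
  top <- leaves[w == max(w)]
  if (length(top) == 1L) top else taxonomy_lca(taxonomy, top)
}

#' Classify a single read against a k-mer database
#'
#' Counts database hits of the read's canonical k-mers per taxon and
#' applies root-to-leaf path scoring. Reads shorter than `k` or with no
#' database hits are unclassified (`NA`).
#'
#' @param read A single sequence string.
#' @param db A `kmer_db`.
#' @param taxonomy A `taxonomy`.
#' @return Assigned taxon identifier, or `NA_character_` if unclassified.
#' @export
classify_read <- function(read, db, taxonomy) {
  kmers <- canonical_kmers(read, db$k)
  if (length(kmers) == 0) return(NA_character_)
  hit <- db$entries[data.table::data.table(kmer = kmers), nomatch = NULL,
                    on = "kmer"]
  if (nrow(hit) == 0) return(NA_character_)
  counts <- table(hit$taxon)
  score_hit_taxa(stats::setNames(as.numeric(counts), names(counts)),
                 taxonomy)
}

#' Classify a set of reads
#'
#' Vectorized aggregation of [classify_read()]: per-read assignments,
#' per-taxon read counts, and exact per-taxon distinct-k-mer counts (the
#' number of distinct database k-mers of each taxon observed across the
#' read set, as a uniqueness-aware classifier would tally).
#'
#' @param reads A `read_set` (or data.frame with `read_id`, `sequence`).
#' @param db A `kmer_db`.
#' @param taxonomy A `taxonomy`.
#' @param kmer_table Optional precomputed result of the internal read
#'   k-mer extraction, to avoid recomputation when classifying the same
#'   reads against several databases.
#' @return A list of class `classification_result`: `assignments`
#'   (data.frame `read_id`, `taxon`; `NA` = unclassified), `taxon_counts`
#'   (data.frame `taxon`, `reads`, `distinct_kmers`), `n_unclassified`,
#'   `n_reads`.
#' @export
classify_set <- function(reads, db, taxonomy, kmer_table = NULL) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  kt <- kmer_table %||% read_kmer_table(reads, db$k)
  hits <- db$entries[kt, nomatch = NULL, on = "kmer"]

  assigned <- stats::setNames(rep(NA_character_, nrow(reads)),
                              reads$read_id)
  if (nrow(hits) > 0) {
    per_rt <- hits[, .N, by = .(read_id, taxon)]
    data.table::setorder(per_rt, read_id, taxon)
    sig_dt <- per_rt[, .(sig = paste0(taxon, "=", N, collapse = ";"),
                         taxa = list(stats::setNames(as.numeric(N), taxon))),
                     by = read_id]
    usig <- sig_dt[!duplicated(sig)]
    usig[, call := vapply(taxa, score_hit_taxa, character(1),
                          taxonomy = taxonomy)]
    assigned[sig_dt$read_id] <-
      usig$call[match(sig_dt$sig, usig$sig)]
  }

  dk <- if (nrow(hits) > 0) {
    hits[, .(distinct_kmers = data.table::uniqueN(kmer)), by = taxon]
  } else {
    data.table::data.table(taxon = character(0), distinct_kmers = integer(0))
  }
  rc <- table(factor(assigned, levels = taxonomy$nodes))
  taxon_counts <- data.frame(taxon = names(rc), reads = as.integer(rc),
                             stringsAsFactors = FALSE)
  taxon_counts$distinct_kmers <-
    dk$distinct_kmers[match(taxon_counts$taxon, dk$taxon)]
  taxon_counts$distinct_kmers[is.na(taxon_counts$distinct_kmers)] <- 0L

  structure(
    list(assignments = data.frame(read_id = reads$read_id,
                                  taxon = unname(assigned[reads$read_id]),
                                  stringsAsFactors = FALSE),
         taxon_counts = taxon_counts,
         n_unclassified = sum(is.na(assigned)),
         n_reads = nrow(reads)),
    class = "classification_result"
  )
}

#' Host-contamination classification experiment
#'
#' Classifies a read set twice - against a database built from the
#' bacterial genomes only, and against the same database plus the host
#' genome - and tallies false positives: reads whose true source is the
#' host but which were assigned to a bacterial taxon. With contaminated
#' draft genomes in the database and no host genome, host reads overlapping
#' the injected contigs are misassigned to bacteria; adding the host genome
#' moves the shared k-mers to the host/bacterium LCA and collapses the
#' false-positive counts.
#'
#' @param host Host genome sequence.
#' @param bacteria Named character vector of bacterial genome sequences.
#' @param reads A `read_set` with `true_source` ground truth.
#' @param k K-mer length (default 31).
#' @return A list of class `contamination_experiment` with `without_host`
#'   and `with_host` (each: the `classification_result` plus `fp_by_taxon`
#'   and `fp_total`), `fold_decline` (ratio of false-positive totals;
#'   `Inf` if the with-host arm has none), and `infinite` flag.
#' @export
contamination_experiment <- function(host, bacteria, reads, k = 31L) {
  stopifnot("true_source" %in% names(reads))
  bact_names <- names(bacteria)
  tax <- build_taxonomy(data.frame(
    child = c(bact_names, "host"),
    parent = "root", stringsAsFactors = FALSE
  ))
  taxa_map <- stats::setNames(c(bact_names, "host"),
                              c(bact_names, "host"))
  db_without <- build_kmer_db(bacteria, taxa_map, tax, k)
  db_with <- build_kmer_db(c(bacteria, host = host), taxa_map, tax, k)

  kt <- read_kmer_table(reads, k)
  res_wo <- classify_set(reads, db_without, tax, kmer_table = kt)
  res_wi <- classify_set(reads, db_with, tax, kmer_table = kt)

  fp_tally <- function(res) {
    host_reads <- reads$true_source == "host"
    asg <- res$assignments$taxon
    fp <- host_reads & !is.na(asg) & asg %in% bact_names
    by_taxon <- table(factor(asg[fp], levels = bact_names))
    list(fp_by_taxon = data.frame(taxon = names(by_taxon),
                                  false_positives = as.integer(by_taxon),
                                  stringsAsFactors = FALSE),
         fp_total = sum(fp))
  }
  wo <- c(list(result = res_wo), fp_tally(res_wo))
  wi <- c(list(result = res_wi), fp_tally(res_wi))
  fd <- fold_decline(wo$fp_total, wi$fp_total, allow_infinite = TRUE)

  structure(
    list(without_host = wo, with_host = wi, fold_decline = fd,
         infinite = !is.finite(fd)),
    class = "contamination_experiment"
  )
}
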