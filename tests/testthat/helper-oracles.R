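# Independent brute-force oracles used to cross-check the package's
# vectorized implementations. Deliberately written as plain loops.

oracle_empty_submatrix <- function(counts, threshold) {
  keep_g <- character(0)
  for (g in colnames(counts)) {
    if (sum(counts[, g] > 0) < threshold) keep_g <- c(keep_g, g)
  }
  keep_s <- character(0)
  for (s in rownames(counts)) {
    ok <- TRUE
    for (g in keep_g) if (counts[s, g] > 0) ok <- FALSE
    if (ok) keep_s <- c(keep_s, s)
  }
  list(sample_ids = keep_s, genus_ids = keep_g)
}

oracle_compare_summary <- function(o, r, t) {
  n_pairs <- 0L; ge10 <- 0L; w50 <- 0L
  for (i in seq_len(nrow(o))) {
    for (j in seq_len(ncol(o))) {
      if (o[i, j] >= t) {
        n_pairs <- n_pairs + 1L
        if (o[i, j] >= 10 * r[i, j]) ge10 <- ge10 + 1L
        if (r[i, j] > 0 && abs(o[i, j] - r[i, j]) <= 0.5 * r[i, j]) {
          w50 <- w50 + 1L
        }
      }
    }
  }
  list(n_pairs = n_pairs, n_ge_10x = ge10, n_within_50pct = w50)
}

oracle_threshold_metrics <- function(values, labels, thr, side) {
  tp <- 0L; fp <- 0L; p <- 0L
  for (i in seq_along(values)) {
    pos_call <- if (side == "le") values[i] <= thr else values[i] > thr
    if (labels[i]) p <- p + 1L
    if (pos_call && labels[i]) tp <- tp + 1L
    if (pos_call && !labels[i]) fp <- fp + 1L
  }
  list(sensitivity = tp / p, error_fraction = fp / length(values))
}

oracle_multiplicity <- function(values) {
  sizes <- integer(0)
  seen <- numeric(0)
  for (v in values) {
    hit <- which(vapply(seen, function(s) identical(s, v), logical(1)))
    if (length(hit) == 1) {
      sizes[hit] <- sizes[hit] + 1L
    } else {
      seen <- c(seen, v)
      sizes <- c(sizes, 1L)
    }
  }
  sort(sizes, decreasing = TRUE)
}

oracle_ancestors <- function(parent, node) {
  anc <- node
  while (!is.na(parent[[node]])) {
    node <- parent[[node]]
    anc <- c(anc, node)
  }
  anc
}

oracle_lca <- function(parent, depth, nodes) {
  common <- oracle_ancestors(parent, nodes[1])
  for (nd in nodes[-1]) {
    common <- intersect(common, oracle_ancestors(parent, nd))
  }
  common[which.max(depth[common])]
}

# naive Kraken-style classification: enumerate every root-to-leaf path by
# walking parent pointers, weight by hits, tie-break by ancestor-set LCA
oracle_classify <- function(read, db, taxonomy) {
  kmers <- contamaudit::canonical_kmers(read, db$k)
  hits <- table(db$entries$taxon[match(kmers, db$entries$kmer)])
  if (length(hits) == 0) return(NA_character_)
  leaves <- setdiff(taxonomy$nodes, stats::na.omit(taxonomy$parent))
  w <- sapply(leaves, function(lf) {
    path <- oracle_ancestors(taxonomy$parent, lf)
    sum(hits[names(hits) %in% path])
  })
  top <- leaves[w == max(w)]
  if (length(top) == 1) top else
    oracle_lca(taxonomy$parent, taxonomy$depth, top)
}

random_tree_edges <- function(n_nodes, seed) {
  # node i attaches to a uniformly drawn earlier node
  withr::with_seed(seed, {
    data.frame(
      child = paste0("n", 2:n_nodes),
      parent = paste0("n", vapply(2:n_nodes,
                                  function(i) sample.int(i - 1L, 1L),
                                  integer(1))),
      stringsAsFactors = FALSE
    )
  })
}

random_count_matrix <- function(n, g, seed, lambda = 3) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n * g, lambda), n, g,
                dimnames = list(sprintf("S%03d", seq_len(n)),
                                sprintf("g%03d", seq_len(g))))
    storage.mode(m) <- "integer"
    m
  })
}
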