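#' Configuration for the sparse count-matrix simulator
#'
#' Builds and validates the parameter set for [simulate_counts()]. The
#' defaults define the package's reference study conditions for the
#' normalization-leakage audit: 5 classes of 100 samples each, 150 genera of
#' which 40% are all-zero, and per-class sequencing-depth offsets that
#' confound class with library size (the ingredient the leak feeds on).
#'
#' @param n_samples,n_genera Matrix dimensions (samples x genera).
#' @param n_classes Number of class labels (e.g. cancer types), assigned in
#'   balanced round-robin order.
#' @param n_batches Number of batches.
#' @param class_effect_genera Number of genera with a true class-associated
#'   abundance effect.
#' @param class_effect_sd SD of the log-scale class effects for those genera.
#' @param batch_effect_sd SD of log-scale genus-by-batch multipliers.
#' @param batch_class_confounding Probability, in `[0, 1]`, that a sample's
#'   batch equals its class index modulo `n_batches` rather than being drawn
#'   uniformly. 0 means batches are independent of class; 1 with
#'   `n_batches == n_classes` makes class and batch perfectly collinear.
#' @param baseline_log_mean Mean log expected count (at the reference depth)
#'   for ordinary genera; genus baselines are drawn around it with SD 1.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed); variance is `mu + mu^2 / dispersion`.
#' @param zero_genus_fraction Fraction of genera forced all-zero.
#' @param rare_genus_fraction Fraction of genera made sparsely present.
#' @param rare_max_prevalence Cap on the designed prevalence of rare genera:
#'   each rare genus is present in a sample with probability
#'   `rare_max_prevalence / (2 * n_samples)` (expected prevalence = half the
#'   cap, so the cap is exceeded with negligible probability).
#' @param library_size_log_mean,library_size_log_sd Log-normal parameters
#'   (natural log) of per-sample total sequencing depth.
#' @param library_size_class_spread Span (natural-log units) of equally
#'   spaced per-class depth offsets, emulating cohorts sequenced at
#'   systematically different depths. 0 removes the class-depth confound.
#' @param seed Integer seed; all randomness in [simulate_counts()] derives
#'   from it.
#' @return A validated list of class `sim_count_config`.
#' @export
sim_count_config <- function(n_samples = 500L,
                             n_genera = 150L,
                             n_classes = 5L,
                             n_batches = 2L,
                             class_effect_genera = 10L,
                             class_effect_sd = 1,
                             batch_effect_sd = 0.3,
                             batch_class_confounding = 0,
                             baseline_log_mean = log(10),
                             dispersion = 0.5,
                             zero_genus_fraction = 0.4,
                             rare_genus_fraction = 0,
                             rare_max_prevalence = 20L,
                             library_size_log_mean = log(1e5),
                             library_size_log_sd = 0.2,
                             library_size_class_spread = 2,
                             seed = 1L) {
  cfg <- list(
    n_samples = n_samples, n_genera = n_genera, n_classes = n_classes,
    n_batches = n_batches, class_effect_genera = class_effect_genera,
    class_effect_sd = class_effect_sd, batch_effect_sd = batch_effect_sd,
    batch_class_confounding = batch_class_confounding,
    baseline_log_mean = baseline_log_mean, dispersion = dispersion,
    zero_genus_fraction = zero_genus_fraction,
    rare_genus_fraction = rare_genus_fraction,
    rare_max_prevalence = rare_max_prevalence,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    library_size_class_spread = library_size_class_spread,
    seed = seed
  )
  check_scalar(n_samples, "n_samples", 1, integerish = TRUE)
  check_scalar(n_genera, "n_genera", 1, integerish = TRUE)
  check_scalar(n_classes, "n_classes", 1, integerish = TRUE)
  check_scalar(n_batches, "n_batches", 1, integerish = TRUE)
  check_scalar(class_effect_genera, "class_effect_genera", 0,
               integerish = TRUE)
  check_scalar(class_effect_sd, "class_effect_sd", 0)
  check_scalar(batch_effect_sd, "batch_effect_sd", 0)
  check_scalar(batch_class_confounding, "batch_class_confounding", 0, 1)
  check_scalar(baseline_log_mean, "baseline_log_mean")
  check_scalar(dispersion, "dispersion", .Machine$double.eps)
  check_scalar(zero_genus_fraction, "zero_genus_fraction", 0, 1)
  check_scalar(rare_genus_fraction, "rare_genus_fraction", 0, 1)
  check_scalar(rare_max_prevalence, "rare_max_prevalence", 1,
               integerish = TRUE)
  check_scalar(library_size_log_mean, "library_size_log_mean")
  check_scalar(library_size_log_sd, "library_size_log_sd", 0)
  check_scalar(library_size_class_spread, "library_size_class_spread", 0)
  check_scalar(seed, "seed", integerish = TRUE)
  if (zero_genus_fraction + rare_genus_fraction > 1) {
    stop("'zero_genus_fraction' + 'rare_genus_fraction' must be <= 1",
         call. = FALSE)
  }
  structure(cfg, class = "sim_count_config")
}

#' Simulate a sparse, overdispersed sample x genus count matrix
#'
#' Generates negative-binomial counts with log-linear class and batch
#' effects, a block of all-zero genera, optional sparsely present ("rare")
#' genera, and log-normal per-sample sequencing depths whose class-specific
#' offsets confound class label with library size.
#'
#' Genus columns are laid out deterministically: the first
#' `round(zero_genus_fraction * n_genera)` genera are all-zero, the next
#' `round(rare_genus_fraction * n_genera)` are rare, and the remainder are
#' ordinary; the first `class_effect_genera` ordinary genera carry the true
#' class effects. The random stream order (assignments, depths, genus
#' baselines, effects, ordinary counts, rare counts) is fixed, so results
#' are stable across runs for a given seed.
#'
#' @param config A [sim_count_config()].
#' @return A list with `counts` (integer matrix, samples x genera, dimnames
#'   set) and `metadata` (data.frame with `sample_id`, `class`, `kind`,
#'   `batch`, `library_size`). `library_size` is the simulated total
#'   sequencing depth of the sample (host reads included), the quantity a
#'   normalization pipeline would use as the library size; it is not the
#'   row sum of the microbial count matrix.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_count_config"))
  c_ <- config
  n <- as.integer(c_$n_samples)
  g <- as.integer(c_$n_genera)
  k <- as.integer(c_$n_classes)

  withr::local_seed(c_$seed)

  sample_id <- sprintf("S%04d", seq_len(n))
  genus_id <- sprintf("g%03d", seq_len(g))
  class_idx <- rep_len(seq_len(k), n)
  class_lab <- sprintf("C%d", class_idx)
  kind <- sample(c("tumor", "normal"), n, replace = TRUE,
                 prob = c(0.7, 0.3))
  confounded <- stats::runif(n) < c_$batch_class_confounding
  batch_idx <- ifelse(confounded,
                      ((class_idx - 1L) %% c_$n_batches) + 1L,
                      sample.int(c_$n_batches, n, replace = TRUE))
  batch_lab <- sprintf("B%d", batch_idx)

  # per-class depth offsets: equally spaced, centred, spanning the spread
  offs <- if (k > 1) {
    c_$library_size_class_spread * (seq_len(k) - 1) / (k - 1) -
      c_$library_size_class_spread / 2
  } else 0
  lib <- round(exp(c_$library_size_log_mean + offs[class_idx] +
                     stats::rnorm(n, 0, c_$library_size_log_sd)))
  lib <- pmax(lib, 1)

  n_zero <- round(c_$zero_genus_fraction * g)
  n_rare <- round(c_$rare_genus_fraction * g)
  n_ord <- g - n_zero - n_rare
  idx_zero <- seq_len(n_zero)
  idx_rare <- seq_len(n_rare) + n_zero
  idx_ord <- seq_len(n_ord) + n_zero + n_rare

  counts <- matrix(0L, n, g, dimnames = list(sample_id, genus_id))

  if (n_ord > 0) {
    base <- stats::rnorm(n_ord, c_$baseline_log_mean, 1)
    n_eff <- min(c_$class_effect_genera, n_ord)
    delta <- matrix(0, n_ord, k)
    if (n_eff > 0 && k > 1) {
      delta[seq_len(n_eff), ] <- stats::rnorm(n_eff * k, 0,
                                              c_$class_effect_sd)
    }
    gamma <- matrix(0, n_ord, c_$n_batches)
    if (c_$n_batches > 1) {
      gamma[] <- stats::rnorm(n_ord * c_$n_batches, 0, c_$batch_effect_sd)
    }
    depth_ratio <- lib / exp(c_$library_size_log_mean)
    for (j in seq_len(n_ord)) {
      mu <- exp(base[j] + delta[j, class_idx] + gamma[j, batch_idx]) *
        depth_ratio
      counts[, idx_ord[j]] <- stats::rnbinom(n, mu = mu, size = c_$dispersion)
    }
  }

  if (n_rare > 0) {
    p_present <- min(1, c_$rare_max_prevalence / (2 * n))
    for (j in idx_rare) {
      present <- stats::runif(n) < p_present
      counts[present, j] <- 1L + stats::rpois(sum(present), 0.7)
    }
  }

  storage.mode(counts) <- "integer"
  metadata <- data.frame(
    sample_id = sample_id,
    class = class_lab,
    kind = kind,
    batch = batch_lab,
    library_size = as.numeric(lib),
    stringsAsFactors = FALSE
  )
  list(counts = counts, metadata = metadata)
}

#' Configuration for the toy genome simulator
#'
#' @param host_length Host genome length in bp.
#' @param n_bacteria Number of bacterial genomes.
#' @param bacterial_length Length of each bacterial genome in bp.
#' @param contaminated_fraction Fraction of bacterial genomes that receive a
#'   verbatim host contig (a "draft genome" contamination event).
#' @param contig_length Length in bp of the injected host contig.
#' @param gc_content GC fraction of the i.i.d. base composition.
#' @param seed Integer seed.
#' @return A validated list of class `sim_genome_config`.
#' @export
sim_genome_config <- function(host_length = 100000L,
                              n_bacteria = 5L,
                              bacterial_length = 50000L,
                              contaminated_fraction = 0.6,
                              contig_length = 500L,
                              gc_content = 0.5,
                              seed = 1L) {
  check_scalar(host_length, "host_length", 1, integerish = TRUE)
  check_scalar(n_bacteria, "n_bacteria", 1, integerish = TRUE)
  check_scalar(bacterial_length, "bacterial_length", 1, integerish = TRUE)
  check_scalar(contaminated_fraction, "contaminated_fraction", 0, 1)
  check_scalar(contig_length, "contig_length", 1, integerish = TRUE)
  check_scalar(gc_content, "gc_content", 1e-9, 1 - 1e-9)
  check_scalar(seed, "seed", integerish = TRUE)
  if (contig_length >= host_length) {
    stop("'contig_length' must be smaller than 'host_length'", call. = FALSE)
  }
  if (contig_length >= bacterial_length) {
    stop("'contig_length' must be smaller than 'bacterial_length'",
         call. = FALSE)
  }
  structure(
    list(host_length = host_length, n_bacteria = n_bacteria,
         bacterial_length = bacterial_length,
         contaminated_fraction = contaminated_fraction,
         contig_length = contig_length, gc_content = gc_content,
         seed = seed),
    class = "sim_genome_config"
  )
}

random_dna <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a host genome plus bacterial genomes with injected host contigs
#'
#' Emulates database contamination by draft genomes: a chosen fraction of
#' the bacterial genomes has one segment replaced by a verbatim substring of
#' the host genome ("contig"), with donor coordinates recorded. Clean
#' genomes share no k-mers with the host except by (astronomically unlikely)
#' chance at toy scale.
#'
#' @param config A [sim_genome_config()].
#' @return A list with `host` (character sequence), `bacteria` (named
#'   character vector `bact1`, `bact2`, ...), and `contamination` — a
#'   BED-like data.frame (`genome_id`, `start`, `end`, `donor`,
#'   `donor_start`; 0-based half-open coordinates) with one row per
#'   injected contig.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_genome_config"))
  c_ <- config
  withr::local_seed(c_$seed)

  host <- random_dna(c_$host_length, c_$gc_content)
  bacteria <- vapply(seq_len(c_$n_bacteria), function(i) {
    random_dna(c_$bacterial_length, c_$gc_content)
  }, character(1))
  names(bacteria) <- sprintf("bact%d", seq_len(c_$n_bacteria))

  n_cont <- round(c_$contaminated_fraction * c_$n_bacteria)
  ann <- data.frame(genome_id = character(0), start = integer(0),
                    end = integer(0), donor = character(0),
                    donor_start = integer(0), stringsAsFactors = FALSE)
  if (n_cont > 0) {
    which_cont <- sort(sample.int(c_$n_bacteria, n_cont))
    for (i in which_cont) {
      donor_start <- sample.int(c_$host_length - c_$contig_length + 1L, 1L)
      ins_start <- sample.int(c_$bacterial_length - c_$contig_length + 1L, 1L)
      contig <- substr(host, donor_start, donor_start + c_$contig_length - 1L)
      seq_i <- bacteria[[i]]
      substr(seq_i, ins_start, ins_start + c_$contig_length - 1L) <- contig
      bacteria[[i]] <- seq_i
      ann <- rbind(ann, data.frame(
        genome_id = names(bacteria)[i],
        start = ins_start - 1L,
        end = ins_start - 1L + c_$contig_length,
        donor = "host",
        donor_start = donor_start - 1L,
        stringsAsFactors = FALSE
      ))
    }
  }
  list(host = host, bacteria = bacteria, contamination = ann)
}

#' Simulate error-prone reads from a set of source sequences
#'
#' Reads are drawn from the sources in proportion to `source_mix`, with
#' uniform start positions and i.i.d. substitution errors. The generating
#' source is recorded as ground truth.
#'
#' @param genomes Named character vector of source sequences (e.g.
#'   `c(host = ..., bact1 = ...)`).
#' @param n_reads Number of reads.
#' @param read_length Read length in bp; must not exceed any drawn source's
#'   length.
#' @param source_mix Named non-negative weights over names of `genomes`;
#'   must sum to a positive value.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A data.frame of class `read_set` with columns `read_id`,
#'   `sequence`, `true_source`.
#' @export
simulate_reads <- function(genomes, n_reads, read_length, source_mix,
                           error_rate = 0, seed = 1L) {
  if (length(source_mix) == 0) {
    stop("'source_mix' must name at least one source", call. = FALSE)
  }
  if (is.null(names(source_mix)) || !all(names(source_mix) %in%
                                         names(genomes))) {
    stop("'source_mix' names must be a subset of names(genomes)",
         call. = FALSE)
  }
  if (any(source_mix < 0) || sum(source_mix) <= 0) {
    stop("'source_mix' weights must be >= 0 and sum to > 0", call. = FALSE)
  }
  check_scalar(n_reads, "n_reads", 0, integerish = TRUE)
  check_scalar(read_length, "read_length", 1, integerish = TRUE)
  check_scalar(error_rate, "error_rate", 0, 1)
  lens <- nchar(genomes[names(source_mix)])
  if (any(read_length > lens)) {
    stop("'read_length' exceeds the length of a source sequence",
         call. = FALSE)
  }
  withr::local_seed(seed)

  src <- sample(names(source_mix), n_reads, replace = TRUE,
                prob = source_mix / sum(source_mix))
  seqs <- character(n_reads)
  for (s in unique(src)) {
    idx <- which(src == s)
    starts <- sample.int(nchar(genomes[[s]]) - read_length + 1L,
                         length(idx), replace = TRUE)
    seqs[idx] <- substring(genomes[[s]], starts, starts + read_length - 1L)
  }
  if (error_rate > 0 && n_reads > 0) {
    total <- n_reads * read_length
    hit <- which(stats::runif(total) < error_rate)
    if (length(hit) > 0) {
      bases <- c("A", "C", "G", "T")
      read_i <- ((hit - 1L) %/% read_length) + 1L
      pos_i <- ((hit - 1L) %% read_length) + 1L
      for (h in seq_along(hit)) {
        old <- substr(seqs[read_i[h]], pos_i[h], pos_i[h])
        new <- sample(setdiff(bases, old), 1L)
        substr(seqs[read_i[h]], pos_i[h], pos_i[h]) <- new
      }
    }
  }
  out <- data.frame(
    read_id = sprintf("r%06d", seq_len(n_reads)),
    sequence = seqs,
    true_source = src,
    stringsAsFactors = FALSE
  )
  class(out) <- c("read_set", "data.frame")
  out
}
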