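#' Run the normalization-leakage demonstration end to end
#'
#' Simulates a labeled count matrix, applies the voom transform (library
#' size = total sequencing depth), runs the SNM-style adjustment in both
#' supervised and blind mode, extracts the empty submatrix from the raw
#' counts, populates it from each normalized matrix, and audits both with
#' one-vs-rest classifiers. The supervised arm demonstrates the leak
#' (near-perfect AUROC despite all-zero raw counts); the blind arm is the
#' control (chance-level AUROC).
#'
#' @param config A [sim_count_config()]; its defaults are the package's
#'   reference study conditions.
#' @param prevalence_threshold Passed to [extract_empty_submatrix()].
#' @param cv_folds,backend Passed to [one_vs_all_audit()].
#' @param seed Seed for the audit stage (fold assignment / learner);
#'   defaults to `config$seed`.
#' @return A list with the simulation (`counts`, `metadata`), both
#'   normalized matrices, the `index`, both audits, and
#'   `median_auroc_supervised` / `median_auroc_blind` (over non-skipped
#'   classes).
#' @export
leak_demo <- function(config = sim_count_config(),
                      prevalence_threshold = 50L, cv_folds = 5L,
                      backend = "xgboost", seed = config$seed) {
  sim <- simulate_counts(config)
  voomed <- voom_transform(sim$counts,
                           lib_size = sim$metadata$library_size)
  supervised <- snm_normalize(voomed, sim$metadata, bio_vars = "class",
                              adj_vars = c("batch", "log_lib"),
                              mode = "supervised")
  blind <- snm_normalize(voomed, sim$metadata, bio_vars = character(0),
                         adj_vars = c("batch", "log_lib"), mode = "blind")

  index <- extract_empty_submatrix(sim$counts, prevalence_threshold)
  labels <- sim$metadata$class[match(index$sample_ids,
                                     sim$metadata$sample_id)]
  vals_sup <- populate_from_normalized(index, supervised)
  vals_bli <- populate_from_normalized(index, blind)
  audit_sup <- one_vs_all_audit(vals_sup, labels, cv_folds = cv_folds,
                                seed = seed, backend = backend)
  audit_bli <- one_vs_all_audit(vals_bli, labels, cv_folds = cv_folds,
                                seed = seed, backend = backend)

  med <- function(a) stats::median(a$auroc[a$flag != "skipped"],
                                   na.rm = TRUE)
  list(counts = sim$counts, metadata = sim$metadata, voomed = voomed,
       supervised = supervised, blind = blind, index = index,
       audit_supervised = audit_sup, audit_blind = audit_bli,
       median_auroc_supervised = med(audit_sup),
       median_auroc_blind = med(audit_bli))
}

#' Run the database-contamination demonstration end to end
#'
#' Simulates a host genome and bacterial genomes (a fraction of which carry
#' an injected host contig), draws host reads, and runs the two-database
#' classification experiment.
#'
#' @param genome_config A [sim_genome_config()].
#' @param n_reads Number of host reads (default 50,000).
#' @param read_length Read length in bp (default 67, the short-read length
#'   of the bladder-cohort whole-genome samples the demonstration mirrors).
#' @param error_rate Per-base substitution rate (default 0).
#' @param k K-mer length (default 31).
#' @param seed Seed for the read simulation.
#' @return The [contamination_experiment()] result, with the simulated
#'   `genomes` attached.
#' @export
contam_demo <- function(genome_config = sim_genome_config(),
                        n_reads = 50000L, read_length = 67L,
                        error_rate = 0, k = 31L,
                        seed = genome_config$seed) {
  gen <- simulate_genomes(genome_config)
  reads <- simulate_reads(c(host = gen$host, gen$bacteria),
                          n_reads = n_reads, read_length = read_length,
                          source_mix = c(host = 1), error_rate = error_rate,
                          seed = seed)
  out <- contamination_experiment(gen$host, gen$bacteria, reads, k = k)
  out$genomes <- gen
  out
}

pipeline_known_keys <- c("pipeline", "seed", "out_dir", "counts", "genomes",
                         "reads", "normalize", "audit", "kmer")

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (typically read from YAML or JSON)
#' with `pipeline` (`"leak-demo"` or `"contam-demo"`), `seed`, `out_dir`,
#' and optional stage-parameter sub-lists `counts`, `genomes`, `reads`,
#' `normalize`, `audit`, `kmer`. Unknown keys are rejected, so a config
#' round-trips losslessly through its file representation.
#'
#' @param config Named list.
#' @return The validated config, invisibly.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), pipeline_known_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!isTRUE(config$pipeline %in% c("leak-demo", "contam-demo"))) {
    stop("'pipeline' must be \"leak-demo\" or \"contam-demo\"",
         call. = FALSE)
  }
  check_scalar(config$seed %||% 1L, "seed", integerish = TRUE)
  if (is.null(config$out_dir)) stop("'out_dir' is required", call. = FALSE)
  invisible(config)
}

#' Execute a pipeline run configuration and write a manifest
#'
#' Runs the requested demonstration, writes its tabular outputs under
#' `config$out_dir`, and records every output file with an MD5 content
#' digest in `manifest.json`. Identical config + seed produce identical
#' digests (floats are serialized at 9 significant digits).
#'
#' @param config A run configuration (see [validate_run_config()]); may
#'   also be a path to a YAML file.
#' @return Data.frame manifest (`file`, `md5`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  validate_run_config(config)
  seed <- as.integer(config$seed %||% 1L)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)

  if (config$pipeline == "leak-demo") {
    cfg <- do.call(sim_count_config,
                   c(config$counts %||% list(), list(seed = seed)))
    aud <- config$audit %||% list()
    demo <- leak_demo(cfg,
                      prevalence_threshold = aud$prevalence_threshold %||% 50L,
                      cv_folds = aud$cv_folds %||% 5L,
                      backend = aud$backend %||% "xgboost", seed = seed)
    write_count_matrix(demo$counts, out("counts.tsv"))
    write_metadata(demo$metadata, out("metadata.tsv"))
    write_normalized_matrix(demo$supervised, out("normalized_supervised.tsv"))
    write_normalized_matrix(demo$blind, out("normalized_blind.tsv"))
    data.table::fwrite(demo$audit_supervised, out("audit_supervised.tsv"),
                       sep = "\t")
    data.table::fwrite(demo$audit_blind, out("audit_blind.tsv"), sep = "\t")
    jsonlite::write_json(
      list(median_auroc_supervised = demo$median_auroc_supervised,
           median_auroc_blind = demo$median_auroc_blind,
           n_samples_retained = length(demo$index$sample_ids),
           n_genera_retained = length(demo$index$genus_ids)),
      out("leak_summary.json"), auto_unbox = TRUE, digits = NA)
    files <- c("counts.tsv", "metadata.tsv", "normalized_supervised.tsv",
               "normalized_supervised.tsv.json", "normalized_blind.tsv",
               "normalized_blind.tsv.json", "audit_supervised.tsv",
               "audit_blind.tsv", "leak_summary.json")
  } else {
    gcfg <- do.call(sim_genome_config,
                    c(config$genomes %||% list(), list(seed = seed)))
    rd <- config$reads %||% list()
    demo <- contam_demo(gcfg,
                        n_reads = rd$n_reads %||% 50000L,
                        read_length = rd$read_length %||% 67L,
                        error_rate = rd$error_rate %||% 0,
                        k = (config$kmer %||% list())$k %||% 31L,
                        seed = seed)
    write_fasta(c(host = demo$genomes$host, demo$genomes$bacteria),
                out("genomes.fasta"))
    write_contamination(demo$genomes$contamination, out("contamination.tsv"))
    data.table::fwrite(demo$without_host$fp_by_taxon,
                       out("false_positives_without_host.tsv"), sep = "\t")
    data.table::fwrite(demo$with_host$fp_by_taxon,
                       out("false_positives_with_host.tsv"), sep = "\t")
    jsonlite::write_json(
      list(fp_total_without_host = demo$without_host$fp_total,
           fp_total_with_host = demo$with_host$fp_total,
           fold_decline = if (demo$infinite) "Inf" else demo$fold_decline,
           infinite = demo$infinite),
      out("contam_summary.json"), auto_unbox = TRUE, digits = NA)
    files <- c("genomes.fasta", "contamination.tsv",
               "false_positives_without_host.tsv",
               "false_positives_with_host.tsv", "contam_summary.json")
  }

  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, out("manifest.json"), digits = NA)
  invisible(manifest)
}
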