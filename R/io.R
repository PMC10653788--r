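#' Write / read a sample x genus count matrix as TSV
#'
#' Samples are rows; the first column is `sample_id` and the remaining
#' header names are genus identifiers. Cells must be non-negative integers;
#' violations are reported with their row/column coordinates. Round-trips
#' exactly.
#'
#' @param matrix Integer matrix with dimnames.
#' @param path File path.
#' @return `write_count_matrix()` returns `path` invisibly;
#'   `read_count_matrix()` returns the integer matrix.
#' @export
write_count_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  dt <- data.table::data.table(sample_id = rownames(matrix))
  dt <- cbind(dt, data.table::as.data.table(matrix))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != "sample_id") {
    stop("first column must be 'sample_id' (samples are rows)",
         call. = FALSE)
  }
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id at row(s): ",
         paste(which(duplicated(ids)), collapse = ", "), call. = FALSE)
  }
  gen <- names(dt)[-1]
  if (anyDuplicated(gen)) {
    stop("duplicate genus column(s): ",
         paste(unique(gen[duplicated(gen)]), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-integer or negative cell at row %d ('%s'), column '%s'",
      bad[1, 1], ids[bad[1, 1]], gen[bad[1, 2]]), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(ids, gen)
  m
}

#' Write / read sample metadata as TSV
#'
#' @param metadata Data.frame keyed by `sample_id`.
#' @param path File path.
#' @return `write_metadata()` returns `path` invisibly; `read_metadata()`
#'   the data.frame.
#' @export
write_metadata <- function(metadata, path) {
  stopifnot("sample_id" %in% names(metadata))
  data.table::fwrite(metadata, path, sep = "\t")
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  colClasses = list(character = "sample_id")))
}

#' Write a normalized matrix as TSV with a JSON provenance sidecar
#'
#' Values are serialized with 9 significant digits - enough to preserve the
#' bit-identical duplicated-value diagnostic - and the normalization
#' provenance (mode, variables, transform parameters) goes to
#' `<path>.json`.
#'
#' @param normalized A `normalized_matrix`.
#' @param path File path for the TSV.
#' @return `path`, invisibly.
#' @export
write_normalized_matrix <- function(normalized, path) {
  stopifnot(inherits(normalized, "normalized_matrix"))
  v <- normalized$values
  fmt <- matrix(sprintf("%.9g", v), nrow(v), dimnames = dimnames(v))
  dt <- data.table::data.table(sample_id = rownames(v))
  dt <- cbind(dt, data.table::as.data.table(fmt))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  jsonlite::write_json(
    list(mode = normalized$mode, bio_vars = normalized$bio_vars,
         adj_vars = normalized$adj_vars, params = normalized$params),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a normalized matrix written by [write_normalized_matrix()]
#'
#' @param path TSV path; the `<path>.json` sidecar is read if present.
#' @return A `normalized_matrix` (weights are not round-tripped).
#' @export
read_normalized_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "sample_id"))
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- dt$sample_id
  side <- paste0(path, ".json")
  prov <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
  else list(mode = "unknown", bio_vars = character(0),
            adj_vars = character(0), params = list())
  structure(list(values = m, weights = NULL, mode = prov$mode,
                 lib_size = NULL, params = prov$params,
                 bio_vars = prov$bio_vars, adj_vars = prov$adj_vars),
            class = "normalized_matrix")
}

#' Write genomes as FASTA (with a BED-like contamination sidecar)
#'
#' @param genomes Named character vector of sequences.
#' @param path FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  set <- Biostrings::DNAStringSet(genomes)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write contamination annotations (0-based half-open) as TSV
#'
#' @param annotations Data.frame with `genome_id`, `start`, `end`,
#'   `donor`, `donor_start`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_contamination <- function(annotations, path) {
  data.table::fwrite(annotations, path, sep = "\t")
  invisible(path)
}

#' Write / read a read set as FASTQ
#'
#' Dummy quality `"I"` per base; the true source is carried in the read
#' description after a space.
#'
#' @param reads A `read_set`.
#' @param path FASTQ path.
#' @return `write_fastq()` returns `path` invisibly; `read_fastq()` a
#'   `read_set`.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$sequence),
                 function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(
    paste0("@", reads$read_id, " ", reads$true_source),
    reads$sequence, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 4 == 0)
  hdr <- lines[seq(1, length(lines), by = 4)]
  parts <- strsplit(sub("^@", "", hdr), " ")
  out <- data.frame(
    read_id = vapply(parts, `[`, character(1), 1),
    sequence = lines[seq(2, length(lines), by = 4)],
    true_source = vapply(parts, function(p) p[2] %||% NA_character_,
                         character(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("read_set", "data.frame")
  out
}
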