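#' Summary fractions for an original-vs-re-analysis comparison
#'
#' Given tallies of sample/genus pairs, returns the fractions (and
#' table-style percentages) of pairs whose original count is at least ten
#' times the re-analysed count, and of pairs within 50% of the re-analysed
#' count. Shared by [compare_counts()] and usable directly on published
#' tallies.
#'
#' @param n_pairs Number of pairs at the threshold.
#' @param n_ge_10x Pairs with original >= 10 x re-analysis.
#' @param n_within_50pct Pairs within 50% of the re-analysis value.
#' @return List with `frac_ge_10x`, `frac_within_50pct`, `pct_ge_10x`,
#'   `pct_within_50pct` (percentages rounded as in published tables).
#' @export
comparison_fractions <- function(n_pairs, n_ge_10x, n_within_50pct) {
  stopifnot(n_pairs >= 0, n_ge_10x <= n_pairs, n_within_50pct <= n_pairs)
  if (n_pairs == 0) {
    return(list(frac_ge_10x = NA_real_, frac_within_50pct = NA_real_,
                pct_ge_10x = NA_real_, pct_within_50pct = NA_real_))
  }
  list(
    frac_ge_10x = n_ge_10x / n_pairs,
    frac_within_50pct = n_within_50pct / n_pairs,
    pct_ge_10x = pct_of(n_ge_10x, n_pairs),
    pct_within_50pct = pct_of(n_within_50pct, n_pairs)
  )
}

#' Compare two aligned count matrices cell by cell
#'
#' Inner-joins two sample x genus count matrices on their identifiers and,
#' for each minimum-count threshold, summarizes how many original counts
#' are at least 10 times the re-analysed count and how many are within 50%
#' of it. A re-analysed count of zero counts toward the ">= 10 times too
#' high" condition (the ratio is infinite) and can never be "within 50%".
#'
#' @param original,reanalysis Integer matrices with sample row names and
#'   genus column names; identifiers are inner-joined, and unmatched ones
#'   reported in the result.
#' @param min_counts Integer thresholds applied to the original count.
#' @return A list of class `comparison_report`: `pairs` (data.table of
#'   sample_id, genus_id, count_original, count_reanalysis, ratio over all
#'   non-zero original counts), `summary` (data.frame per threshold:
#'   min_count, n_pairs, n_ge_10x, frac_ge_10x, pct_ge_10x, n_within_50pct,
#'   frac_within_50pct, pct_within_50pct), and `unmatched` (list of sample
#'   and genus identifiers present in only one matrix).
#' @export
compare_counts <- function(original, reanalysis, min_counts = c(10L, 100L)) {
  stopifnot(is.matrix(original), is.matrix(reanalysis))
  s_common <- intersect(rownames(original), rownames(reanalysis))
  g_common <- intersect(colnames(original), colnames(reanalysis))
  if (length(s_common) == 0 || length(g_common) == 0) {
    stop("matrices share no sample or genus identifiers", call. = FALSE)
  }
  unmatched <- list(
    samples = union(setdiff(rownames(original), s_common),
                    setdiff(rownames(reanalysis), s_common)),
    genera = union(setdiff(colnames(original), g_common),
                   setdiff(colnames(reanalysis), g_common))
  )
  o <- original[s_common, g_common, drop = FALSE]
  r <- reanalysis[s_common, g_common, drop = FALSE]

  nz <- which(o > 0, arr.ind = TRUE)
  pairs <- data.table::data.table(
    sample_id = s_common[nz[, 1]],
    genus_id = g_common[nz[, 2]],
    count_original = o[nz],
    count_reanalysis = r[nz]
  )
  pairs[, ratio := count_original / count_reanalysis]

  summary <- do.call(rbind, lapply(sort(min_counts), function(t) {
    sub <- pairs[count_original >= t]
    ge10 <- sub[, sum(count_original >= 10 * count_reanalysis)]
    w50 <- sub[, sum(count_reanalysis > 0 &
                       abs(count_original - count_reanalysis) <=
                       0.5 * count_reanalysis)]
    fr <- comparison_fractions(nrow(sub), ge10, w50)
    data.frame(min_count = t, n_pairs = nrow(sub), n_ge_10x = ge10,
               frac_ge_10x = fr$frac_ge_10x, pct_ge_10x = fr$pct_ge_10x,
               n_within_50pct = w50,
               frac_within_50pct = fr$frac_within_50pct,
               pct_within_50pct = fr$pct_within_50pct)
  }))

  structure(list(pairs = pairs, summary = summary, unmatched = unmatched),
            class = "comparison_report")
}

#' Fold decline of a read count
#'
#' Ratio of a count before to after an intervention (e.g. adding the host
#' genome to a classification database).
#'
#' @param count_before,count_after Non-negative counts.
#' @param allow_infinite If `TRUE`, `count_after == 0` yields `Inf` instead
#'   of an error.
#' @return `count_before / count_after`.
#' @export
fold_decline <- function(count_before, count_after, allow_infinite = FALSE) {
  stopifnot(count_before >= 0, count_after >= 0)
  if (count_after == 0) {
    if (!allow_infinite) {
      stop("count_after is zero; set allow_infinite = TRUE to report Inf",
           call. = FALSE)
    }
    return(Inf)
  }
  count_before / count_after
}

#' Residual host-read accounting
#'
#' From per-dataset totals - total reads, reads initially unmapped to the
#' host reference, and reads identified as host in a second alignment pass
#' against a complete genome - derives the percentage initially unmapped,
#' the percentage of initially unmapped reads that are actually host, and
#' the mean residual host reads per sample. Percentages are rounded
#' half-up to one decimal, matching published accounting tables.
#'
#' @param acct Data.frame with columns `dataset`, `total_reads`,
#'   `initially_unmapped`, `second_pass_human`, `n_samples`.
#' @return The input with derived columns `pct_unmapped`,
#'   `pct_second_pass_human`, `mean_human_per_sample` appended.
#' @export
residual_human_summary <- function(acct) {
  needed <- c("total_reads", "initially_unmapped", "second_pass_human",
              "n_samples")
  stopifnot(all(needed %in% names(acct)))
  with(acct, {
    if (any(total_reads <= 0) || any(initially_unmapped <= 0) ||
        any(n_samples < 1)) {
      stop("denominators must be positive", call. = FALSE)
    }
    if (any(second_pass_human > initially_unmapped) ||
        any(initially_unmapped > total_reads)) {
      stop("accounting invariant violated: need second_pass_human <= ",
           "initially_unmapped <= total_reads", call. = FALSE)
    }
  })
  acct$pct_unmapped <-
    round_half_up(100 * acct$initially_unmapped / acct$total_reads, 1)
  acct$pct_second_pass_human <-
    round_half_up(100 * acct$second_pass_human / acct$initially_unmapped, 1)
  acct$mean_human_per_sample <- acct$second_pass_human / acct$n_samples
  acct
}

#' Most abundant genera by mean reads per sample
#'
#' @param counts Count matrix, samples x genera.
#' @param n Number of top genera to return.
#' @return Data.frame with `genus` and `mean_reads`, ordered by decreasing
#'   mean (ties broken lexicographically by genus id).
#' @export
top_genera_means <- function(counts, n) {
  stopifnot(is.matrix(counts))
  check_scalar(n, "n", 1, integerish = TRUE)
  m <- colMeans(counts)
  ord <- order(-m, colnames(counts))
  head_n <- utils::head(ord, n)
  data.frame(genus = colnames(counts)[head_n],
             mean_reads = unname(m[head_n]),
             stringsAsFactors = FALSE)
}
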