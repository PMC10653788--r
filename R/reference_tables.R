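#' Published read-accounting totals for three re-analysed tumor cohorts
#'
#' Integer totals from the re-analysis of the bladder (BLCA), head-and-neck
#' (HNSC) and breast (BRCA) cancer cohorts: total reads in the raw
#' alignment files, reads initially unmapped to the human reference, reads
#' identified as human in a second alignment pass against the complete
#' CHM13 genome, and the number of samples downloaded. These are the
#' inputs for [residual_human_summary()].
#'
#' @return Data.frame with columns `dataset`, `total_reads`,
#'   `initially_unmapped`, `second_pass_human`, `n_samples`.
#' @export
cohort_read_accounting <- function() {
  data.frame(
    dataset = c("BLCA", "HNSC", "BRCA"),
    total_reads = c(207716524420, 258961253944, 324824097837),
    initially_unmapped = c(5025973203, 3573898240, 1532210153),
    second_pass_human = c(981451972, 519222095, 785947157),
    n_samples = c(683, 334, 238),
    stringsAsFactors = FALSE
  )
}

#' Published sample/genus pair tallies for the count-inflation comparison
#'
#' Per cohort and minimum original count: the number of non-zero
#' sample/genus pairs, the number whose originally reported count was at
#' least 10 times the re-analysed count, and the number within 50% of the
#' re-analysed count. Inputs for [comparison_fractions()].
#'
#' @return Data.frame with `dataset`, `min_count`, `n_pairs`, `n_ge_10x`,
#'   `n_within_50pct`.
#' @export
comparison_tallies <- function() {
  data.frame(
    dataset = rep(c("BLCA", "HNSC", "BRCA"), each = 2),
    min_count = rep(c(10L, 100L), 3),
    n_pairs = c(37258, 16969, 114640, 55259, 83476, 46025),
    n_ge_10x = c(36714, 16869, 106544, 52689, 81736, 45686),
    n_within_50pct = c(90, 5, 1190, 274, 172, 11),
    stringsAsFactors = FALSE
  )
}

#' Published constants of the single-genus threshold-rule example
#'
#' The normalized-value rule for one virus genus in the adrenocortical
#' cohort: 71 of 79 positive samples sit exactly at the threshold value
#' 3.078874655, the other 8 positives lie above it, 77 of the 17,546
#' negative samples lie at or below it, and the rest lie above. Together
#' with the raw-matrix entry tallies (zero and non-zero cells) and the
#' before/after read counts of the two-genus database experiment, these
#' integers drive the worked-example arithmetic.
#'
#' @return A list with elements `rule` (threshold, n_total, n_pos,
#'   n_pos_at_threshold, n_neg_le_threshold), `matrix_entries`
#'   (n_zero, n_nonzero), and `db_experiment` (data.frame genus,
#'   reads_without_host, reads_with_host).
#' @export
rule_example_constants <- function() {
  list(
    rule = list(threshold = 3.078874655, n_total = 17625L, n_pos = 79L,
                n_pos_at_threshold = 71L, n_neg_le_threshold = 77L),
    matrix_entries = list(n_zero = 21074259, n_nonzero = 14071985),
    db_experiment = data.frame(
      genus = c("Streptococcus", "Waddlia"),
      reads_without_host = c(1434287, 197811),
      reads_with_host = c(10792, 174),
      stringsAsFactors = FALSE
    )
  )
}

#' Construct the worked-example value vector of the threshold rule
#'
#' Builds a full-cohort vector and label set matching the published
#' description: positives at/above the threshold and negatives at/below or
#' above as tallied, suitable for [threshold_rule_metrics()] with
#' `positive_side = "le"`.
#'
#' @param constants The `rule` element of [rule_example_constants()].
#' @return List with `values` and `labels` (logical, `TRUE` = positive).
#' @export
rule_example_vectors <- function(constants = rule_example_constants()$rule) {
  c_ <- constants
  thr <- c_$threshold
  n_neg <- c_$n_total - c_$n_pos
  values <- c(
    rep(thr, c_$n_pos_at_threshold),              # positives at threshold
    rep(thr + 1, c_$n_pos - c_$n_pos_at_threshold), # positives above
    rep(thr - 0.5, c_$n_neg_le_threshold),        # negatives at/below
    rep(thr + 2, n_neg - c_$n_neg_le_threshold)   # negatives above
  )
  labels <- c(rep(TRUE, c_$n_pos), rep(FALSE, n_neg))
  list(values = values, labels = labels)
}
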