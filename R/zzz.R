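#' @importFrom data.table := .N .SD data.table
#' @importFrom stats median sd
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "count_original", "count_reanalysis", "ratio", "kmer", "taxon",
  "read_id", "valid", "N", "sig", "taxa", "call", "distinct_kmers"
))
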