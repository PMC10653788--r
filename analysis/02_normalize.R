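#!/usr/bin/env Rscript
# Stage 2: normalize the simulated counts two ways.
#
# Both arms share the voom-style log-CPM transform (library size = total
# sequencing depth). The supervised arm then applies the SNM-style
# adjustment with the class label as a retained biological variable (the
# leak-prone configuration); the blind arm adjusts for batch and log
# library size without ever seeing the label.

suppressMessages(library(contamaudit))

data_dir <- "results/data"
out <- "results/normalized"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

counts <- read_count_matrix(file.path(data_dir, "counts.tsv"))
meta <- read_metadata(file.path(data_dir, "metadata.tsv"))

voomed <- voom_transform(counts, lib_size = meta$library_size)
cat(sprintf("voom: values in [%.2f, %.2f]\n",
            min(voomed$values), max(voomed$values)))

supervised <- snm_normalize(voomed, meta, bio_vars = "class",
                            adj_vars = c("batch", "log_lib"),
                            mode = "supervised")
blind <- snm_normalize(voomed, meta, bio_vars = character(0),
                       adj_vars = c("batch", "log_lib"), mode = "blind")

write_normalized_matrix(supervised, file.path(out, "supervised.tsv"))
write_normalized_matrix(blind, file.path(out, "blind.tsv"))

# what each arm did to an all-zero genus
zero_genus <- colnames(counts)[colSums(counts) == 0][1]
by_class <- function(x) round(tapply(x, meta$class, mean), 3)
cat(sprintf("all-zero genus '%s', per-class mean normalized value:\n",
            zero_genus))
cat("  supervised:", by_class(supervised$values[, zero_genus]), "\n")
cat("  blind:     ", by_class(blind$values[, zero_genus]), "\n")
cat("(supervised retains class-dependent constants; blind is flat)\n")
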