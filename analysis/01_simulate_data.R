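#!/usr/bin/env Rscript
# Stage 1: generate the study's synthetic inputs.
#
# (a) A sample x genus count matrix under the reference conditions: 5
#     classes x 100 samples, 150 genera, 40% all-zero genera, sequencing
#     depth confounded with class (equally spaced per-class log-depth
#     offsets). This is the stand-in for a genus-level taxonomic
#     classification matrix over a multi-cohort tumor collection.
# (b) A toy host genome plus five bacterial genomes, three of which carry a
#     verbatim 500 bp host contig ("draft-genome contamination"), and
#     50,000 error-free 67 bp host reads.

suppressMessages(library(contamaudit))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

cfg <- sim_count_config(seed = seed)
sim <- simulate_counts(cfg)
write_count_matrix(sim$counts, file.path(out, "counts.tsv"))
write_metadata(sim$metadata, file.path(out, "metadata.tsv"))
cat(sprintf("count matrix: %d samples x %d genera, %.1f%% zero entries, %d all-zero genera\n",
            nrow(sim$counts), ncol(sim$counts),
            100 * mean(sim$counts == 0), sum(colSums(sim$counts) == 0)))
cat(sprintf("per-class mean depth: %s\n",
            paste(round(tapply(sim$metadata$library_size,
                               sim$metadata$class, mean)), collapse = " ")))

gcfg <- sim_genome_config(seed = seed)
gen <- simulate_genomes(gcfg)
write_fasta(c(host = gen$host, gen$bacteria), file.path(out, "genomes.fasta"))
write_contamination(gen$contamination, file.path(out, "contamination.tsv"))
cat(sprintf("genomes: host %d bp, %d bacteria, %d contaminated with %d bp contigs\n",
            nchar(gen$host), length(gen$bacteria),
            nrow(gen$contamination), gcfg$contig_length))

reads <- simulate_reads(c(host = gen$host, gen$bacteria),
                        n_reads = 50000L, read_length = 67L,
                        source_mix = c(host = 1), error_rate = 0,
                        seed = seed)
write_fastq(reads, file.path(out, "host_reads.fastq"))
cat(sprintf("reads: %d x %d bp, all host-derived, error-free\n",
            nrow(reads), 67L))
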