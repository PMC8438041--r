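#!/usr/bin/env Rscript

# Stage 1: simulate the reference synthetic virome community.
#
# Fifty viral genomes (8-20 kb) partitioned into genera with shared gene
# content, thirty 30-kb host genomes each carrying one planted CRISPR
# array whose spacers are exact protospacer copies from the viruses,
# three samples with log-normal genus abundances and a forced core, 2000
# error-free 150-bp reads per sample, and a Hi-C contact table. Seed 1
# throughout; every downstream stage reuses this community.

suppressPackageStartupMessages(library(asvirome))

dir.create("results", showWarnings = FALSE)
cfg <- synth_config(n_viruses = 50, n_hosts = 30, n_samples = 3,
                    subs_per_spacer = 0, n_reads_per_sample = 2000,
                    seed = 1)
comm <- gen_community(cfg)
files <- write_community(comm, "results/01_community")
saveRDS(comm, "results/community.rds")

tl <- comm$truth$true_links
cat("viral genomes:   ", length(comm$viruses), "\n")
cat("host genomes:    ", length(comm$hosts), "\n")
cat("planted genera:  ", length(unique(comm$truth$true_genus_of)), "\n")
cat("planted spacers: ", nrow(comm$truth$planted_spacers), "\n")
cat("true virus-host links:", nrow(tl), "\n")
cat("core genera:     ",
    length(attr(comm$truth$true_abundance, "core_genera")), "\n")
cat("files written under results/01_community:", length(files), "\n")
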