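#!/usr/bin/env Rscript

# Stage 2: identify viral contigs among all assembled contigs.
#
# Two routes, then a union: (i) the viral-protein-family screen (length
# > 5 kb, >= 5 VPF-hit genes, and any of the three evidence criteria) on
# per-contig annotation counts; (ii) an LCA taxonomic assignment over the
# taxonomy-hit table, keeping contigs resolving under Viruses. On planted
# data every viral genome and no host genome should survive.

suppressPackageStartupMessages(library(asvirome))
comm <- readRDS("results/community.rds")

all_contigs <- c(comm$viruses, comm$hosts)
counts <- contig_annotation_counts(comm$annotation, nchar(all_contigs))
counts$vpf_viral <- screen_vpf(counts)

lca <- lca_assign_all(comm$taxhits)
lca_viral <- lca$contig_id[startsWith(lca$lineage, "Viruses")]
viral_ids <- merge_viral_sets(counts$contig_id[counts$vpf_viral], lca_viral)

dir.create("results/02_screen", showWarnings = FALSE)
write.table(counts, "results/02_screen/screen_decisions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(contig_id = viral_ids),
            "results/02_screen/viral_contigs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth_viral <- names(comm$viruses)
cat("contigs screened:      ", nrow(counts), "\n")
cat("VPF route:             ", sum(counts$vpf_viral), "\n")
cat("LCA route:             ", length(lca_viral), "\n")
cat("union:                 ", length(viral_ids), "\n")
cat("false positives (hosts):",
    sum(!(viral_ids %in% truth_viral)), "\n")
cat("false negatives:       ",
    sum(!(truth_viral %in% viral_ids)), "\n")
cat("viral contig N50 (bp): ",
    compute_n50(nchar(comm$viruses[viral_ids[viral_ids %in% truth_viral]])),
    "\n")
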