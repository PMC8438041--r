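#!/usr/bin/env Rscript

# Stage 5: abundance, diversity, rarefaction, ordination, core genera.
#
# Coverage-based relative abundances are aggregated to planted genera;
# Shannon and Pielou indices summarize each sample; Bray-Curtis
# dissimilarities are ordinated by PCoA; rarefaction tracks detected
# contigs against subsampled reads; and exclusive intersection counts
# identify the core shared across all samples.

suppressPackageStartupMessages(library(asvirome))
comm <- readRDS("results/community.rds")
dir.create("results/05_ecology", showWarnings = FALSE)

gm <- comm$truth$true_genus_of
ab <- relative_abundance(comm$coverage, nchar(comm$viruses), gm)
write.table(data.frame(genus = rownames(ab$abundance), ab$abundance,
                       check.names = FALSE),
            "results/05_ecology/abundance_matrix.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

div <- data.frame(sample_id = colnames(ab$abundance),
                  shannon = apply(ab$abundance, 2, shannon),
                  pielou = apply(ab$abundance, 2, pielou),
                  n_genera = colSums(ab$presence))
write.table(div, "results/05_ecology/diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Shannon H' range:", round(min(div$shannon), 2), "-",
    round(max(div$shannon), 2), "\n")
cat("Pielou J' range: ", round(min(div$pielou), 2), "-",
    round(max(div$pielou), 2), "\n")

## Spearman agreement between planted and estimated abundances
truth <- comm$truth$true_abundance
rho <- sapply(colnames(truth), function(s)
  cor(truth[rownames(ab$abundance), s], ab$abundance[, s],
      method = "spearman"))
cat("planted-vs-estimated Spearman per sample:",
    paste(round(rho, 3), collapse = " "), "\n")

D <- bray_curtis_matrix(ab$abundance)
ord <- pcoa_ord(D, k = 2)
write.table(data.frame(sample_id = rownames(ord$points), ord$points,
                       check.names = FALSE),
            "results/05_ecology/pcoa_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Bray-Curtis range:", round(min(D[upper.tri(D)]), 3), "-",
    round(max(D[upper.tri(D)]), 3), "\n")

rar <- do.call(rbind, lapply(names(comm$reads), function(s) {
  rc <- rarefaction_curve(comm$reads[[s]], comm$viruses,
                          fractions = seq(0, 1, by = 0.2), seed = 1)
  rc$sample_id <- s
  rc
}))
write.table(rar, "results/05_ecology/rarefaction.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("rarefaction endpoint detections:",
    paste(rar$n_detected[rar$fraction == 1], collapse = " "), "\n")

core <- core_shared_genera(ab$presence)
write.table(core$counts, "results/05_ecology/upset_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("core genera present in all samples:", length(core$core), "\n")

ra <- rank_abundance(ab$abundance[, 1], threshold = 0.001)
cat("rank at which s1 abundance first drops below 0.1%:",
    ra$crossing_rank, "\n")
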