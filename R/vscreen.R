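#' Aggregate a gene-level annotation table into per-contig counts
#'
#' @param annotation Data frame with columns `gene_id`, `contig_id`,
#'   `has_vpf`, `has_pfam`, `has_ko` (one row per predicted gene).
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @return Data frame with one row per contig: `contig_id`, `length`,
#'   `n_genes`, `n_ko`, `n_pfam`, `n_vpf`.
#' @export
contig_annotation_counts <- function(annotation, contig_lengths) {
  ids <- names(contig_lengths)
  cnt <- function(flag) {
    x <- tapply(as.logical(annotation[[flag]]), annotation$contig_id, sum)
    out <- x[ids]
    out[is.na(out)] <- 0
    as.integer(out)
  }
  ng <- tapply(annotation$gene_id, annotation$contig_id, length)[ids]
  ng[is.na(ng)] <- 0
  data.frame(contig_id = ids, length = as.numeric(contig_lengths),
             n_genes = as.integer(ng), n_ko = cnt("has_ko"),
             n_pfam = cnt("has_pfam"), n_vpf = cnt("has_vpf"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Viral-protein-family screen for viral contigs
#'
#' A contig is called viral when it passes two hard gates -- length strictly
#' greater than 5 kb and at least five genes with VPF hits -- and satisfies
#' the evidence criteria: (C1) at most 20% of genes with KO terms, at most
#' 40% with Pfam hits and at least 10% with VPF hits; (C2) more VPF than
#' Pfam genes; (C3) at least 60% of genes with VPF hits. With
#' `criteria_mode = "any"` (default) any one criterion suffices; with
#' `"all"` all three must hold.
#'
#' @param ann Data frame with columns `length`, `n_genes`, `n_ko`,
#'   `n_pfam`, `n_vpf` (one row per contig); extra columns are ignored.
#' @param criteria_mode `"any"` or `"all"`.
#' @return Logical vector, one element per row of `ann`.
#' @export
screen_vpf <- function(ann, criteria_mode = c("any", "all")) {
  criteria_mode <- match.arg(criteria_mode)
  len <- ann$length
  ng <- ann$n_genes
  frac <- function(x) ifelse(ng > 0, x / ng, 0)
  gate <- len > 5000 & ann$n_vpf >= 5
  c1 <- frac(ann$n_ko) <= 0.20 & frac(ann$n_pfam) <= 0.40 &
    frac(ann$n_vpf) >= 0.10
  c2 <- ann$n_vpf > ann$n_pfam
  c3 <- frac(ann$n_vpf) >= 0.60
  crit <- if (criteria_mode == "any") c1 | c2 | c3 else c1 & c2 & c3
  out <- gate & crit & ng > 0
  out[is.na(out)] <- FALSE
  out
}

#' Lowest-common-ancestor lineage assignment
#'
#' Retains hits whose bitscore is within `top_percent` of the best hit
#' (score at least `(1 - top_percent) * max`) and returns the longest
#' common prefix of their `;`-separated lineages, or `"unassigned"` when
#' there are no hits or no shared prefix.
#'
#' @param lineages Character vector of `;`-separated lineages.
#' @param bitscores Numeric vector of scores, parallel to `lineages`.
#' @param top_percent Score band as a fraction of the maximum, in (0, 1].
#' @return A single lineage string (possibly `"unassigned"`).
#' @export
lca_assign <- function(lineages, bitscores, top_percent = 0.10) {
  stopifnot(top_percent > 0, top_percent <= 1)
  if (length(lineages) == 0) return("unassigned")
  keep <- bitscores >= (1 - top_percent) * max(bitscores)
  ranks <- strsplit(lineages[keep], ";", fixed = TRUE)
  prefix <- ranks[[1]]
  for (r in ranks[-1]) {
    k <- min(length(prefix), length(r))
    same <- prefix[seq_len(k)] == r[seq_len(k)]
    k <- if (all(same)) k else min(which(!same)) - 1L
    if (k == 0) return("unassigned")
    prefix <- prefix[seq_len(k)]
  }
  paste(prefix, collapse = ";")
}

#' Per-contig LCA assignment over a taxonomy-hit table
#'
#' @param taxhits Data frame with columns `contig_id`, `lineage`, `bitscore`.
#' @param top_percent See [lca_assign()].
#' @return Data frame `contig_id`, `lineage` (one row per contig).
#' @export
lca_assign_all <- function(taxhits, top_percent = 0.10) {
  ids <- sort(unique(taxhits$contig_id))
  lin <- vapply(ids, function(cid) {
    sub <- taxhits[taxhits$contig_id == cid, ]
    lca_assign(sub$lineage, sub$bitscore, top_percent)
  }, character(1))
  data.frame(contig_id = ids, lineage = unname(lin), stringsAsFactors = FALSE)
}

#' Merge viral-contig sets from the two identification routes
#'
#' @param setA,setB Character vectors of contig ids.
#' @return Deduplicated union in stable sorted order.
#' @export
merge_viral_sets <- function(setA, setB) {
  sort(unique(c(setA, setB)))
}

#' Assembly N50
#'
#' The largest length L such that contigs of length at least L together
#' cover at least half of the total assembly length.
#'
#' @param lengths Numeric vector of contig lengths (all positive).
#' @return N50 in bp.
#' @export
compute_n50 <- function(lengths) {
  if (length(lengths) == 0) stop("empty length list")
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}
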