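#' Greedy centroid clustering of predicted proteins
#'
#' Proteins are sorted by length (descending, ties by id) and each joins
#' the earliest-founded centroid with global identity at or above the
#' threshold, otherwise founds a new cluster. Identity is the number of
#' aligned matches from a Needleman-Wunsch global alignment divided by the
#' longer sequence length; identical sequences short-circuit, and a shared
#' 8-mer prefilter skips hopeless pairs.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param id_threshold Identity threshold in (0, 1].
#' @return Data frame `protein_id`, `pc_id` (protein-cluster label, assigned
#'   in founding order).
#' @export
cluster_proteins <- function(proteins, id_threshold = 0.9) {
  stopifnot(id_threshold > 0, id_threshold <= 1)
  if (length(proteins) == 0)
    return(data.frame(protein_id = character(0), pc_id = character(0),
                      stringsAsFactors = FALSE))
  ord <- order(-nchar(proteins), names(proteins))
  ids <- names(proteins)[ord]
  seqs <- unname(proteins[ord])
  exact <- new.env(parent = emptyenv())   # sequence -> centroid index
  cent_seq <- character(0)
  cent_kmers <- list()
  assign_to <- integer(length(seqs))
  kmers8 <- function(s) {
    n <- nchar(s)
    if (n < 8) return(s)
    unique(substring(s, 1:(n - 7), 8:n))
  }
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    hit <- exact[[s]]
    if (!is.null(hit)) {
      assign_to[i] <- hit
      next
    }
    km <- kmers8(s)
    found <- 0L
    for (ci in seq_along(cent_seq)) {
      if (!any(km %in% cent_kmers[[ci]])) next
      if (protein_global_identity(s, cent_seq[ci]) >= id_threshold) {
        found <- ci
        break
      }
    }
    if (found == 0L) {
      cent_seq <- c(cent_seq, s)
      cent_kmers[[length(cent_seq)]] <- km
      found <- length(cent_seq)
    }
    exact[[s]] <- found
    assign_to[i] <- found
  }
  data.frame(protein_id = ids,
             pc_id = sprintf("PC%04d", assign_to),
             stringsAsFactors = FALSE)[order(ids), , drop = FALSE]
}

# global alignment identity: matches / max(length); simple +1/-1 scoring
protein_global_identity <- function(a, b) {
  if (a == b) return(1)
  alpha <- sort(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])))
  sm <- matrix(-1L, length(alpha), length(alpha),
               dimnames = list(alpha, alpha))
  diag(sm) <- 1L
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    substitutionMatrix = sm, gapOpening = 2, gapExtension = 1,
    type = "global")
  Biostrings::nmatch(aln) / max(nchar(a), nchar(b))
}

#' Significance of shared protein-cluster content between two contigs
#'
#' Scores the overlap of the protein-cluster (PC) repertoires of two
#' contigs as `-log10 P(X >= shared)` under a hypergeometric null: drawing
#' `nB` PCs from a universe of `n_total` of which `nA` belong to contig A.
#' Returns 0 when nothing is shared.
#'
#' @param nA,nB PC counts of the two contigs.
#' @param shared Number of PCs present in both.
#' @param n_total Total number of distinct PCs in the dataset.
#' @return Non-negative similarity score (`-log10` survival probability).
#' @export
shared_pc_significance <- function(nA, nB, shared, n_total) {
  if (shared > min(nA, nB) || min(nA, nB) > n_total || min(nA, nB, shared) < 0)
    stop("require shared <= min(nA, nB) <= n_total")
  if (shared == 0) return(0)
  p <- stats::phyper(shared - 1, nA, n_total - nA, nB, lower.tail = FALSE)
  if (p <= 0) return(Inf)
  -log10(p)
}

#' Assign viral contigs to genus-level clusters
#'
#' Builds a gene-sharing graph with an edge wherever the shared-PC
#' significance reaches `score_threshold`, then takes connected components:
#' components of size two or more become genera (labelled `VC_<smallest
#' member id>`), size-one components are `"singleton"`.
#'
#' @param pc_map Data frame with columns `contig_id`, `pc_id` (one row per
#'   gene; a contig's PC set is the distinct `pc_id`s of its genes).
#' @param score_threshold Minimum significance for an edge (> 0).
#' @param contigs Optional character vector of contig ids to include even
#'   when they have no genes (assigned `"singleton"`).
#' @param n_total Optional PC universe size; defaults to the number of
#'   distinct PCs in `pc_map`.
#' @return List with `assignment` (data frame `contig_id`, `genus`) and
#'   `edges` (data frame `contig_a`, `contig_b`, `score`).
#' @export
assign_genera <- function(pc_map, score_threshold = 1, contigs = NULL,
                          n_total = NULL) {
  stopifnot(score_threshold > 0)
  pc_map <- unique(pc_map[, c("contig_id", "pc_id")])
  ids <- sort(unique(c(pc_map$contig_id, contigs)))
  if (length(ids) == 0)
    return(list(assignment = data.frame(contig_id = character(0),
                                        genus = character(0),
                                        stringsAsFactors = FALSE),
                edges = data.frame(contig_a = character(0),
                                   contig_b = character(0),
                                   score = numeric(0))))
  if (is.null(n_total)) n_total <- length(unique(pc_map$pc_id))
  inc <- table(factor(pc_map$contig_id, levels = ids), pc_map$pc_id)
  inc <- matrix(as.integer(inc > 0), nrow = length(ids),
                dimnames = list(ids, colnames(inc)))
  shared <- inc %*% t(inc)
  npc <- rowSums(inc)
  edges <- data.frame(contig_a = character(0), contig_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (length(ids) > 1 && n_total > 0) {
    pairs <- which(upper.tri(shared) & shared > 0, arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      sc <- vapply(seq_len(nrow(pairs)), function(k) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        shared_pc_significance(npc[i], npc[j], shared[i, j], n_total)
      }, numeric(1))
      keep <- sc >= score_threshold
      edges <- data.frame(contig_a = ids[pairs[keep, 1]],
                          contig_b = ids[pairs[keep, 2]],
                          score = sc[keep], stringsAsFactors = FALSE)
    }
  }
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = ids)
  comp <- igraph::components(g)
  genus <- character(length(ids))
  names(genus) <- ids
  for (ci in seq_len(comp$no)) {
    members <- ids[comp$membership == ci]
    genus[members] <- if (length(members) >= 2)
      paste0("VC_", min(members)) else "singleton"
  }
  list(assignment = data.frame(contig_id = ids, genus = unname(genus),
                               stringsAsFactors = FALSE),
       edges = edges)
}

#' Dereplicate contigs at identity and coverage thresholds
#'
#' Greedy longest-first clustering: a contig is absorbed by an existing
#' representative when an anchored ungapped alignment covers at least
#' `cov_threshold` of the shorter sequence at `id_threshold` identity or
#' better; otherwise it founds a new representative. Candidate alignments
#' are anchored on shared 15-mers.
#'
#' @param contigs Named character vector of nucleotide sequences.
#' @param id_threshold Identity over the aligned region (default 0.90).
#' @param cov_threshold Minimum aligned fraction of the shorter sequence
#'   (default 0.80).
#' @return Data frame `contig_id`, `representative_id`.
#' @export
dereplicate <- function(contigs, id_threshold = 0.90, cov_threshold = 0.80) {
  stopifnot(id_threshold > 0, id_threshold <= 1,
            cov_threshold > 0, cov_threshold <= 1)
  if (length(contigs) == 0)
    return(data.frame(contig_id = character(0),
                      representative_id = character(0),
                      stringsAsFactors = FALSE))
  ord <- order(-nchar(contigs), names(contigs))
  ids <- names(contigs)[ord]
  seqs <- unname(contigs[ord])
  reps <- integer(0)
  rep_of <- character(length(seqs))
  for (i in seq_along(seqs)) {
    assigned <- NA_character_
    for (ri in reps) {
      if (absorbed_by(seqs[i], seqs[ri], id_threshold, cov_threshold)) {
        assigned <- ids[ri]
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, i)
      assigned <- ids[i]
    }
    rep_of[i] <- assigned
  }
  out <- data.frame(contig_id = ids, representative_id = rep_of,
                    stringsAsFactors = FALSE)
  out[order(out$contig_id), , drop = FALSE]
}

# TRUE when `query` (the shorter) aligns to `rep` at the thresholds,
# anchored on a shared 15-mer; ungapped evaluation on the anchor diagonal
absorbed_by <- function(query, rep, id_threshold, cov_threshold) {
  nq <- nchar(query)
  if (nq < 15) return(FALSE)
  qi <- seq_ints(query)
  ri <- seq_ints(rep)
  nr <- length(ri)
  tried <- integer(0)
  starts <- unique(round(seq(1, nq - 14, length.out = min(40, nq - 14))))
  for (s in starts) {
    anchor <- substr(query, s, s + 14)
    hits <- gregexpr(anchor, rep, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    for (h in hits[seq_len(min(3, length(hits)))]) {
      d <- h - s                      # rep offset of query position 1 - 1
      if (d %in% tried) next
      tried <- c(tried, d)
      q0 <- max(1, 1 - d)
      q1 <- min(nq, nr - d)
      ov <- q1 - q0 + 1
      if (ov < cov_threshold * nq) next
      mism <- sum(qi[q0:q1] != ri[(q0 + d):(q1 + d)])
      if ((ov - mism) / ov >= id_threshold) return(TRUE)
    }
  }
  FALSE
}
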