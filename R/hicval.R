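#' Deconvolve a Hi-C contact table into virus-host links
#'
#' For each virus, candidate bins are those with at least `min_count`
#' contacts; among candidates, every bin whose count is within
#' `dominance_ratio` of the top count is assigned (co-assignment), so a
#' single dominant bin is assigned alone and near-ties are kept together.
#' Viruses with no candidate bin are unassigned.
#'
#' @param contacts Data frame `virus_id`, `bin_id`, `count`.
#' @param min_count Contact-count floor for a candidate bin (>= 1).
#' @param dominance_ratio Maximum top-to-assigned count ratio (>= 1).
#' @return Data frame `virus_id`, `bin_id`, `count`.
#' @export
hic_deconvolve <- function(contacts, min_count = 5L, dominance_ratio = 2) {
  stopifnot(min_count >= 1, dominance_ratio >= 1)
  out <- lapply(sort(unique(contacts$virus_id)), function(v) {
    sub <- contacts[contacts$virus_id == v & contacts$count >= min_count, ]
    if (nrow(sub) == 0) return(NULL)
    top <- max(sub$count)
    keep <- sub$count * dominance_ratio >= top
    data.frame(virus_id = v, bin_id = sub$bin_id[keep],
               count = sub$count[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(
    data.frame(virus_id = character(0), bin_id = character(0),
               count = numeric(0), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Compare CRISPR-predicted links with Hi-C deconvolution
#'
#' Each CRISPR link is classified as undetected (virus absent from the
#' Hi-C link set), same (its bin is among the virus's Hi-C bins) or
#' different. Precision is `100 * same / (same + different)`, rounded to
#' the nearest integer percent (undetected links do not enter the
#' denominator; precision is `NA` when nothing is detected).
#'
#' @param crispr_links Data frame `virus_id`, `bin_id`.
#' @param hic_links Data frame `virus_id`, `bin_id` (multiple bins per
#'   virus allowed).
#' @return List with `n_crispr`, `n_detected`, `n_same`, `n_different`,
#'   `precision` (integer percent or `NA`), `precision_unrounded`, and
#'   `detail` (the per-link classification).
#' @export
compare_with_crispr <- function(crispr_links, hic_links) {
  cls <- character(nrow(crispr_links))
  for (i in seq_len(nrow(crispr_links))) {
    v <- crispr_links$virus_id[i]
    bins <- hic_links$bin_id[hic_links$virus_id == v]
    cls[i] <- if (length(bins) == 0) "undetected"
    else if (crispr_links$bin_id[i] %in% bins) "same" else "different"
  }
  n_same <- sum(cls == "same")
  n_diff <- sum(cls == "different")
  n_det <- n_same + n_diff
  prec <- if (n_det > 0) 100 * n_same / n_det else NA_real_
  list(n_crispr = nrow(crispr_links), n_detected = n_det,
       n_same = n_same, n_different = n_diff,
       precision = if (is.na(prec)) NA_real_ else round(prec),
       precision_unrounded = prec,
       detail = cbind(crispr_links,
                      data.frame(status = cls, stringsAsFactors = FALSE)))
}

#' Hi-C comparison precision from link counts
#'
#' @param n_same,n_different Counts of consistent and conflicting detected
#'   links.
#' @return Rounded integer percent (`NA` when both are zero).
#' @export
hic_precision <- function(n_same, n_different) {
  if (n_same + n_different == 0) return(NA_real_)
  round(100 * n_same / (n_same + n_different))
}
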