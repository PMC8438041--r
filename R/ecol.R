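#' Average normalized coverage of a contig
#'
#' Aligned bases divided by contig length (average depth), then divided by
#' the dataset size for cross-sample normalization.
#'
#' @param aligned_bases Total aligned bases on the contig.
#' @param contig_length Contig length (bp).
#' @param dataset_size Sample dataset size (bp).
#' @return Normalized coverage (vectorized).
#' @export
avg_norm_coverage <- function(aligned_bases, contig_length, dataset_size) {
  (aligned_bases / contig_length) / dataset_size
}

#' Map reads to contigs with exact 20-mer seeds
#'
#' A toy read mapper for synthetic reads: candidate placements are
#' anchored on exact 20-mer seeds taken at a few read offsets (both
#' strands), evaluated ungapped. A read is counted iff at least
#' `length_fraction` of its length aligns at `similarity` identity or
#' better; the aligned portion accumulates into `aligned_bases`. Each read
#' contributes at most one placement.
#'
#' @param reads Named character vector of reads (length >= 20 bp).
#' @param contigs Named character vector of contigs.
#' @param length_fraction Minimum aligned fraction of the read length.
#' @param similarity Minimum identity over the aligned portion.
#' @param detail When `TRUE`, also return per-contig aligned intervals
#'   (0-based half-open) for horizontal-coverage computation.
#' @return Data frame `contig_id`, `n_reads`, `aligned_bases`; with
#'   `detail = TRUE` a list with elements `coverage` and `intervals`.
#' @export
toy_map_reads <- function(reads, contigs, length_fraction = 0.8,
                          similarity = 0.9, detail = FALSE) {
  cov <- stats::setNames(numeric(length(contigs)), names(contigs))
  nrd <- stats::setNames(integer(length(contigs)), names(contigs))
  ivals <- list()
  if (length(reads) > 0 && length(contigs) > 0) {
    cint <- lapply(contigs, seq_ints)
    rlen <- nchar(reads)
    placed <- logical(length(reads))
    offsets <- c(1L, 66L, 131L)
    for (strand in c("+", "-")) {
      rs_all <- if (strand == "+") unname(reads) else revcomp(reads)
      for (off in offsets) {
        usable <- which(rlen >= off + 19L)
        if (length(usable) == 0) next
        if (all(placed[usable])) next
        seeds <- substr(rs_all[usable], off, off + 19L)
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
        for (ctg in names(contigs)) {
          clen <- nchar(contigs[[ctg]])
          m <- Biostrings::matchPDict(pd, Biostrings::DNAString(contigs[[ctg]]))
          starts <- IRanges::start(m)
          for (k in which(lengths(starts) > 0)) {
            ri <- usable[k]
            if (placed[ri]) next
            rl <- rlen[ri]
            rint <- seq_ints(rs_all[ri])
            for (pos in starts[[k]]) {
              cpos <- pos - off            # 0-based contig offset of read pos 1
              a0 <- max(0L, -cpos)
              a1 <- min(rl, clen - cpos)
              ov <- a1 - a0
              if (ov < length_fraction * rl - 1e-9) next
              mism <- sum(rint[(a0 + 1):a1] !=
                            cint[[ctg]][(a0 + 1 + cpos):(a1 + cpos)])
              if ((ov - mism) / ov < similarity - 1e-9) next
              placed[ri] <- TRUE
              cov[ctg] <- cov[ctg] + ov
              nrd[ctg] <- nrd[ctg] + 1L
              if (detail)
                ivals[[length(ivals) + 1L]] <-
                  data.frame(contig_id = ctg, start = cpos + a0,
                             end = cpos + a1, stringsAsFactors = FALSE)
              break
            }
          }
        }
      }
    }
  }
  out <- data.frame(contig_id = names(contigs), n_reads = unname(nrd),
                    aligned_bases = unname(cov), stringsAsFactors = FALSE)
  if (!detail) return(out)
  intervals <- if (length(ivals)) do.call(rbind, ivals)
  else data.frame(contig_id = character(0), start = integer(0),
                  end = integer(0), stringsAsFactors = FALSE)
  list(coverage = out, intervals = intervals)
}

# fraction of a contig covered by at least one aligned interval
horizontal_coverage <- function(intervals, contig_id, contig_length) {
  sub <- intervals[intervals$contig_id == contig_id, , drop = FALSE]
  if (nrow(sub) == 0) return(0)
  red <- IRanges::reduce(IRanges::IRanges(start = sub$start + 1L,
                                          end = sub$end))
  sum(IRanges::width(red)) / contig_length
}

#' Relative abundance matrix at the genus level
#'
#' Converts a per-contig coverage table into normalized coverages, takes
#' each contig's share of its sample's total, and sums shares within
#' genera. Singleton contigs keep individual entities
#' (`singleton:<contig>`), so sample columns always sum to one over
#' detected entities.
#'
#' @param coverage Data frame `contig_id`, `sample_id`, `aligned_bases`,
#'   `dataset_size`.
#' @param contig_lengths Named vector of contig lengths.
#' @param genus_map Named character vector contig -> genus label
#'   (`"singleton"` allowed).
#' @return List with `abundance` (genus x sample matrix) and `presence`
#'   (logical matrix, abundance > 0).
#' @export
relative_abundance <- function(coverage, contig_lengths, genus_map) {
  gm <- genus_map
  sing <- names(gm)[gm == "singleton"]
  gm[sing] <- paste0("singleton:", sing)
  samples <- sort(unique(coverage$sample_id))
  genera <- sort(unique(unname(gm[unique(coverage$contig_id)])))
  ab <- matrix(0, nrow = length(genera), ncol = length(samples),
               dimnames = list(genera, samples))
  for (s in samples) {
    sub <- coverage[coverage$sample_id == s, ]
    nc <- avg_norm_coverage(sub$aligned_bases,
                            contig_lengths[sub$contig_id],
                            sub$dataset_size)
    tot <- sum(nc)
    if (tot == 0) next
    share <- nc / tot
    agg <- tapply(share, gm[sub$contig_id], sum)
    ab[names(agg), s] <- agg
  }
  list(abundance = ab, presence = ab > 0)
}

#' Shannon diversity index (natural log)
#'
#' @param p Abundance vector summing to one (zeros dropped).
#' @return H' in nats.
#' @export
shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Pielou evenness index
#'
#' @param p Abundance vector summing to one.
#' @return J' = H' / ln(S) with S the number of nonzero entries (`NA` when
#'   S = 1).
#' @export
pielou <- function(p) {
  s <- sum(p > 0)
  if (s <= 1) return(NA_real_)
  shannon(p) / log(s)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' @param u,v Non-negative vectors of equal length.
#' @return `sum(|u - v|) / sum(u + v)`.
#' @export
bray_curtis <- function(u, v) {
  sum(abs(u - v)) / sum(u + v)
}

#' Bray-Curtis dissimilarity matrix over samples
#'
#' @param mat Entity x sample abundance matrix.
#' @return Symmetric sample x sample dissimilarity matrix.
#' @export
bray_curtis_matrix <- function(mat) {
  s <- ncol(mat)
  D <- matrix(0, s, s, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(s)) for (j in seq_len(s)) {
    if (j > i) D[i, j] <- D[j, i] <- bray_curtis(mat[, i], mat[, j])
  }
  D
}

#' Principal coordinate analysis
#'
#' Metric ordination via eigendecomposition of the double-centred
#' `-D^2 / 2` matrix (classical MDS). Negative eigenvalues are reported,
#' not dropped.
#'
#' @param D Dissimilarity matrix or `dist` object.
#' @param k Number of coordinate axes.
#' @return List with `points` (n x k coordinates) and `eig` (all
#'   eigenvalues).
#' @export
pcoa_ord <- function(D, k = 2) {
  fit <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  list(points = fit$points, eig = fit$eig)
}

#' Rarefaction curve of detected contigs
#'
#' Subsamples reads without replacement at each fraction, remaps with
#' [toy_map_reads()] and counts contigs meeting the detection rule (at
#' least `min_reads` mapped reads and horizontal coverage at least
#' `min_cov` of the contig length).
#'
#' @param reads Named character vector of reads for one sample.
#' @param contigs Named character vector of contigs.
#' @param fractions Numeric vector of subsampling fractions in [0, 1].
#' @param min_reads Detection rule: minimum mapped reads.
#' @param min_cov Detection rule: minimum horizontal coverage fraction.
#' @param seed Integer seed for the subsampling.
#' @return Data frame `fraction`, `n_reads`, `n_detected`.
#' @export
rarefaction_curve <- function(reads, contigs, fractions,
                              min_reads = 1L, min_cov = 0.10, seed = 1L) {
  with_seed(seed, {
    out <- lapply(fractions, function(f) {
      nr <- floor(f * length(reads))
      sub <- if (nr > 0) reads[sort(sample.int(length(reads), nr))]
      else character(0)
      det <- 0L
      if (nr > 0) {
        mp <- toy_map_reads(sub, contigs, detail = TRUE)
        for (ctg in names(contigs)) {
          n_mapped <- mp$coverage$n_reads[mp$coverage$contig_id == ctg]
          if (n_mapped >= min_reads &&
              horizontal_coverage(mp$intervals, ctg,
                                  nchar(contigs[[ctg]])) >= min_cov)
            det <- det + 1L
        }
      }
      data.frame(fraction = f, n_reads = nr, n_detected = det)
    })
    do.call(rbind, out)
  })
}

#' Core and shared genera across samples (UpSet counts)
#'
#' Computes exclusive intersection counts for every nonempty sample
#' subset: a genus counts towards exactly the subset of samples it is
#' present in. The core set is the genera present in all samples.
#'
#' @param presence Logical genus x sample matrix.
#' @return List with `core` (character vector of core genera) and
#'   `counts` (data frame `subset`, `n_samples`, `count` over all
#'   `2^S - 1` nonempty subsets).
#' @export
core_shared_genera <- function(presence) {
  s <- ncol(presence)
  samples <- colnames(presence)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(s))
  pat <- if (nrow(presence) > 0)
    as.integer(presence %*% 2^(seq_len(s) - 1)) else integer(0)
  masks <- seq_len(2^s - 1)
  counts <- data.frame(
    subset = vapply(masks, function(m)
      paste(samples[bitwAnd(m, 2^(seq_len(s) - 1)) > 0], collapse = "&"),
      character(1)),
    n_samples = vapply(masks, function(m)
      sum(bitwAnd(m, 2^(seq_len(s) - 1)) > 0), numeric(1)),
    count = vapply(masks, function(m) sum(pat == m), numeric(1)),
    stringsAsFactors = FALSE)
  core <- rownames(presence)[pat == 2^s - 1]
  list(core = core, counts = counts)
}

#' Rank-abundance table
#'
#' @param p Named abundance vector.
#' @param threshold Abundance threshold for the crossing rank.
#' @return List with `table` (data frame `rank`, `genus`, `abundance`,
#'   sorted descending, ties by label) and `crossing_rank` (first rank
#'   with abundance below `threshold`; `length(p) + 1` when none).
#' @export
rank_abundance <- function(p, threshold = 0.001) {
  ord <- order(-p, names(p))
  tab <- data.frame(rank = seq_along(p), genus = names(p)[ord],
                    abundance = unname(p[ord]), stringsAsFactors = FALSE)
  below <- which(tab$abundance < threshold)
  list(table = tab,
       crossing_rank = if (length(below)) below[1] else length(p) + 1L)
}
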