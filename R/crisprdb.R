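#' Detector parameters for CRISPR repeat-spacer arrays
#'
#' Defaults follow the published defaults of the CRISPR Recognition Tool:
#' at least 3 repeat copies, repeat length 19-38 bp, spacer length
#' 19-48 bp, and an 8-bp seed window.
#'
#' @param min_repeats Minimum number of repeat copies per array.
#' @param repeat_len_range Allowed repeat length range (bp).
#' @param spacer_len_range Allowed spacer length range (bp).
#' @param seed_window Exact k-mer seed length used to anchor candidate
#'   repeats.
#' @return A list of class `crt_params`.
#' @export
crt_params <- function(min_repeats = 3L, repeat_len_range = c(19L, 38L),
                       spacer_len_range = c(19L, 48L), seed_window = 8L) {
  structure(list(min_repeats = as.integer(min_repeats),
                 repeat_len_range = as.integer(repeat_len_range),
                 spacer_len_range = as.integer(spacer_len_range),
                 seed_window = as.integer(seed_window)),
            class = "crt_params")
}

#' Detect CRISPR repeat-spacer arrays in a genome
#'
#' Scans for exact k-mer seeds recurring with a tandem period compatible
#' with a repeat of length 19-38 bp separated by spacers of 19-48 bp, then
#' extends each anchor set to the maximal sequence shared exactly by all
#' copies (exact-repeat mode). Arrays need at least `min_repeats` copies;
#' junctions whose spacer falls outside the allowed range split the array.
#' Returned arrays are non-overlapping, reported left to right, with
#' 0-based half-open spacer coordinates.
#'
#' @param genome Nucleotide string (uppercase ACGT).
#' @param params A [crt_params()] object.
#' @return A list of arrays; each is a list with `repeat_seq`,
#'   `repeat_len`, `n_repeats`, `repeat_starts` (0-based), and `spacers`
#'   (data frame `sequence`, `start`, `end`).
#' @export
find_crispr_arrays <- function(genome, params = crt_params()) {
  w <- params$seed_window
  n <- nchar(genome)
  rmin <- params$repeat_len_range[1]; rmax <- params$repeat_len_range[2]
  smin <- params$spacer_len_range[1]; smax <- params$spacer_len_range[2]
  if (n < params$min_repeats * rmin + (params$min_repeats - 1) * smin)
    return(list())
  gi <- seq_ints(genome)
  kpos <- split(seq_len(n - w + 1),
                substring(genome, 1:(n - w + 1), w:n))
  kpos <- kpos[lengths(kpos) >= params$min_repeats]
  pmin_ <- rmin + smin
  pmax_ <- rmax + smax
  cand <- list()
  seen <- character(0)
  for (pos in kpos) {
    d <- diff(pos)
    ok <- d >= pmin_ & d <= pmax_
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    for (j in which(r$values & r$lengths >= params$min_repeats - 1L)) {
      anchors <- pos[(ends[j] - r$lengths[j] + 1L):(ends[j] + 1L)]
      for (arr in build_arrays(gi, genome, anchors, w, params)) {
        key <- paste(arr$repeat_starts, collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        cand[[length(cand) + 1L]] <- arr
      }
    }
  }
  if (length(cand) == 0) return(list())
  ## resolve overlaps: prefer candidates with more repeat copies, then
  ## longer span (a seed straddling a repeat boundary can found a shorter
  ## sub-array shifted by a base); report kept arrays left to right
  first <- vapply(cand, function(a) a$repeat_starts[1], numeric(1))
  span <- vapply(cand, function(a)
    a$repeat_starts[a$n_repeats] + a$repeat_len - a$repeat_starts[1],
    numeric(1))
  nrep <- vapply(cand, function(a) a$n_repeats, numeric(1))
  cand <- cand[order(-nrep, -span, first)]
  kept <- list()
  spans <- matrix(numeric(0), ncol = 2)
  for (a in cand) {
    a_start <- a$repeat_starts[1]
    a_end <- a$repeat_starts[a$n_repeats] + a$repeat_len
    if (nrow(spans) == 0 ||
        all(a_end <= spans[, 1] | a_start >= spans[, 2])) {
      kept[[length(kept) + 1L]] <- a
      spans <- rbind(spans, c(a_start, a_end))
    }
  }
  kept[order(vapply(kept, function(a) a$repeat_starts[1], numeric(1)))]
}

# extend an anchor set to the maximal exactly-shared repeat and validate;
# returns a list of zero or more arrays (junction splits may yield several)
build_arrays <- function(gi, genome, anchors, w, params, depth = 0L) {
  rmin <- params$repeat_len_range[1]; rmax <- params$repeat_len_range[2]
  smin <- params$spacer_len_range[1]; smax <- params$spacer_len_range[2]
  n <- length(gi)
  k <- length(anchors)
  ## simultaneous maximal extension across all copies
  l <- 0L
  while (anchors[1] - l - 1L >= 1L &&
         length(unique(gi[anchors - l - 1L])) == 1L && l + w < rmax + 20L)
    l <- l + 1L
  r <- 0L
  while (anchors[k] + w + r <= n &&
         length(unique(gi[anchors + w + r])) == 1L && l + w + r < rmax + 20L)
    r <- r + 1L
  rlen <- l + w + r
  if (rlen < rmin || rlen > rmax) {
    ## a flanking anchor outside the true array can poison the extension;
    ## retry without it
    if (k > params$min_repeats && depth < 4L) {
      alt <- c(build_arrays(gi, genome, anchors[-1], w, params, depth + 1L),
               build_arrays(gi, genome, anchors[-k], w, params, depth + 1L))
      return(alt)
    }
    return(list())
  }
  starts <- anchors - l               # 1-based repeat starts
  gaps <- diff(starts) - rlen         # spacer lengths
  bad <- which(gaps < smin | gaps > smax)
  if (length(bad) > 0) {
    ## split at bad junctions into sub-runs
    grp <- cumsum(c(1L, seq_len(k - 1L) %in% bad))
    out <- list()
    for (g in split(seq_len(k), grp)) {
      if (length(g) >= params$min_repeats && depth < 4L)
        out <- c(out, build_arrays(gi, genome, anchors[g], w, params,
                                   depth + 1L))
    }
    return(out)
  }
  spacer_start0 <- starts[-k] + rlen - 1L      # 0-based
  spacer_end0 <- starts[-1] - 1L
  list(list(
    repeat_seq = substr(genome, starts[1], starts[1] + rlen - 1L),
    repeat_len = rlen,
    n_repeats = k,
    repeat_starts = starts - 1L,
    spacers = data.frame(
      sequence = substring(genome, spacer_start0 + 1L, spacer_end0),
      start = spacer_start0, end = spacer_end0,
      stringsAsFactors = FALSE)))
}

#' Build a CRISPR spacer database with host taxonomy
#'
#' Runs the array detector on each genome and emits one record per
#' detected spacer, deduplicating identical spacer sequences within a
#' genome but never across genomes (so cross-domain queries stay
#' answerable).
#'
#' @param genomes Named character vector of genome sequences.
#' @param lineage Data frame with columns `genome_id`, `domain`, `phylum`,
#'   `class`, `order`, `family`, `genus`; every genome must have a row.
#' @param params A [crt_params()] object.
#' @return Data frame with columns `spacer_id`, `sequence`, `genome_id`,
#'   `start`, `end` (0-based half-open), and the lineage ranks.
#' @export
build_spacer_db <- function(genomes, lineage, params = crt_params()) {
  missing <- setdiff(names(genomes), lineage$genome_id)
  if (length(missing) > 0)
    stop("no lineage row for genome(s): ", paste(missing, collapse = ", "))
  recs <- list()
  for (g in names(genomes)) {
    arrays <- find_crispr_arrays(genomes[[g]], params)
    if (length(arrays) == 0) next
    sp <- do.call(rbind, lapply(seq_along(arrays), function(ai) {
      s <- arrays[[ai]]$spacers
      s$array <- ai
      s
    }))
    sp <- sp[!duplicated(sp$sequence), , drop = FALSE]
    lin <- lineage[match(g, lineage$genome_id), ]
    recs[[g]] <- data.frame(
      spacer_id = sprintf("%s_a%d_s%02d", g, sp$array, seq_len(nrow(sp))),
      sequence = sp$sequence, genome_id = g,
      start = sp$start, end = sp$end,
      domain = lin$domain, phylum = lin$phylum, class = lin$class,
      order = lin$order, family = lin$family, genus = lin$genus,
      stringsAsFactors = FALSE)
  }
  if (length(recs) == 0)
    return(data.frame(spacer_id = character(0), sequence = character(0),
                      genome_id = character(0), start = integer(0),
                      end = integer(0), domain = character(0),
                      phylum = character(0), class = character(0),
                      order = character(0), family = character(0),
                      genus = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
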