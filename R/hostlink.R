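#' Thresholds for spacer-protospacer matching
#'
#' Defaults reproduce the tuned short-read BLAST settings used for host
#' prediction: identity at least 97% over the alignment, alignment covering
#' at least 90% of the spacer, and at most one mismatch. Word size 11 is
#' the seed length; with ungapped alignment and at most one mismatch any
#' passing alignment of a spacer of 19 bp or more necessarily contains an
#' exact 11-mer, so seeding loses no sensitivity.
#'
#' @param identity Minimum identity over the alignment length.
#' @param coverage Minimum alignment length as a fraction of spacer length.
#' @param max_mismatch Maximum mismatches in the alignment.
#' @param word_size Exact seed length.
#' @return A list of class `match_thresholds`.
#' @export
match_thresholds <- function(identity = 0.97, coverage = 0.90,
                             max_mismatch = 1L, word_size = 11L) {
  structure(list(identity = identity, coverage = coverage,
                 max_mismatch = as.integer(max_mismatch),
                 word_size = as.integer(word_size)),
            class = "match_thresholds")
}

# shared deterministic ordering of candidate alignments:
# matching bases desc, identity desc, + strand first, leftmost, then
# spacer trim offset
order_alignments <- function(df) {
  order(-df$matches, -df$identity, df$strand != "+", df$contig_start,
        df$spacer_start)
}

#' Match one CRISPR spacer against a viral contig
#'
#' Seeded ungapped alignment on both strands (the reverse complement of
#' the spacer is scanned for the minus strand). Alignments may trim spacer
#' ends (local semantics): identity is computed over the alignment length,
#' coverage over the full spacer length. Among alignments passing all
#' three thresholds the one with most matching bases is returned; ties go
#' to the leftmost hit on the plus strand.
#'
#' @param spacer Spacer sequence (uppercase ACGT, length >= `word_size`).
#' @param contig Contig sequence.
#' @param thresholds A [match_thresholds()] object.
#' @return One-row data frame with `alignment_length`, `mismatches`,
#'   `matches`, `identity`, `spacer_coverage`, `contig_start`,
#'   `contig_end` (0-based half-open), `strand`, `spacer_start`; or `NULL`
#'   when no alignment passes.
#' @export
match_spacer <- function(spacer, contig, thresholds = match_thresholds()) {
  n <- nchar(spacer)
  if (n < thresholds$word_size)
    stop("spacer shorter than the seed word size")
  cand <- rbind(
    scan_strand(spacer, contig, "+", thresholds),
    scan_strand(revcomp(spacer), contig, "-", thresholds))
  if (is.null(cand) || nrow(cand) == 0) return(NULL)
  cand[order_alignments(cand)[1], , drop = FALSE]
}

# enumerate passing ungapped alignments of `sp` on the forward text of
# `contig`; `strand` only labels the output
scan_strand <- function(sp, contig, strand, th) {
  n <- nchar(sp)
  m <- nchar(contig)
  w <- th$word_size
  minL <- as.integer(ceiling(th$coverage * n - 1e-9))
  if (m < minL) return(NULL)
  spi <- seq_ints(sp)
  ci <- seq_ints(contig)
  diags <- integer(0)
  for (k in 1:(n - w + 1)) {
    hits <- gregexpr(substr(sp, k, k + w - 1), contig, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    diags <- c(diags, hits - k)       # 0-based contig offset of spacer pos 1
  }
  diags <- unique(diags)
  if (length(diags) == 0) return(NULL)
  rows <- list()
  for (d in diags) {
    i0 <- max(0L, -d)                 # 0-based spacer overlap range [i0, i1)
    i1 <- min(n, m - d)
    if (i1 - i0 < minL) next
    neq <- as.integer(spi[(i0 + 1):i1] != ci[(i0 + 1 + d):(i1 + d)])
    cum <- c(0L, cumsum(neq))
    for (s in i0:(i1 - minL)) {
      for (L in minL:(i1 - s)) {
        mm <- cum[s + L - i0 + 1L] - cum[s - i0 + 1L]
        if (mm > th$max_mismatch) next
        if (L - mm < th$identity * L - 1e-9) next
        rows[[length(rows) + 1L]] <- c(s = s, L = L, mm = mm, d = d)
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  x <- do.call(rbind, rows)
  data.frame(alignment_length = x[, "L"], mismatches = x[, "mm"],
             matches = x[, "L"] - x[, "mm"],
             identity = (x[, "L"] - x[, "mm"]) / x[, "L"],
             spacer_coverage = x[, "L"] / n,
             contig_start = x[, "s"] + x[, "d"],
             contig_end = x[, "s"] + x[, "d"] + x[, "L"],
             strand = strand, spacer_start = x[, "s"],
             stringsAsFactors = FALSE)
}

#' Brute-force reference matcher
#'
#' Exhaustive sliding-window enumeration of every ungapped alignment (all
#' contig offsets, all spacer trims with alignment length at least the
#' coverage floor, both strands), with the same thresholds and tie-break
#' as [match_spacer()]. Quadratic and intended as an independent oracle
#' for verification at small scale.
#'
#' @inheritParams match_spacer
#' @return Same contract as [match_spacer()].
#' @export
match_spacer_oracle <- function(spacer, contig,
                                thresholds = match_thresholds()) {
  n <- nchar(spacer)
  if (n < thresholds$word_size)
    stop("spacer shorter than the seed word size")
  m <- nchar(contig)
  minL <- as.integer(ceiling(thresholds$coverage * n - 1e-9))
  ci <- seq_ints(contig)
  all_rows <- list()
  for (strand in c("+", "-")) {
    sp <- if (strand == "+") spacer else revcomp(spacer)
    spi <- seq_ints(sp)
    for (L in minL:n) {
      if (L > m) next
      for (s in 0:(n - L)) {
        win <- spi[(s + 1):(s + L)]
        mis <- integer(m - L + 1)
        for (k in seq_len(L)) {
          mis <- mis + (ci[k:(m - L + k)] != win[k])
        }
        pass <- which(mis <= thresholds$max_mismatch &
                        (L - mis) >= thresholds$identity * L - 1e-9)
        for (j in pass) {
          all_rows[[length(all_rows) + 1L]] <- data.frame(
            alignment_length = L, mismatches = mis[j],
            matches = L - mis[j], identity = (L - mis[j]) / L,
            spacer_coverage = L / n, contig_start = j - 1L,
            contig_end = j - 1L + L, strand = strand, spacer_start = s,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(all_rows) == 0) return(NULL)
  cand <- do.call(rbind, all_rows)
  cand[order_alignments(cand)[1], , drop = FALSE]
}

#' Predict hosts of viral contigs from a spacer database
#'
#' Every spacer is matched against every contig; passing matches are
#' collapsed to one link per (contig, host genome) keeping the best match,
#' and the globally best hit per contig is flagged primary (matching bases
#' desc, identity desc, spacer id asc).
#'
#' @param contigs Named character vector of viral contig sequences.
#' @param spacer_db Spacer database from [build_spacer_db()].
#' @param thresholds A [match_thresholds()] object.
#' @return Data frame of virus-host links with the match statistics,
#'   lineage ranks and a `primary` flag.
#' @export
predict_hosts <- function(contigs, spacer_db,
                          thresholds = match_thresholds()) {
  empty <- data.frame(contig_id = character(0), genome_id = character(0),
                      spacer_id = character(0), domain = character(0),
                      genus = character(0), alignment_length = integer(0),
                      mismatches = integer(0), matches = integer(0),
                      identity = numeric(0), spacer_coverage = numeric(0),
                      contig_start = integer(0), contig_end = integer(0),
                      strand = character(0), primary = logical(0),
                      stringsAsFactors = FALSE)
  if (length(contigs) == 0 || nrow(spacer_db) == 0) return(empty)
  hits <- list()
  for (v in names(contigs)) {
    for (i in seq_len(nrow(spacer_db))) {
      if (nchar(spacer_db$sequence[i]) < thresholds$word_size) next
      m <- match_spacer(spacer_db$sequence[i], contigs[[v]], thresholds)
      if (is.null(m)) next
      m$contig_id <- v
      m$spacer_id <- spacer_db$spacer_id[i]
      m$genome_id <- spacer_db$genome_id[i]
      m$domain <- spacer_db$domain[i]
      m$genus <- spacer_db$genus[i]
      hits[[length(hits) + 1L]] <- m
    }
  }
  if (length(hits) == 0) return(empty)
  hits <- do.call(rbind, hits)
  ## best hit per (contig, genome)
  ord <- order(hits$contig_id, hits$genome_id, -hits$matches,
               -hits$identity, hits$spacer_id)
  hits <- hits[ord, ]
  hits <- hits[!duplicated(hits[, c("contig_id", "genome_id")]), ]
  ## primary flag: globally best hit per contig
  ord2 <- order(hits$contig_id, -hits$matches, -hits$identity,
                hits$spacer_id)
  hits <- hits[ord2, ]
  hits$primary <- !duplicated(hits$contig_id)
  out <- hits[, c("contig_id", "genome_id", "spacer_id", "domain", "genus",
                  "alignment_length", "mismatches", "matches", "identity",
                  "spacer_coverage", "contig_start", "contig_end", "strand",
                  "primary")]
  rownames(out) <- NULL
  out
}

#' Benchmark matching thresholds against references with known hosts
#'
#' For each grid point, precision is the percentage of predictions whose
#' host genus equals the reference virus's known genus, and recall the
#' percentage of reference viruses with a correct-genus prediction
#' (`recall_any` counts viruses with any prediction).
#'
#' @param ref_viruses Named character vector of reference virus sequences.
#' @param known_genus Known host genus per virus: a named character vector,
#'   or a named list of genus vectors for viruses with several known hosts
#'   (a prediction is correct when its genus is among them).
#' @param spacer_db Spacer database.
#' @param grid Data frame with columns `identity`, `coverage`,
#'   `max_mismatch` (one row per threshold combination).
#' @return Data frame with the grid columns plus `n_predictions`,
#'   `precision`, `recall`, `recall_any` (precision `NA` when there are no
#'   predictions).
#' @export
benchmark_thresholds <- function(ref_viruses, known_genus, spacer_db, grid) {
  stopifnot(all(names(ref_viruses) %in% names(known_genus)))
  if (!is.list(known_genus)) known_genus <- as.list(known_genus)
  out <- grid
  out$n_predictions <- NA_integer_
  out$precision <- NA_real_
  out$recall <- NA_real_
  out$recall_any <- NA_real_
  nv <- length(ref_viruses)
  for (r in seq_len(nrow(grid))) {
    th <- match_thresholds(identity = grid$identity[r],
                           coverage = grid$coverage[r],
                           max_mismatch = grid$max_mismatch[r])
    links <- predict_hosts(ref_viruses, spacer_db, th)
    out$n_predictions[r] <- nrow(links)
    if (nrow(links) > 0) {
      correct <- vapply(seq_len(nrow(links)), function(i)
        links$genus[i] %in% known_genus[[links$contig_id[i]]], logical(1))
      out$precision[r] <- 100 * sum(correct) / nrow(links)
      out$recall[r] <- 100 *
        length(unique(links$contig_id[correct])) / nv
      out$recall_any[r] <- 100 * length(unique(links$contig_id)) / nv
    } else {
      out$recall[r] <- 0
      out$recall_any[r] <- 0
    }
  }
  out
}

#' Random-sequence null recall
#'
#' Generates replicate sets of random sequences matching a length
#' distribution and reports the mean fraction of sequences with at least
#' one passing spacer hit -- the rate at which host links arise by chance.
#'
#' @param spacer_db Spacer database.
#' @param n_seqs Number of random sequences per replicate.
#' @param lengths Vector of sequence lengths to sample from.
#' @param thresholds A [match_thresholds()] object.
#' @param n_replicates Number of replicate databases.
#' @param seed Integer seed. Replicates run on streams derived from this
#'   seed by an intermediate scrambling draw, so the null sequences are
#'   decorrelated from any synthetic community generated with the same
#'   seed (replaying the generator's base stream would plant real
#'   protospacers into the "random" pool).
#' @return Mean fraction in [0, 1] of random sequences with a hit.
#' @export
random_null_recall <- function(spacer_db, n_seqs, lengths,
                               thresholds = match_thresholds(),
                               n_replicates = 3L, seed = 1L) {
  stopifnot(n_seqs >= 1)
  if (nrow(spacer_db) == 0) return(0)
  rep_seeds <- with_seed(seed, sample.int(2147483646L, n_replicates + 1L))
  fr <- vapply(seq_len(n_replicates), function(rep_i) {
    with_seed(rep_seeds[rep_i + 1L], {
      hit <- vapply(seq_len(n_seqs), function(i) {
        s <- random_dna(sample(rep(lengths, 2), 1))
        for (j in seq_len(nrow(spacer_db))) {
          if (nchar(spacer_db$sequence[j]) < thresholds$word_size) next
          if (!is.null(match_spacer(spacer_db$sequence[j], s, thresholds)))
            return(TRUE)
        }
        FALSE
      }, logical(1))
      mean(hit)
    })
  }, numeric(1))
  mean(fr)
}

#' Erroneous-association rate from the random null
#'
#' The fraction of observed host associations expected to be spurious:
#' `100 * random_recall / observed_recall`, both inputs in percent.
#'
#' @param random_recall Random-null recall, percent.
#' @param observed_recall Observed recall, percent (> 0).
#' @return List with `percent` (unrounded) and `reported` (nearest
#'   integer percent).
#' @export
erroneous_fraction <- function(random_recall, observed_recall) {
  if (observed_recall == 0) stop("observed recall is zero")
  val <- 100 * random_recall / observed_recall
  list(percent = val, reported = round(val))
}

#' Probability that a multi-domain host assignment is false
#'
#' With per-assignment error probability `p` and `k` independent
#' assignments, the probability that at least one is false is
#' `1 - (1 - p)^k`.
#'
#' @param p Per-assignment error probability in [0, 1].
#' @param k Number of independent assignments (>= 1).
#' @return Probability in [0, 1].
#' @export
false_multidomain_prob <- function(p, k = 2) {
  stopifnot(p >= 0, p <= 1, k >= 1)
  1 - (1 - p)^k
}

#' Expected number of spurious links
#'
#' @param n_links Number of observed links.
#' @param p_false Per-link false probability.
#' @return List with `expected` (unrounded) and `reported` (rounded count).
#' @export
expected_false_count <- function(n_links, p_false) {
  val <- n_links * p_false
  list(expected = val, reported = round(val))
}

#' Recall rate of host prediction
#'
#' @param n_linked Number of viral contigs with a predicted host.
#' @param n_total Total number of viral contigs.
#' @return Percentage.
#' @export
host_recall_rate <- function(n_linked, n_total) {
  stopifnot(n_total > 0)
  100 * n_linked / n_total
}

#' Classify host range per viral contig
#'
#' @param links Link table from [predict_hosts()] (needs `contig_id`,
#'   `genus`, `domain`).
#' @return Data frame `contig_id`, `n_genera`, `n_domains`, `label` with
#'   labels `specialist` (one host genus), `multi-genus` (several genera,
#'   one domain) or `cross-domain` (genera in different domains; implies
#'   multi-genus).
#' @export
classify_host_range <- function(links) {
  ids <- sort(unique(links$contig_id))
  rows <- lapply(ids, function(v) {
    sub <- links[links$contig_id == v, ]
    ngen <- length(unique(sub$genus))
    ndom <- length(unique(sub$domain))
    lab <- if (ndom > 1) "cross-domain"
    else if (ngen > 1) "multi-genus" else "specialist"
    data.frame(contig_id = v, n_genera = ngen, n_domains = ndom,
               label = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows,
                          list(data.frame(contig_id = character(0),
                                          n_genera = integer(0),
                                          n_domains = integer(0),
                                          label = character(0)))))
  rownames(out) <- NULL
  out
}

#' Map predicted host genera to ecosystem functions
#'
#' Every distinct (viral contig, host genus) pair contributes one count to
#' each function annotated for that genus (a genus with m functions
#' increments all m counters); genera absent from the table are counted
#' under `"unclassified"`.
#'
#' @param links Link table (needs `contig_id`, `genus`).
#' @param function_table Data frame `genus`, `func` (unique rows).
#' @param presence Optional contig presence data frame (`contig_id`,
#'   `sample_id`); when given, counts are reported per sample over the
#'   contigs present there.
#' @return Data frame `func`, `count` (plus `sample_id` when `presence`
#'   is given).
#' @export
map_functions <- function(links, function_table, presence = NULL) {
  count_one <- function(lk) {
    pairs <- unique(lk[, c("contig_id", "genus")])
    if (nrow(pairs) == 0)
      return(data.frame(func = character(0), count = integer(0),
                        stringsAsFactors = FALSE))
    fns <- lapply(seq_len(nrow(pairs)), function(i) {
      f <- function_table$func[function_table$genus == pairs$genus[i]]
      if (length(f) == 0) f <- "unclassified"
      f
    })
    tab <- table(unlist(fns))
    data.frame(func = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  if (is.null(presence)) return(count_one(links))
  out <- lapply(sort(unique(presence$sample_id)), function(s) {
    keep <- presence$contig_id[presence$sample_id == s]
    d <- count_one(links[links$contig_id %in% keep, , drop = FALSE])
    if (nrow(d) > 0) d$sample_id <- s
    d
  })
  do.call(rbind, out)
}
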