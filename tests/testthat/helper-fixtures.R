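# shared small community fixture, built once per test run
local_community <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 3, ...) {
    key <- paste(seed, paste(c(...), collapse = "_"), sep = "_")
    if (is.null(cache[[key]])) {
      cfg <- synth_config(n_viruses = 10, n_hosts = 6, n_samples = 3,
                          virus_len_range = c(6000, 9000),
                          host_len = 12000, seed = seed, ...)
      cache[[key]] <- gen_community(cfg)
    }
    cache[[key]]
  }
})

# substitute the central base (far from both ends, so no trimmed window
# can drop the mismatch); deterministic ACGT cycle
mutate_with_central_sub <- function(s) {
  i <- ceiling(nchar(s) / 2)
  b <- substr(s, i, i)
  repl <- c(A = "C", C = "G", G = "T", T = "A")[[b]]
  paste0(substr(s, 1, i - 1), repl, substr(s, i + 1, nchar(s)))
}

# independent screening oracle: literal transcription of the gates and
# criteria, evaluated one contig at a time
screen_oracle_one <- function(length, n_genes, n_ko, n_pfam, n_vpf, mode) {
  if (!(length > 5000)) return(FALSE)
  if (!(n_vpf >= 5)) return(FALSE)
  if (n_genes == 0) return(FALSE)
  c1 <- (n_ko / n_genes <= 0.20) && (n_pfam / n_genes <= 0.40) &&
    (n_vpf / n_genes >= 0.10)
  c2 <- n_vpf > n_pfam
  c3 <- n_vpf / n_genes >= 0.60
  if (mode == "any") c1 || c2 || c3 else c1 && c2 && c3
}

# exhaustive-enumeration oracle for the hypergeometric survival score:
# counts size-nB subsets of 1:n_total overlapping a fixed nA-set by >= shared
hyper_score_oracle <- function(nA, nB, shared, n_total) {
  if (shared == 0) return(0)
  A <- seq_len(nA)
  sets <- utils::combn(n_total, nB)
  hits <- sum(apply(sets, 2, function(b) sum(b %in% A) >= shared))
  -log10(hits / ncol(sets))
}
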