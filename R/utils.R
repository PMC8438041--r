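#' Generate a random DNA sequence
#'
#' Draws bases uniformly from the uppercase ACGT alphabet using the current
#' RNG stream. Synthetic communities use ACGT only (no ambiguity codes), so
#' identity arithmetic downstream is defined on exact base comparisons.
#'
#' @param n Sequence length in bp.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of uppercase ACGT sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# integer codes for fast base comparison
seq_ints <- function(s) utf8ToInt(s)

# random amino-acid string over the 20 standard residues
random_protein <- function(n) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# run code under a temporary RNG state restored on exit
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# write a data.frame as a TSV with a header row, no quoting
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

# write named character vector of sequences as FASTA
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (length(seqs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  xs <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
        else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a (multi-)FASTA file.
#' @param type `"DNA"` or `"AA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  xs <- if (type == "DNA") Biostrings::readDNAStringSet(path)
        else Biostrings::readAAStringSet(path)
  out <- as.character(xs)
  names(out) <- sub("\\s.*$", "", names(xs))
  out
}
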