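## Small shared helpers: sequence handling, FASTA I/O, seeded evaluation.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate uniform random DNA
#'
#' Bases are drawn i.i.d. uniform over A/C/G/T (GC content 50%).
#'
#' @param n sequence length in bp.
#' @return a single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Write sequences to FASTA
#'
#' Lines are wrapped at 60 columns; output is byte-deterministic for a given
#' input, so repeated runs of the simulator produce identical files.
#'
#' @param x named character vector, `DNAStringSet` or `AAStringSet`.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) {
    stopifnot(!is.null(names(x)))
    x <- Biostrings::BStringSet(x)
  }
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a FASTA/FASTQ file into a named character vector
#'
#' @param path input file.
#' @param format "fasta" or "fastq" (qualities are discarded).
#' @param type "DNA" or "AA".
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, format = "fasta", type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") {
    Biostrings::readDNAStringSet(path, format = format)
  } else {
    Biostrings::readAAStringSet(path, format = format)
  }
  out <- as.character(set)
  # keep only the first word of each FASTA header, as mappers do
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current stream" (callers composing stages
# manage one master seed instead).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 0-based half-open interval intersection length.
interval_intersection <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# write a data.frame as a plain TSV with header, no quoting/row names
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", colClasses = colClasses,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
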