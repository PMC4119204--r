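## K-mer spectrum genome-size estimation.
##
## Canonical k-mers (each k-mer pooled with its reverse complement under
## the lexicographically smaller of the two) are counted across all reads;
## the multiplicity histogram has its main peak at the expected k-mer depth
## M, which relates to the sequencing depth N via M = N (L - K + 1) / L
## for read length L.  Genome size is then total bases / N.

#' Count canonical k-mers in reads
#'
#' K-mers containing non-ACGT characters are skipped; reads shorter than
#' `k` contribute nothing (with a warning).
#'
#' @param reads named character vector of reads, an `XStringSet`, or a path
#'   to a FASTA/FASTQ file.
#' @param k k-mer length (1..32).
#' @param format file format when `reads` is a path ("fasta" or "fastq").
#' @return object of class `kmer_histogram`: list with `k`, `histogram`
#'   (`data.frame` multiplicity/count), `total_kmers` (k-mer instances),
#'   `n_distinct`, `total_bases`, `read_length` (modal read length).
#' @export
count_kmers <- function(reads, k, format = "fasta") {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      is.null(names(reads))) {
    reads <- read_fasta(reads, format = format)
  }
  if (!is.character(reads)) reads <- as.character(reads)
  stopifnot(length(reads) >= 1L)
  k <- as.integer(k)
  if (k < 1L || k > 32L) stop("count_kmers: k must be in 1..32")
  lens <- nchar(reads)
  if (any(lens < k))
    warning("count_kmers: ", sum(lens < k),
            " read(s) shorter than k contribute no k-mers")
  res <- kmer_hist_cpp(reads, k)
  hist <- data.frame(multiplicity = res$multiplicity, count = res$count)
  hist <- hist[order(hist$multiplicity), , drop = FALSE]
  rownames(hist) <- NULL
  rl <- as.integer(names(sort(table(lens), decreasing = TRUE))[1L])
  structure(list(k = k, histogram = hist,
                 total_kmers = res$total_instances,
                 n_distinct = res$n_distinct,
                 total_bases = sum(as.numeric(lens)),
                 read_length = rl),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("k-mer histogram: k=%d, %.0f instances, %.0f distinct, %.0f bases\n",
              x$k, x$total_kmers, x$n_distinct, x$total_bases))
  print(utils::head(x$histogram, 10L))
  invisible(x)
}

#' Locate the coverage peak of a k-mer spectrum
#'
#' With real reads the spectrum has an error spike at low multiplicity
#' followed by a trough and the main coverage peak.  The search region
#' starts at the first local minimum of counts as multiplicity increases
#' (or at `min_multiplicity` if given); if counts decrease monotonically
#' there is no peak to find and the global argmax (multiplicity 1) is
#' returned with a warning.
#'
#' Within the search region the default `refine = TRUE` returns the
#' count-weighted mean multiplicity over the window \[0.6, 1.4\] times the
#' raw argmax, rounded to the nearest integer: the formula's M is the
#' *expected* k-mer depth, and for a Poisson-shaped peak with near-integer
#' mean the raw argmax is a coin flip between the two central bins (a
#' half-unit downward bias on average) while the local centroid estimates
#' the mean consistently.  The window covers essentially all of the peak's
#' mass at realistic depths yet excludes the doubled-multiplicity peak that
#' k-mers shared between the subgenomes of a polyploid produce at twice
#' the main peak.  `refine = FALSE` returns the raw argmax (ties to the
#' smallest multiplicity).
#'
#' @param hist a `kmer_histogram` (or its `histogram` `data.frame`).
#' @param min_multiplicity explicit lower bound of the search region
#'   (overrides the trough search).
#' @param refine use the centroid of the peak region (default) instead of
#'   the raw argmax.
#' @return integer M, with attributes `raw` (argmax) and `centroid`.
#' @export
find_coverage_peak <- function(hist, min_multiplicity = NULL, refine = TRUE) {
  h <- if (inherits(hist, "kmer_histogram")) hist$histogram else hist
  if (!nrow(h)) stop("find_coverage_peak: empty histogram")
  maxm <- max(h$multiplicity)
  counts <- numeric(maxm)
  counts[h$multiplicity] <- h$count
  if (is.null(min_multiplicity)) {
    trough <- NA_integer_
    if (maxm > 1L) {
      for (m in seq_len(maxm - 1L)) {
        if (counts[m] <= counts[m + 1L]) { trough <- m; break }
      }
    }
    if (is.na(trough)) {
      warning("find_coverage_peak: monotonically decreasing spectrum; ",
              "returning the global argmax")
      M <- as.integer(which.max(counts))
      attr(M, "raw") <- M
      attr(M, "centroid") <- NA_real_
      return(M)
    }
    region <- trough:maxm
  } else {
    region <- min_multiplicity:maxm
  }
  rc <- counts[region]
  raw <- as.integer(region[which.max(rc)])
  win <- region[region >= ceiling(0.6 * raw) & region <= floor(1.4 * raw)]
  centroid <- sum(win * counts[win]) / sum(counts[win])
  M <- if (refine) as.integer(round(centroid)) else raw
  attr(M, "raw") <- raw
  attr(M, "centroid") <- centroid
  M
}

#' Sequencing depth from the coverage peak
#'
#' Inverts M = N (L - K + 1) / L.
#'
#' @param M integer coverage peak multiplicity (>= 1).
#' @param read_length read length L.
#' @param k k-mer length (1 <= k <= L).
#' @return fold-coverage N.
#' @export
estimate_depth <- function(M, read_length, k) {
  if (k > read_length) stop("estimate_depth: k must be <= read_length")
  if (k < 1L) stop("estimate_depth: k must be >= 1")
  if (M < 1) stop("estimate_depth: M must be >= 1")
  M * read_length / (read_length - k + 1)
}

#' Genome size from total bases and depth
#'
#' @param total_bases total sequenced bases.
#' @param N fold-coverage (> 0).
#' @return genome size estimate in bp.
#' @export
estimate_genome_size <- function(total_bases, N) {
  if (!is.numeric(N) || N <= 0) stop("estimate_genome_size: N must be > 0")
  if (total_bases == 0) {
    warning("estimate_genome_size: zero input bases")
    return(0)
  }
  total_bases / N
}

#' Full genome-size estimate from reads
#'
#' Convenience pipeline: count k-mers, locate the coverage peak, invert to
#' depth, divide total bases.
#'
#' @param reads reads as for [count_kmers()].
#' @param k k-mer length, default 21.
#' @param ... passed to [find_coverage_peak()].
#' @return list with `M`, `N`, `G`, and the `kmer_histogram`.
#' @export
genome_size_from_reads <- function(reads, k = 21L, ...) {
  hist <- count_kmers(reads, k)
  M <- find_coverage_peak(hist, ...)
  N <- estimate_depth(as.integer(M), hist$read_length, k)
  G <- estimate_genome_size(hist$total_bases, N)
  list(M = as.integer(M), N = N, G = G, histogram = hist)
}
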