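## Nei-Gojobori (1986) divergence estimation and Ks-peak clock dating.
##
## For an aligned pair of coding sequences, synonymous (S) and
## non-synonymous (N) site counts are obtained per codon by asking, for each
## of the nine single-base changes, whether it preserves the encoded amino
## acid (changes to stop codons are excluded from the denominator at that
## position).  Observed differences are classified by averaging over all
## minimal substitution pathways between the two codons, excluding pathways
## through stop codons.  The proportions pS = Sd/S and pN = Nd/N are
## corrected for multiple hits with the Jukes-Cantor formula
## d = -(3/4) log(1 - (4/3) p), undefined at p >= 3/4 (saturation).
## Under a molecular clock, a Ks peak at mode m dates the underlying
## duplication/speciation to T = m / (2 r) years for synonymous rate r.

#' Molecular clock rate
#'
#' Synonymous substitutions per synonymous site per year; the default
#' 6.5e-9 is the standard plant nuclear rate used for grass Ks dating.
#' @export
DEFAULT_CLOCK_RATE <- 6.5e-9

# codon tables, built once: the 61 sense codons, their amino acids, and
# per-codon synonymous site fractions
.codon_tables <- function() {
  env <- .tetrakit_env
  if (is.null(env$codon_tables)) {
    code <- Biostrings::GENETIC_CODE
    codons <- names(code)[code != "*"]
    s <- vapply(codons, .codon_sites_enum, numeric(1L))
    # allowed substitution targets per (codon, position): the non-stop
    # alternatives, i.e. the opportunity space NG86 site counting assumes
    allowed <- list()
    for (cd in codons) {
      chars <- strsplit(cd, "")[[1L]]
      for (pos in 1:3) {
        alts <- character(0)
        for (b in setdiff(DNA_BASES, chars[pos])) {
          alt <- chars; alt[pos] <- b
          if (code[[paste(alt, collapse = "")]] != "*") alts <- c(alts, b)
        }
        allowed[[paste0(cd, ".", pos)]] <- alts
      }
    }
    env$codon_tables <- list(codons = codons, aa = code,
                             s_sites = stats::setNames(s, codons),
                             allowed = allowed)
    env$pair_memo <- new.env(parent = emptyenv())
  }
  env$codon_tables
}

# synonymous site fraction of one sense codon, by enumerating the nine
# single-base changes; stop-codon targets are excluded from the
# denominator position-wise
.codon_sites_enum <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  chars <- strsplit(codon, "")[[1L]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; denom <- 0L
    for (b in setdiff(DNA_BASES, chars[pos])) {
      alt <- chars; alt[pos] <- b
      alt_codon <- paste(alt, collapse = "")
      alt_aa <- code[[alt_codon]]
      if (alt_aa == "*") next
      denom <- denom + 1L
      if (alt_aa == aa) syn <- syn + 1L
    }
    if (denom > 0L) s <- s + syn / denom
  }
  s
}

#' Synonymous and non-synonymous site fractions of a codon
#'
#' @param codon a 3-letter sense codon over A/C/G/T (standard code).
#' @return named numeric `c(s = , n = )` with `s + n == 3`.
#' @export
codon_sites <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L)
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon))
    stop("codon_sites: '", codon, "' is not an unambiguous ACGT codon")
  if (Biostrings::GENETIC_CODE[[codon]] == "*")
    stop("codon_sites: '", codon, "' is a stop codon")
  s <- .codon_tables()$s_sites[[codon]]
  c(s = s, n = 3 - s)
}

# (Sd, Nd) contribution of one differing codon pair, averaged over minimal
# substitution pathways; pathways through stop codons are excluded (if all
# are blocked, the average falls back to all pathways).  Memoized.
.codon_pair_diff <- function(c1, c2) {
  tabs <- .codon_tables()
  memo <- .tetrakit_env$pair_memo
  key <- paste0(c1, c2)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  code <- tabs$aa
  a1 <- strsplit(c1, "")[[1L]]
  a2 <- strsplit(c2, "")[[1L]]
  diff_pos <- which(a1 != a2)
  paths <- .permutations(diff_pos)
  syn_per_path <- numeric(0)
  syn_all <- numeric(0)
  for (ord in paths) {
    cur <- a1
    syn <- 0
    blocked <- FALSE
    for (pos in ord) {
      prev_aa <- code[[paste(cur, collapse = "")]]
      cur[pos] <- a2[pos]
      cur_codon <- paste(cur, collapse = "")
      cur_aa <- code[[cur_codon]]
      if (cur_aa == "*" && cur_codon != c2) blocked <- TRUE
      if (cur_aa == prev_aa) syn <- syn + 1
    }
    syn_all <- c(syn_all, syn)
    if (!blocked) syn_per_path <- c(syn_per_path, syn)
  }
  if (!length(syn_per_path)) syn_per_path <- syn_all
  sd <- mean(syn_per_path)
  out <- c(sd = sd, nd = length(diff_pos) - sd)
  memo[[key]] <- out
  memo[[paste0(c2, c1)]] <- out   # pathway averaging is symmetric
  out
}

.permutations <- function(x) {
  n <- length(x)
  if (n <= 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' NG86 divergence estimate for one aligned CDS pair
#'
#' Codon columns containing gaps, ambiguity characters or stop codons (in
#' either sequence) are skipped pairwise; the remaining columns are scored
#' as described in the module header.  `dS`/`dN` are `NA` when the
#' corresponding proportion reaches the Jukes-Cantor saturation bound 3/4
#' (flagged in `saturated_s`/`saturated_n`).
#'
#' @param a,b aligned coding sequences of equal length divisible by 3
#'   (gap character '-').
#' @param pair_id identifier carried into the result.
#' @return an object of class `ks_estimate`: a list with pair_id, codons
#'   (compared), skipped_codons, S, N, Sd, Nd, pS, pN, dS, dN, omega and
#'   the saturation flags.
#' @export
ng86_pair <- function(a, b, pair_id = "pair") {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b))
    stop("ng86_pair: sequences have unequal aligned length")
  if (nchar(a) %% 3L != 0L)
    stop("ng86_pair: aligned length not divisible by 3")
  tabs <- .codon_tables()
  starts <- seq(1L, nchar(a), by = 3L)
  ca <- substring(a, starts, starts + 2L)
  cb <- substring(b, starts, starts + 2L)
  ok <- ca %in% tabs$codons & cb %in% tabs$codons
  skipped <- sum(!ok)
  ca <- ca[ok]; cb <- cb[ok]
  n_codons <- length(ca)
  if (n_codons == 0L) stop("ng86_pair: no comparable codons")
  S <- (sum(tabs$s_sites[ca]) + sum(tabs$s_sites[cb])) / 2
  N <- 3 * n_codons - S
  d <- which(ca != cb)
  Sd <- 0; Nd <- 0
  if (length(d)) {
    keys <- paste(ca[d], cb[d])
    tab <- table(keys)
    for (k in names(tab)) {
      parts <- strsplit(k, " ", fixed = TRUE)[[1L]]
      contrib <- .codon_pair_diff(parts[1L], parts[2L])
      Sd <- Sd + tab[[k]] * contrib[["sd"]]
      Nd <- Nd + tab[[k]] * contrib[["nd"]]
    }
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  sat_s <- pS >= 0.75
  sat_n <- pN >= 0.75
  dS <- if (sat_s) NA_real_ else -0.75 * log(1 - 4 * pS / 3)
  dN <- if (sat_n) NA_real_ else -0.75 * log(1 - 4 * pN / 3)
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  structure(list(pair_id = pair_id, codons = n_codons,
                 skipped_codons = skipped, S = S, N = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
                 saturated_s = sat_s, saturated_n = sat_n),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("NG86 estimate [%s]: %d codons (%d skipped)\n",
              x$pair_id, x$codons, x$skipped_codons))
  cat(sprintf("  S=%.3f N=%.3f Sd=%.3f Nd=%.3f pS=%.4f pN=%.4f\n",
              x$S, x$N, x$Sd, x$Nd, x$pS, x$pN))
  cat(sprintf("  dS=%s dN=%s omega=%s\n",
              if (x$saturated_s) "saturated" else sprintf("%.4f", x$dS),
              if (x$saturated_n) "saturated" else sprintf("%.4f", x$dN),
              if (is.na(x$omega)) "NA" else sprintf("%.4f", x$omega)))
  invisible(x)
}

#' NG86 estimates for many pairs
#'
#' @param a,b character vectors of aligned sequences (element i of `a`
#'   pairs with element i of `b`).
#' @param pair_ids identifiers, recycled from names or indices.
#' @return `data.frame` with one row per pair and the `ks_estimate` fields.
#' @export
ng86_pairs <- function(a, b, pair_ids = NULL) {
  stopifnot(length(a) == length(b))
  if (is.null(pair_ids)) {
    pair_ids <- if (!is.null(names(a))) names(a)
                else sprintf("pair%05d", seq_along(a))
  }
  rows <- lapply(seq_along(a), function(i) {
    e <- ng86_pair(a[[i]], b[[i]], pair_id = pair_ids[[i]])
    data.frame(pair_id = e$pair_id, codons = e$codons,
               skipped_codons = e$skipped_codons, S = e$S, N = e$N,
               Sd = e$Sd, Nd = e$Nd, pS = e$pS, pN = e$pN,
               dS = e$dS, dN = e$dN, omega = e$omega,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binned Ks distribution
#'
#' Histogram over fixed bins `[k*w, (k+1)*w)` covering `range`; values
#' outside the range (or `NA`, i.e. saturated) are excluded and counted.
#'
#' @param values numeric dS values.
#' @param bin_width bin width, default 0.01.
#' @param range histogram range, default `c(0, 2)`.
#' @return object of class `ks_distribution`.
#' @export
ks_distribution <- function(values, bin_width = 0.01, range = c(0, 2)) {
  stopifnot(bin_width > 0, length(range) == 2L, range[1L] < range[2L])
  na <- sum(is.na(values))
  v <- values[!is.na(values)]
  out_of_range <- sum(v < range[1L] | v >= range[2L])
  v <- v[v >= range[1L] & v < range[2L]]
  nbins <- ceiling((range[2L] - range[1L]) / bin_width)
  idx <- pmin(floor((v - range[1L]) / bin_width) + 1L, nbins)
  counts <- tabulate(idx, nbins = nbins)
  structure(list(values = v, bin_width = bin_width, range = range,
                 counts = counts, excluded = out_of_range, na = na),
            class = "ks_distribution")
}

#' Mode of a Ks distribution
#'
#' Left edge of the maximal histogram bin; ties resolve to the smallest
#' edge.
#'
#' @param x a `ks_distribution` or a numeric vector of dS values.
#' @param ... passed to [ks_distribution()] when `x` is numeric.
#' @return the mode as a bin left edge (multiple of the bin width).
#' @export
ks_mode <- function(x, ...) {
  if (is.numeric(x)) x <- ks_distribution(x, ...)
  stopifnot(inherits(x, "ks_distribution"))
  if (!length(x$values)) stop("ks_mode: no in-range values")
  x$range[1L] + (which.max(x$counts) - 1L) * x$bin_width
}

#' Date a divergence from its Ks value
#'
#' Two lineages diverged T years ago accumulate Ks = 2 r T synonymous
#' substitutions per synonymous site between them, so T = Ks / (2 r).
#'
#' @param ks synonymous divergence (>= 0).
#' @param rate synonymous substitutions per synonymous site per year
#'   (> 0); default [DEFAULT_CLOCK_RATE].
#' @return divergence time in years.
#' @export
date_from_ks <- function(ks, rate = DEFAULT_CLOCK_RATE) {
  if (!is.numeric(rate) || rate <= 0) stop("date_from_ks: rate must be > 0")
  if (any(ks < 0)) stop("date_from_ks: ks must be >= 0")
  ks / (2 * rate)
}

#' @rdname date_from_ks
#' @return `date_from_ks_my`: millions of years, rounded to the nearest
#'   integer.
#' @export
date_from_ks_my <- function(ks, rate = DEFAULT_CLOCK_RATE) {
  round(date_from_ks(ks, rate) / 1e6)
}

#' Global alignment (Needleman-Wunsch, linear gaps)
#'
#' Optimal global alignment under match/mismatch/gap scores with the
#' deterministic tie-break diagonal > up (gap in `b`) > left (gap in `a`)
#' during traceback.  Intended for real, indel-bearing CDS pairs before
#' [ng86_pair()]; simulator pairs are pre-aligned and skip this step.
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap scores (gap is the per-base linear penalty).
#' @return list with `aligned_a`, `aligned_b`, `score`.
#' @export
global_align <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  nw_align_cpp(toupper(a), toupper(b), as.integer(match),
               as.integer(mismatch), as.integer(gap))
}
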