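## SSR (microsatellite) detection, in-silico PCR and genetic-map linking.
##
## SSR detection follows the MISA convention: a maximal tandem run of a
## 1-6 bp motif is reported when its full repeat count reaches the
## per-motif-length minimum (10 for mononucleotides, 6 for dinucleotides,
## 5 for motif lengths 3-6).  A run whose motif is itself a repetition of a
## shorter motif is reported at the shortest period only; two SSRs
## separated by at most `max_interruption` bases merge into one compound
## record.

#' Default MISA-style minimum repeat counts by motif length
#' @export
MISA_MIN_REPEATS <- c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L,
                      `6` = 5L)

# is `motif` a whole-number repetition of one of its proper prefixes?
.is_minimal_motif <- function(motif) {
  p <- nchar(motif)
  for (q in seq_len(p - 1L)) {
    if (p %% q == 0L &&
        motif == strrep(substr(motif, 1L, q), p %/% q)) return(FALSE)
  }
  TRUE
}

#' Detect SSRs
#'
#' @param seqs named character vector of DNA sequences (A/C/G/T/N; runs
#'   containing N terminate).
#' @param min_repeats named integer vector mapping motif length ("1".."6")
#'   to the minimum repeat count; default [MISA_MIN_REPEATS].
#' @param max_interruption maximum gap (bp) between two SSRs merged into a
#'   compound record; default 100.
#' @return `data.frame` with columns sequence_id, start, end (0-based
#'   half-open), motif (as found; "+"-joined for compounds), motif_length
#'   (shortest member motif for compounds), repeat_count (sum of members
#'   for compounds, interruption bases excluded), kind (simple/compound).
#' @export
find_ssrs <- function(seqs, min_repeats = MISA_MIN_REPEATS,
                      max_interruption = 100L) {
  stopifnot(is.character(seqs))
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  periods <- as.integer(names(min_repeats))
  out <- list()
  for (sid in names(seqs)) {
    s <- toupper(seqs[[sid]])
    recs <- list()
    for (p in sort(periods)) {
      minrep <- min_repeats[[as.character(p)]]
      if (minrep < 2L) stop("find_ssrs: minimum repeat counts must be >= 2")
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", p, minrep - 1L)
      m <- gregexpr(pat, s, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
      for (j in seq_along(starts)) {
        motif <- substr(s, starts[j], starts[j] + p - 1L)
        if (!.is_minimal_motif(motif)) next
        nrep <- lens[j] %/% p
        recs[[length(recs) + 1L]] <- data.frame(
          sequence_id = sid, start = starts[j] - 1L,
          end = starts[j] - 1L + nrep * p,
          motif = motif, motif_length = p, repeat_count = nrep,
          kind = "simple", stringsAsFactors = FALSE)
      }
    }
    if (!length(recs)) next
    recs <- do.call(rbind, recs)
    recs <- recs[order(recs$start, recs$end), , drop = FALSE]
    # merge runs separated by <= max_interruption into compound records
    merged <- list()
    cur <- recs[1L, ]
    for (j in seq_len(nrow(recs))[-1L]) {
      nxt <- recs[j, ]
      if (nxt$start - cur$end <= max_interruption) {
        cur$end <- max(cur$end, nxt$end)
        cur$motif <- paste(cur$motif, nxt$motif, sep = "+")
        cur$motif_length <- min(cur$motif_length, nxt$motif_length)
        cur$repeat_count <- cur$repeat_count + nxt$repeat_count
        cur$kind <- "compound"
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- nxt
      }
    }
    merged[[length(merged) + 1L]] <- cur
    out[[sid]] <- do.call(rbind, merged)
  }
  if (!length(out))
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      motif_length = integer(0), repeat_count = integer(0),
                      kind = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}

#' Write SSRs as BED
#'
#' 0-based half-open, name column `motif xrepeat_count`.
#'
#' @param ssrs output of [find_ssrs()].
#' @param path output file.
#' @export
write_ssr_bed <- function(ssrs, path) {
  bed <- data.frame(ssrs$sequence_id, ssrs$start, ssrs$end,
                    sprintf("(%s)x%d", ssrs$motif, ssrs$repeat_count))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' SSR density
#'
#' Bases of genome per SSR; with `min_motif_length = 2` only di-nucleotide
#' or larger SSRs are counted (the convention of the genome-wide density
#' figure this mirrors).
#'
#' @param total_bp total genome length in bp (or a named character vector
#'   of sequences, whose lengths are summed).
#' @param ssrs output of [find_ssrs()].
#' @param min_motif_length count only SSRs with motif length >= this.
#' @return bases per SSR, or `NA` (with a warning) when no SSR qualifies.
#' @export
ssr_density <- function(total_bp, ssrs, min_motif_length = 1L) {
  if (is.character(total_bp)) total_bp <- sum(nchar(total_bp))
  n <- sum(ssrs$motif_length >= min_motif_length)
  if (n == 0L) {
    warning("ssr_density: no qualifying SSRs; density undefined")
    return(NA_real_)
  }
  total_bp / n
}

#' In-silico PCR
#'
#' Reports every site where the forward primer matches with at most
#' `max_mismatch` mismatches (no indels, full-length match) and the
#' reverse primer's reverse complement matches downstream on the same
#' strand, with a product no longer than `max_product` and no shorter than
#' the two primers laid end to end.  Both strands are searched; product
#' intervals are always reported in forward-genome coordinates.
#'
#' @param genome named character vector of sequences.
#' @param forward,reverse primer sequences (A/C/G/T, length >= 10).
#' @param max_product maximum product length, default 2000.
#' @param max_mismatch mismatches tolerated per primer, default 0.
#' @return `data.frame`: sequence_id, start, end (0-based half-open
#'   product interval), product_length, strand (of the forward primer).
#' @export
epcr_locate <- function(genome, forward, reverse, max_product = 2000L,
                        max_mismatch = 0L) {
  stopifnot(is.character(genome))
  if (is.null(names(genome))) names(genome) <- sprintf("seq%d", seq_along(genome))
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (!grepl("^[ACGT]{10,}$", p))
      stop("epcr_locate: primers must be ACGT and at least 10 bp")
  }
  lf <- nchar(forward); lr <- nchar(reverse)
  hits <- list()
  scan_strand <- function(s, sid, strand, seqlen) {
    fpos <- find_matches_cpp(s, forward, as.integer(max_mismatch))
    if (!length(fpos)) return(NULL)
    rpos <- find_matches_cpp(s, revcomp(reverse), as.integer(max_mismatch))
    if (!length(rpos)) return(NULL)
    rows <- list()
    for (i in fpos) {
      for (j in rpos) {
        prod <- j + lr - i
        if (j >= i + lf && prod <= max_product) {
          # interval on the scanned strand; map back for the minus strand
          if (strand == "+") {
            rows[[length(rows) + 1L]] <- data.frame(
              sequence_id = sid, start = i, end = i + prod,
              product_length = prod, strand = "+")
          } else {
            rows[[length(rows) + 1L]] <- data.frame(
              sequence_id = sid, start = seqlen - (i + prod),
              end = seqlen - i, product_length = prod, strand = "-")
          }
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  for (sid in names(genome)) {
    s <- toupper(genome[[sid]])
    seqlen <- nchar(s)
    hits[[length(hits) + 1L]] <- scan_strand(s, sid, "+", seqlen)
    hits[[length(hits) + 1L]] <- scan_strand(revcomp(s), sid, "-", seqlen)
  }
  hits <- hits[!vapply(hits, is.null, logical(1L))]
  if (!length(hits))
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), product_length = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$sequence_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign linkage groups to pseudo-chromosomes
#'
#' Each linkage group goes to the pseudo-chromosome holding the plurality
#' of its physically located markers; ties resolve to the smallest
#' pseudo-chromosome id and are flagged, as are groups split across
#' chromosomes (translocation-like signal).  Groups with no located marker
#' stay unassigned (`NA`).
#'
#' @param placements `data.frame` with columns marker_id,
#'   pseudo_chromosome (physical marker locations).
#' @param map `data.frame` with columns marker_id, linkage_group, position
#'   (cM).
#' @return `data.frame`: linkage_group, pseudo_chromosome, n_markers,
#'   tie (logical), split (logical).
#' @export
assign_linkage_groups <- function(placements, map) {
  stopifnot(all(c("marker_id", "pseudo_chromosome") %in% names(placements)),
            all(c("marker_id", "linkage_group") %in% names(map)))
  groups <- sort(unique(map$linkage_group))
  rows <- lapply(groups, function(lg) {
    mk <- map$marker_id[map$linkage_group == lg]
    loc <- placements[placements$marker_id %in% mk, , drop = FALSE]
    if (!nrow(loc)) {
      return(data.frame(linkage_group = lg, pseudo_chromosome = NA_character_,
                        n_markers = 0L, tie = FALSE, split = FALSE))
    }
    tab <- table(loc$pseudo_chromosome)
    winners <- names(tab)[tab == max(tab)]   # sorted
    data.frame(linkage_group = lg, pseudo_chromosome = winners[1L],
               n_markers = nrow(loc), tie = length(winners) > 1L,
               split = length(tab) > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genetic-to-physical distance ratios
#'
#' For markers sharing a linkage group and a pseudo-chromosome, sorted by
#' physical position, computes |delta cM| / (|delta bp| / 1e6) per
#' consecutive pair; coincident physical positions give an undefined
#' (`NA`) ratio.
#'
#' @param markers `data.frame` with columns marker_id, linkage_group,
#'   pseudo_chromosome, cm, bp.
#' @return `data.frame` of consecutive pairs with their cm_per_mbp ratio.
#' @export
cm_per_mbp <- function(markers) {
  need <- c("marker_id", "linkage_group", "pseudo_chromosome", "cm", "bp")
  stopifnot(all(need %in% names(markers)))
  parts <- split(markers,
                 paste(markers$linkage_group, markers$pseudo_chromosome,
                       sep = "\r"))
  rows <- list()
  for (g in parts) {
    g <- g[order(g$bp), , drop = FALSE]
    if (nrow(g) < 2L) next
    for (i in seq_len(nrow(g) - 1L)) {
      dbp <- abs(g$bp[i + 1L] - g$bp[i])
      dcm <- abs(g$cm[i + 1L] - g$cm[i])
      rows[[length(rows) + 1L]] <- data.frame(
        linkage_group = g$linkage_group[1L],
        pseudo_chromosome = g$pseudo_chromosome[1L],
        marker_1 = g$marker_id[i], marker_2 = g$marker_id[i + 1L],
        delta_cm = dcm, delta_bp = dbp,
        cm_per_mbp = if (dbp == 0) NA_real_ else dcm / (dbp / 1e6),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(linkage_group = character(0),
                      pseudo_chromosome = character(0),
                      marker_1 = character(0), marker_2 = character(0),
                      delta_cm = numeric(0), delta_bp = numeric(0),
                      cm_per_mbp = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
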