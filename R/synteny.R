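## Syntenic anchor tables, scaffold filtering and placement.
##
## An anchor is one syntenic gene pair linking a scaffold interval to a
## reference-chromosome interval.  Scaffolds supported by at least a minimum
## number of syntenic genes are placed on the reference chromosome holding
## the majority of their anchors, spanned by their anchors, and oriented by
## the sign of the rank correlation between the two coordinate orders.

ANCHOR_COLUMNS <- c("scaffold_id", "scaffold_start", "scaffold_end",
                    "ref_chrom", "ref_start", "ref_end",
                    "scaffold_gene", "ref_gene")

#' Read a syntenic anchor table
#'
#' Expects the tab-separated dialect with header
#' `scaffold_id scaffold_start scaffold_end ref_chrom ref_start ref_end
#' scaffold_gene ref_gene`, coordinates 0-based half-open on both sides.
#' Lines starting with `#` are comments.  Malformed rows (missing columns,
#' non-integer coordinates, start >= end) abort with their line numbers.
#'
#' @param path file to read.
#' @return a `data.frame` of anchors.
#' @export
read_anchor_table <- function(path) {
  if (!file.exists(path)) stop("read_anchor_table: no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("read_anchor_table: header line missing")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, ANCHOR_COLUMNS))
    stop("read_anchor_table: bad header; expected: ",
         paste(ANCHOR_COLUMNS, collapse = "\t"))
  body <- lines[-1L]
  lineno <- lineno[-1L]
  anchors <- data.frame(scaffold_id = character(0), scaffold_start = integer(0),
                        scaffold_end = integer(0), ref_chrom = character(0),
                        ref_start = integer(0), ref_end = integer(0),
                        scaffold_gene = character(0), ref_gene = character(0),
                        stringsAsFactors = FALSE)
  if (!length(body)) return(anchors)
  fields <- strsplit(body, "\t", fixed = TRUE)
  errs <- character(0)
  rows <- vector("list", length(body))
  int_cols <- c(2L, 3L, 5L, 6L)
  for (i in seq_along(body)) {
    f <- fields[[i]]
    if (length(f) != 8L) {
      errs <- c(errs, sprintf("line %d: expected 8 columns, got %d",
                              lineno[i], length(f)))
      next
    }
    co <- suppressWarnings(as.integer(f[int_cols]))
    if (anyNA(co)) {
      errs <- c(errs, sprintf("line %d: non-integer coordinate", lineno[i]))
      next
    }
    if (co[1L] >= co[2L] || co[3L] >= co[4L]) {
      errs <- c(errs, sprintf("line %d: interval start >= end", lineno[i]))
      next
    }
    rows[[i]] <- data.frame(scaffold_id = f[1L], scaffold_start = co[1L],
                            scaffold_end = co[2L], ref_chrom = f[4L],
                            ref_start = co[3L], ref_end = co[4L],
                            scaffold_gene = f[7L], ref_gene = f[8L],
                            stringsAsFactors = FALSE)
  }
  if (length(errs))
    stop("read_anchor_table: malformed rows:\n  ",
         paste(errs, collapse = "\n  "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a syntenic anchor table
#'
#' @param anchors anchor `data.frame`.
#' @param path output file.
#' @export
write_anchor_table <- function(anchors, path) {
  stopifnot(all(ANCHOR_COLUMNS %in% names(anchors)))
  write_tsv(anchors[, ANCHOR_COLUMNS], path)
}

# majority reference chromosome of one scaffold's anchors,
# ties broken by lexicographically smallest chromosome id
.majority_chrom <- function(ref_chrom) {
  tab <- table(ref_chrom)
  names(tab)[tab == max(tab)][1L]   # table() names are sorted
}

#' Filter scaffolds by minimum syntenic-gene support
#'
#' A scaffold survives iff its anchor count on its assigned (majority)
#' chromosome is at least `min_genes`; anchors of surviving scaffolds pass
#' through unchanged.  The operation is idempotent and monotone in
#' `min_genes`.
#'
#' @param anchors anchor `data.frame`.
#' @param min_genes minimum syntenic genes (>= 1); the draft-assembly
#'   placements in the source analysis required at least three.
#' @return the filtered anchor `data.frame`.
#' @export
filter_by_min_genes <- function(anchors, min_genes = 3L) {
  stopifnot(min_genes >= 1L)
  if (!nrow(anchors)) return(anchors)
  support <- vapply(split(anchors$ref_chrom, anchors$scaffold_id),
                    function(rc) sum(rc == .majority_chrom(rc)), integer(1L))
  keep_ids <- names(support)[support >= min_genes]
  out <- anchors[anchors$scaffold_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place one scaffold on the reference
#'
#' The scaffold is assigned to the chromosome holding the most of its
#' anchors (ties to the lexicographically smallest chromosome id); only
#' anchors on the winning chromosome are used thereafter.  Its reference
#' interval spans min anchor start to max anchor end; orientation is the
#' sign of the Spearman rank correlation between anchor order on the
#' scaffold and on the reference (zero/undefined correlation or a single
#' anchor gives '+').
#'
#' @param anchors anchors of a single scaffold.
#' @param scaffold_length scaffold length in bp if known (`NA` otherwise).
#' @return one-row `data.frame`: scaffold_id, scaffold_length, ref_chrom,
#'   ref_start, ref_end, orientation, n_anchors.
#' @export
place_scaffold <- function(anchors, scaffold_length = NA_integer_) {
  if (!nrow(anchors)) stop("place_scaffold: empty anchor list")
  if (length(unique(anchors$scaffold_id)) != 1L)
    stop("place_scaffold: anchors of more than one scaffold supplied")
  chrom <- .majority_chrom(anchors$ref_chrom)
  a <- anchors[anchors$ref_chrom == chrom, , drop = FALSE]
  orientation <- "+"
  if (nrow(a) > 1L) {
    rho <- suppressWarnings(cor(a$scaffold_start, a$ref_start,
                                method = "spearman"))
    if (is.finite(rho) && rho < 0) orientation <- "-"
  }
  data.frame(scaffold_id = a$scaffold_id[1L],
             scaffold_length = scaffold_length,
             ref_chrom = chrom,
             ref_start = min(a$ref_start),
             ref_end = max(a$ref_end),
             orientation = orientation,
             n_anchors = nrow(a),
             stringsAsFactors = FALSE)
}

#' Place all scaffolds of an anchor set
#'
#' Convenience wrapper: filters by `min_genes`, then places each surviving
#' scaffold with [place_scaffold()].
#'
#' @param anchors anchor `data.frame`.
#' @param min_genes minimum syntenic genes per scaffold.
#' @param scaffold_lengths optional named vector of scaffold lengths (bp).
#' @return `data.frame` of placements, one row per placed scaffold.
#' @export
place_scaffolds <- function(anchors, min_genes = 3L, scaffold_lengths = NULL) {
  anchors <- filter_by_min_genes(anchors, min_genes)
  if (!nrow(anchors))
    return(data.frame(scaffold_id = character(0),
                      scaffold_length = integer(0), ref_chrom = character(0),
                      ref_start = integer(0), ref_end = integer(0),
                      orientation = character(0), n_anchors = integer(0)))
  parts <- lapply(split(anchors, anchors$scaffold_id), function(a) {
    sl <- if (!is.null(scaffold_lengths) &&
              a$scaffold_id[1L] %in% names(scaffold_lengths))
      as.integer(scaffold_lengths[[a$scaffold_id[1L]]]) else NA_integer_
    place_scaffold(a, scaffold_length = sl)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Count homology-supported gene copies
#'
#' A target locus counts as a copy of the query iff its aligned query
#' length is at least `min_fraction` (default 70%, inclusive) of the query
#' length; distinct loci are counted once.
#'
#' @param hits `data.frame` with columns `target_locus` and
#'   `aligned_query_length` (residues), one row per homology hit of a
#'   single query.
#' @param query_length query length in residues (> 0).
#' @param min_fraction coverage threshold, default 0.70.
#' @return integer copy count.
#' @export
count_copies <- function(hits, query_length, min_fraction = 0.70) {
  if (!is.numeric(query_length) || query_length <= 0)
    stop("count_copies: query_length must be > 0")
  if (!nrow(hits)) return(0L)
  if (any(hits$aligned_query_length < 0))
    stop("count_copies: negative aligned_query_length")
  ok <- hits$aligned_query_length >= min_fraction * query_length
  length(unique(hits$target_locus[ok]))
}
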