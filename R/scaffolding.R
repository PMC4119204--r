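## Pseudo-chromosome construction and greedy A/B homeolog partitioning.
##
## Scaffolds placed on one reference chromosome are ordered by their
## reference interval and joined with fixed-length N gaps into a
## pseudo-chromosome (with an AGP v2.0 description).  The scaffolds are
## also partitioned into two groups, A and B: the first scaffold goes to A,
## and each subsequent scaffold goes to B iff it overlaps some
## already-labeled A scaffold by strictly more than the threshold (75% of
## the shorter interval by default).  In an allotetraploid draft assembly
## this separates the two homeologous scaffold copies covering the same
## reference region; which copy lands in A vs B is arbitrary.

#' Order placements along a reference chromosome
#'
#' Sorts by reference start ascending, breaking ties by reference end, then
#' scaffold id (lexicographic).
#'
#' @param placements placement `data.frame` (see [place_scaffolds()]), all
#'   on one reference chromosome.
#' @return the reordered `data.frame`.
#' @export
order_scaffolds <- function(placements) {
  out <- placements[order(placements$ref_start, placements$ref_end,
                          placements$scaffold_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap fraction of two intervals
#'
#' Intersection length divided by the length of the shorter interval, so a
#' small interval nested in a large one scores 1.  Symmetric.
#'
#' @param i1,i2 numeric length-2 vectors `c(start, end)`, 0-based half-open,
#'   non-empty.
#' @return fraction in \[0,1\].
#' @export
overlap_fraction <- function(i1, i2) {
  stopifnot(length(i1) == 2L, length(i2) == 2L)
  if (i1[2L] <= i1[1L] || i2[2L] <= i2[1L])
    stop("overlap_fraction: empty interval")
  inter <- interval_intersection(i1[1L], i1[2L], i2[1L], i2[2L])
  inter / min(i1[2L] - i1[1L], i2[2L] - i2[1L])
}

#' Greedy A/B partition of ordered scaffolds
#'
#' Scaffolds are processed in [order_scaffolds()] order: the first goes to
#' A; each later scaffold goes to B iff its reference interval overlaps that
#' of ANY already-labeled A scaffold by strictly more than `threshold`,
#' otherwise to A.  Only A membership is tested (the literal rule); with
#' `check_b = TRUE` scaffolds that also overlap a B scaffold above the
#' threshold are flagged in an `ambiguous` column, the labels themselves
#' are unchanged.
#'
#' Deterministic but order-dependent; permuting the input can change
#' labels, which is why the resulting A/B split is a separation of
#' homeologs, not an assignment to the true subgenome of origin.
#'
#' @param placements placements on a single reference chromosome.
#' @param threshold overlap fraction above which (strictly) a scaffold is
#'   sent to B; default 0.75.
#' @param check_b also test overlap against B-labeled scaffolds and flag.
#' @return `data.frame` with columns scaffold_id, label (and ambiguous if
#'   `check_b`), in processing order.
#' @export
greedy_partition <- function(placements, threshold = 0.75, check_b = FALSE) {
  if (!nrow(placements))
    return(data.frame(scaffold_id = character(0), label = character(0)))
  if (length(unique(placements$ref_chrom)) != 1L)
    stop("greedy_partition: placements span more than one reference chromosome")
  p <- order_scaffolds(placements)
  n <- nrow(p)
  label <- character(n)
  ambiguous <- logical(n)
  for (i in seq_len(n)) {
    iv <- c(p$ref_start[i], p$ref_end[i])
    in_a <- which(label == "A")
    over_a <- length(in_a) > 0L && any(vapply(in_a, function(j) {
      overlap_fraction(iv, c(p$ref_start[j], p$ref_end[j]))
    }, numeric(1L)) > threshold)
    label[i] <- if (i > 1L && over_a) "B" else "A"
    if (check_b && i > 1L) {
      in_b <- which(label[seq_len(i - 1L)] == "B")
      over_b <- length(in_b) > 0L && any(vapply(in_b, function(j) {
        overlap_fraction(iv, c(p$ref_start[j], p$ref_end[j]))
      }, numeric(1L)) > threshold)
      ambiguous[i] <- over_a && over_b
    }
  }
  out <- data.frame(scaffold_id = p$scaffold_id, label = label,
                    stringsAsFactors = FALSE)
  if (check_b) out$ambiguous <- ambiguous
  out
}

#' Build a pseudo-chromosome from ordered members
#'
#' Concatenates member scaffolds in the given order, reverse-complementing
#' '-' members, with `gap_length` 'N's between consecutive members, and
#' produces the matching AGP v2.0 records (W components and N gaps, gap
#' type "scaffold", linkage "yes", evidence "na").
#'
#' @param members `data.frame` with columns `scaffold_id` and `orientation`
#'   ("+"/"-"), already ordered (see [order_scaffolds()]).
#' @param sequences named character vector holding every member sequence.
#' @param gap_length N-gap length between members, default 100.
#' @param name object name for the pseudo-chromosome.
#' @return list with `name`, `sequence`, `length`, `agp` (a `data.frame` of
#'   AGP records) and `layout` (scaffold_id, orientation, offset, length;
#'   offset 0-based).
#' @export
build_pseudochromosome <- function(members, sequences, gap_length = 100L,
                                   name = "pseudo") {
  missing <- setdiff(members$scaffold_id, names(sequences))
  if (length(missing))
    stop("build_pseudochromosome: missing sequence for scaffold(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(members)
  parts <- character(2L * n - 1L)
  agp <- vector("list", 2L * n - 1L)
  layout <- data.frame(scaffold_id = members$scaffold_id,
                       orientation = members$orientation,
                       offset = integer(n), length = integer(n))
  pos <- 0L   # 0-based offset within the object
  part <- 0L
  for (i in seq_len(n)) {
    if (i > 1L && gap_length > 0L) {
      part <- part + 1L
      parts[part] <- strrep("N", gap_length)
      agp[[part]] <- data.frame(
        object = name, object_beg = pos + 1L, object_end = pos + gap_length,
        part_number = part, component_type = "N",
        col6 = as.character(gap_length), col7 = "scaffold",
        col8 = "yes", col9 = "na", stringsAsFactors = FALSE)
      pos <- pos + as.integer(gap_length)
    }
    seq_i <- sequences[[members$scaffold_id[i]]]
    len <- nchar(seq_i)
    if (members$orientation[i] == "-") seq_i <- revcomp(seq_i)
    part <- part + 1L
    parts[part] <- seq_i
    agp[[part]] <- data.frame(
      object = name, object_beg = pos + 1L, object_end = pos + len,
      part_number = part, component_type = "W",
      col6 = members$scaffold_id[i], col7 = "1",
      col8 = as.character(len), col9 = members$orientation[i],
      stringsAsFactors = FALSE)
    layout$offset[i] <- pos
    layout$length[i] <- len
    pos <- pos + len
  }
  agp <- do.call(rbind, agp[seq_len(part)])
  rownames(agp) <- NULL
  list(name = name, sequence = paste(parts[seq_len(part)], collapse = ""),
       length = pos, agp = agp, layout = layout)
}

#' Write AGP v2.0 records
#'
#' @param agp AGP `data.frame` as produced by [build_pseudochromosome()].
#' @param path output file.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  utils::write.table(agp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read AGP v2.0 records
#'
#' Round-trips the output of [write_agp()] exactly (member order,
#' orientations, offsets and gap lengths preserved).
#'
#' @param path AGP file.
#' @return AGP `data.frame` with the same columns [write_agp()] wrote.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad))
    stop("read_agp: line(s) without 9 columns: ",
         paste(bad, collapse = ", "))
  m <- do.call(rbind, f)
  data.frame(object = m[, 1L], object_beg = as.integer(m[, 2L]),
             object_end = as.integer(m[, 3L]),
             part_number = as.integer(m[, 4L]), component_type = m[, 5L],
             col6 = m[, 6L], col7 = m[, 7L], col8 = m[, 8L], col9 = m[, 9L],
             stringsAsFactors = FALSE)
}

#' Lift a scaffold coordinate onto its pseudo-chromosome
#'
#' @param layout layout `data.frame` from [build_pseudochromosome()].
#' @param scaffold_id member scaffold.
#' @param pos 0-based position on the scaffold.
#' @return 0-based position on the pseudo-chromosome (exact; '-' members
#'   map through the reverse complement).
#' @export
lift_to_pseudo <- function(layout, scaffold_id, pos) {
  i <- match(scaffold_id, layout$scaffold_id)
  if (is.na(i)) stop("lift_to_pseudo: unknown scaffold: ", scaffold_id)
  if (any(pos < 0 | pos >= layout$length[i]))
    stop("lift_to_pseudo: position outside scaffold")
  if (layout$orientation[i] == "+") layout$offset[i] + pos
  else layout$offset[i] + (layout$length[i] - 1L - pos)
}

#' Average A/B sequence identity over aligned gene pairs
#'
#' For each aligned pair, identity is matches divided by the number of
#' columns that are non-gap in both sequences (indel columns are excluded
#' from the denominator); pairs are averaged weighted by their compared
#' columns.
#'
#' @param pairs list of character(2) vectors, each an aligned sequence pair
#'   of equal length ('-' for gaps).
#' @return percent identity (0-100), or `NA` with a warning when no
#'   comparable columns exist.
#' @export
ab_identity <- function(pairs) {
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  matches <- 0; compared <- 0
  for (p in pairs) {
    stopifnot(length(p) == 2L)
    if (nchar(p[1L]) != nchar(p[2L]))
      stop("ab_identity: pair members have unequal aligned length")
    a <- strsplit(toupper(p[1L]), "")[[1L]]
    b <- strsplit(toupper(p[2L]), "")[[1L]]
    ok <- a != "-" & b != "-"
    matches <- matches + sum(a[ok] == b[ok])
    compared <- compared + sum(ok)
  }
  if (compared == 0) {
    warning("ab_identity: no comparable (mutually non-gap) columns")
    return(NA_real_)
  }
  100 * matches / compared
}
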