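## Exact-match scanning of proteomes for immunogenic peptides.
##
## Celiac-disease T-cell epitopes are short prolamin-derived peptides
## (11-20 residues); the scan reports every exact occurrence in a protein
## set, counting overlapping occurrences separately.  Absence is a result:
## per-species summaries report zero rows explicitly, mirroring screens
## where the epitopes occur only in wheat, barley and rye.

#' Read an epitope list
#'
#' One peptide per line; `#` starts a comment, blank lines are ignored,
#' input is uppercased and duplicates are collapsed with a warning.
#'
#' @param path file to read.
#' @return character vector of unique peptides (class `epitope_set`), with
#'   a `lengths` attribute tallying observed peptide lengths.
#' @export
read_epitopes <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- toupper(trimws(lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("read_epitopes: no peptides in ", path)
  bad <- grep("[^ACDEFGHIKLMNPQRSTVWY]", lines)
  if (length(bad))
    stop("read_epitopes: non-amino-acid characters on data line(s) ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(lines)) {
    warning("read_epitopes: ", sum(duplicated(lines)),
            " duplicate peptide(s) collapsed")
    lines <- unique(lines)
  }
  structure(lines, lengths = table(nchar(lines)), class = "epitope_set")
}

#' Scan a proteome for exact epitope occurrences
#'
#' Every exact occurrence is reported; overlapping occurrences count
#' separately.  '*' translation terminators are stripped and sequences are
#' uppercased before matching.  Output is deterministically ordered by
#' protein id, position, then epitope.
#'
#' @param proteins named character vector of protein sequences (or an
#'   `AAStringSet`).
#' @param epitopes character vector of peptides (e.g. [read_epitopes()]).
#' @return `data.frame`: protein_id, epitope, position (0-based offset).
#' @export
scan_proteome <- function(proteins, epitopes) {
  if (!is.character(proteins)) proteins <- as.character(proteins)
  stopifnot(!is.null(names(proteins)), length(epitopes) >= 1L)
  proteins <- toupper(gsub("*", "", proteins, fixed = TRUE))
  epitopes <- toupper(as.character(epitopes))
  rows <- list()
  for (ep in epitopes) {
    # zero-width lookahead finds overlapping occurrences
    pat <- paste0("(?=", gsub("([][{}()*+?.\\^$|])", "\\\\\\1", ep), ")")
    m <- gregexpr(pat, proteins, perl = TRUE)
    for (i in seq_along(proteins)) {
      pos <- m[[i]]
      if (pos[1L] == -1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = names(proteins)[i], epitope = ep,
        position = as.integer(pos) - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(protein_id = character(0), epitope = character(0),
                      position = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$position, out$epitope), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize epitope matches by species
#'
#' @param matches output of [scan_proteome()] (possibly rbound across
#'   proteomes).
#' @param proteome_labels named character vector mapping protein_id to a
#'   species/proteome label; labels with no match still get a zero row.
#' @return `data.frame`: species, n_occurrences (total matches),
#'   n_epitopes (distinct epitopes matched).
#' @export
summarize_by_species <- function(matches, proteome_labels) {
  stopifnot(!is.null(names(proteome_labels)))
  species <- sort(unique(unname(proteome_labels)))
  lab <- proteome_labels[matches$protein_id]
  rows <- lapply(species, function(sp) {
    sel <- !is.na(lab) & lab == sp
    data.frame(species = sp, n_occurrences = sum(sel),
               n_epitopes = length(unique(matches$epitope[sel])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
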