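## TSV serialization of the ground-truth table.
##
## One TSV per component, written into a directory; headers are the
## documented column names used throughout the package.

#' Write a truth table to a directory of TSV files
#'
#' @param truth a `truth_table`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_truth_table <- function(truth, dir) {
  stopifnot(inherits(truth, "truth_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kv <- function(x, key) data.frame(id = names(x), value = unname(x),
                                    stringsAsFactors = FALSE)
  write_tsv(kv(truth$sequence_subgenome),
            file.path(dir, "sequence_subgenome.tsv"))
  write_tsv(kv(truth$scaffold_to_subgenome),
            file.path(dir, "scaffold_to_subgenome.tsv"))
  write_tsv(truth$homeolog_pairs, file.path(dir, "homeolog_pairs.tsv"))
  write_tsv(truth$gene_coordinates, file.path(dir, "gene_coordinates.tsv"))
  write_tsv(truth$scaffold_layout, file.path(dir, "scaffold_layout.tsv"))
  write_tsv(truth$spiked_ssrs, file.path(dir, "spiked_ssrs.tsv"))
  write_tsv(truth$spiked_epitopes, file.path(dir, "spiked_epitopes.tsv"))
  invisible(dir)
}

#' Read a truth table written by [write_truth_table()]
#'
#' @param dir directory holding the TSV files.
#' @return a `truth_table`.
#' @export
read_truth_table <- function(dir) {
  truth <- new_truth_table()
  unkv <- function(path) {
    df <- read_tsv(path, colClasses = "character")
    stats::setNames(df$value, df$id)
  }
  truth$sequence_subgenome <- unkv(file.path(dir, "sequence_subgenome.tsv"))
  truth$scaffold_to_subgenome <-
    unkv(file.path(dir, "scaffold_to_subgenome.tsv"))
  truth$homeolog_pairs <- read_tsv(file.path(dir, "homeolog_pairs.tsv"))
  truth$gene_coordinates <- read_tsv(file.path(dir, "gene_coordinates.tsv"))
  truth$scaffold_layout <- read_tsv(file.path(dir, "scaffold_layout.tsv"))
  truth$spiked_ssrs <- read_tsv(file.path(dir, "spiked_ssrs.tsv"))
  truth$spiked_epitopes <- read_tsv(file.path(dir, "spiked_epitopes.tsv"))
  truth
}
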