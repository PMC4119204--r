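# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (plain string handling, no shared code with the
# implementations they check).

# reverse complement without Biostrings
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# canonical k-mer multiplicity histogram by direct substring enumeration
oracle_kmer_hist <- function(reads, k) {
  kmers <- character(0)
  for (s in reads) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      km <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", km)) next
      rc <- oracle_revcomp(km)
      kmers <- c(kmers, if (km <= rc) km else rc)
    }
  }
  if (!length(kmers)) return(data.frame(multiplicity = integer(0),
                                        count = numeric(0)))
  mult <- table(kmers)
  h <- table(as.integer(mult))
  data.frame(multiplicity = as.integer(names(h)), count = as.numeric(h))
}

# synonymous site fraction of a codon by direct enumeration of the nine
# single-base changes (stop targets excluded from the denominator)
oracle_codon_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  chars <- strsplit(codon, "")[[1L]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; denom <- 0L
    for (b in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      alt <- chars; alt[pos] <- b
      aa <- code[[paste(alt, collapse = "")]]
      if (aa == "*") next
      denom <- denom + 1L
      if (aa == code[[codon]]) syn <- syn + 1L
    }
    if (denom > 0L) s <- s + syn / denom
  }
  s
}

# naive O(n*m) substring scan: every exact occurrence of every epitope
oracle_peptide_scan <- function(proteins, epitopes) {
  rows <- list()
  for (pid in names(proteins)) {
    s <- proteins[[pid]]
    for (ep in epitopes) {
      L <- nchar(ep)
      if (nchar(s) < L) next
      for (i in seq_len(nchar(s) - L + 1L)) {
        if (substr(s, i, i + L - 1L) == ep) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = pid, epitope = ep, position = i - 1L,
            stringsAsFactors = FALSE)
        }
      }
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

# exhaustive global-alignment score by recursion (tiny inputs only)
oracle_align_score <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0L)
    best <- -.Machine$integer.max
    if (i > 0L && j > 0L) {
      sub <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + sub)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# repeat-free DNA flank: regenerate until no SSR is detectable
flank <- function(n, seed) {
  set.seed(seed)
  repeat {
    s <- random_dna(n)
    if (nrow(find_ssrs(c(f = s))) == 0L) return(s)
  }
}

# random amino-acid string
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
        collapse = "")
}

# simulate + fragment + anchor a default-condition allotetraploid; returns
# the pieces the synteny/scaffolding tests need
make_toy_assembly <- function(seed, dropout = 0.1, ...) {
  cfg <- simulation_config(seed = seed, ...)
  sim <- simulate_allotetraploid(cfg)
  fr <- fragment_genome(c(sim$genome_a, sim$genome_b),
                        cfg$scaffold_mean_length_bp, sim$truth,
                        seed = seed + 1L)
  anchors <- make_anchor_table(fr$truth, dropout = dropout, seed = seed + 2L)
  list(cfg = cfg, sim = sim, scaffolds = fr$scaffolds, truth = fr$truth,
       anchors = anchors)
}

# label every placed scaffold via per-chromosome greedy partition
partition_all <- function(placements, threshold = 0.75) {
  do.call(rbind, lapply(sort(unique(placements$ref_chrom)), function(ch) {
    out <- greedy_partition(placements[placements$ref_chrom == ch, ,
                                       drop = FALSE], threshold = threshold)
    out$ref_chrom <- ch
    out
  }))
}

# truth homeolog scaffold pairs (one A-subgenome, one B-subgenome scaffold,
# same reference chromosome) whose placed intervals overlap > threshold,
# with whether the partition separated them
homeolog_pair_separation <- function(placements, labels, truth,
                                     threshold = 0.75) {
  pl <- merge(placements, labels[, c("scaffold_id", "label")],
              by = "scaffold_id")
  sub <- truth$scaffold_to_subgenome[pl$scaffold_id]
  pairs <- 0L; separated <- 0L
  for (ch in unique(pl$ref_chrom)) {
    p <- pl[pl$ref_chrom == ch, , drop = FALSE]
    av <- p[sub[p$scaffold_id] == "A", , drop = FALSE]
    bv <- p[sub[p$scaffold_id] == "B", , drop = FALSE]
    for (i in seq_len(nrow(av))) {
      for (j in seq_len(nrow(bv))) {
        ov <- overlap_fraction(c(av$ref_start[i], av$ref_end[i]),
                               c(bv$ref_start[j], bv$ref_end[j]))
        if (ov > threshold) {
          pairs <- pairs + 1L
          separated <- separated + (av$label[i] != bv$label[j])
        }
      }
    }
  }
  c(pairs = pairs, separated = separated)
}
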