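## Synthetic allotetraploid generator.
##
## Forward-simulates a toy allotetraploid: a random ancestor genome is
## duplicated into two subgenomes (A and B) that diverge from each other by
## d_AB expected substitutions/site under Jukes-Cantor, while an outgroup
## reference diverges so that each extant subgenome sits at d_out from it.
## Gene coordinates are identical across all copies (no indels), so
## homeologous CDS pairs are pre-aligned by construction.  Every downstream
## stage (synteny placement, A/B partitioning, Ks dating, k-mer genome size,
## SSR and epitope recovery) can therefore be tested against exact ground
## truth without any external data.

#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic allotetraploid
#' generator.  The divergence defaults mirror a recent within-genome
#' duplication (Ks mode ~0.05) and a ~36-million-year-old outgroup split
#' (Ks mode ~0.47) under the 6.5e-9 substitutions/site/year clock.
#'
#' @param n_chromosomes number of chromosomes per (sub)genome.
#' @param genes_per_chromosome genes per chromosome.
#' @param gene_length_codons gene length in codons (no stops, no introns).
#' @param intergenic_length_bp spacer length between and flanking genes.
#' @param d_AB expected substitutions/site between subgenomes A and B.
#' @param d_out expected substitutions/site between each extant subgenome
#'   and the outgroup reference.
#' @param scaffold_mean_length_bp mean scaffold length for fragmentation.
#' @param anchor_dropout probability in \[0,1) that a syntenic anchor is lost.
#' @param read_depth fold-coverage for read simulation.
#' @param read_length_bp read length.
#' @param seed master RNG seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_chromosomes = 2L,
                              genes_per_chromosome = 60L,
                              gene_length_codons = 200L,
                              intergenic_length_bp = 400L,
                              d_AB = 0.052,
                              d_out = 0.47,
                              scaffold_mean_length_bp = 6000L,
                              anchor_dropout = 0.1,
                              read_depth = 30,
                              read_length_bp = 100L,
                              seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              gene_length_codons = as.integer(gene_length_codons),
              intergenic_length_bp = as.integer(intergenic_length_bp),
              d_AB = d_AB, d_out = d_out,
              scaffold_mean_length_bp = as.integer(scaffold_mean_length_bp),
              anchor_dropout = anchor_dropout,
              read_depth = read_depth,
              read_length_bp = as.integer(read_length_bp),
              seed = as.integer(seed))
  counts <- c("n_chromosomes", "genes_per_chromosome", "gene_length_codons",
              "intergenic_length_bp", "scaffold_mean_length_bp",
              "read_length_bp")
  for (f in counts) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("simulation_config: '", f, "' must be a positive count")
  }
  if (!is.finite(cfg$read_depth) || cfg$read_depth <= 0)
    stop("simulation_config: 'read_depth' must be > 0")
  if (!(cfg$d_AB >= 0 && cfg$d_AB <= cfg$d_out && cfg$d_out < 3))
    stop("simulation_config: need 0 <= d_AB <= d_out < 3")
  if (!(cfg$anchor_dropout >= 0 && cfg$anchor_dropout < 1))
    stop("simulation_config: 'anchor_dropout' must be in [0,1)")
  structure(cfg, class = "simulation_config")
}

#' Empty ground-truth table
#'
#' @return an object of class `truth_table` with empty components.
#' @export
new_truth_table <- function() {
  structure(list(
    sequence_subgenome = character(0),
    scaffold_to_subgenome = character(0),
    homeolog_pairs = data.frame(gene_a = character(0), gene_b = character(0),
                                distance = numeric(0)),
    gene_coordinates = data.frame(seq_id = character(0), gene_id = character(0),
                                  start = integer(0), end = integer(0),
                                  strand = character(0)),
    scaffold_layout = data.frame(source_seq = character(0),
                                 scaffold_id = character(0),
                                 start = integer(0), end = integer(0)),
    spiked_ssrs = data.frame(seq_id = character(0), position = integer(0),
                             motif = character(0), repeat_count = integer(0)),
    spiked_epitopes = data.frame(protein_id = character(0),
                                 position = integer(0), peptide = character(0))
  ), class = "truth_table")
}

#' Evolve a DNA sequence under Jukes-Cantor
#'
#' Each site is independently replaced by one of the three other bases with
#' probability q = (3/4)(1 - exp(-4d/3)), the JC69 mismatch probability at
#' expected distance `d`.  No indels are introduced, so coordinates are
#' preserved.
#'
#' @param seq a DNA string over A/C/G/T.
#' @param d expected substitutions per site (>= 0).
#' @param seed optional RNG seed; `NULL` uses (and advances) the current
#'   stream, which is how the genome simulator composes many calls under one
#'   master seed.
#' @return the evolved DNA string, same length as the input.
#' @export
evolve_sequence <- function(seq, d, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  if (!is.numeric(d) || d < 0) stop("evolve_sequence: 'd' must be >= 0")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("evolve_sequence: non-ACGT character '", chars[bad],
         "' at position ", bad)
  }
  if (d == 0) return(seq)
  with_seed(seed, {
    q <- 0.75 * (1 - exp(-4 * d / 3))
    hit <- which(runif(length(idx)) < q)
    if (length(hit)) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      idx[hit] <- (idx[hit] - 1L + shift) %% 4L + 1L
      chars[hit] <- DNA_BASES[idx[hit]]
      paste(chars, collapse = "")
    } else {
      seq
    }
  })
}

#' Evolve a coding sequence neutrally, excluding nonsense changes
#'
#' Codon-aware companion to [evolve_sequence()]: each site substitutes with
#' the same Jukes-Cantor probability q = (3/4)(1 - exp(-4d/3)), but the
#' target base is drawn uniformly from the changes that keep the codon a
#' sense codon -- purifying selection against premature stops only,
#' otherwise neutral.  This is exactly the mutational opportunity space
#' that synonymous/non-synonymous site counting assumes, so [ng86_pair()]
#' recovers `d` without bias on sequences evolved this way.
#'
#' @param seq an in-frame CDS over A/C/G/T, length divisible by 3, no stop
#'   codons.
#' @param d expected substitutions per site (>= 0).
#' @param seed optional RNG seed (`NULL`: current stream).
#' @return the evolved CDS, same length, still stop-free.
#' @export
evolve_cds <- function(seq, d, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  if (!is.numeric(d) || d < 0) stop("evolve_cds: 'd' must be >= 0")
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("evolve_cds: length not divisible by 3")
  tabs <- .codon_tables()
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  bad <- which(!codons %in% tabs$codons)
  if (length(bad))
    stop("evolve_cds: non-sense codon '", codons[bad[1L]], "' at codon ",
         bad[1L])
  if (d == 0) return(seq)
  with_seed(seed, {
    q <- 0.75 * (1 - exp(-4 * d / 3))
    hit <- which(runif(n) < q)
    if (length(hit)) {
      u <- runif(length(hit))
      allowed <- tabs$allowed
      for (i in seq_along(hit)) {
        ci <- (hit[i] - 1L) %/% 3L + 1L
        pos <- hit[i] - 3L * (ci - 1L)
        alts <- allowed[[paste0(codons[ci], ".", pos)]]
        substr(codons[ci], pos, pos) <- alts[floor(u[i] * length(alts)) + 1L]
      }
      paste(codons, collapse = "")
    } else {
      seq
    }
  })
}

# evolve a chromosome piecewise: gene intervals (0-based half-open, sorted)
# codon-aware via evolve_cds, intergenic spacers via plain JC
.evolve_chromosome <- function(seq, gene_coords, d) {
  if (d == 0) return(seq)
  if (!nrow(gene_coords)) return(evolve_sequence(seq, d))
  gc <- gene_coords[order(gene_coords$start), , drop = FALSE]
  parts <- character(0)
  pos <- 0L
  for (i in seq_len(nrow(gc))) {
    if (gc$start[i] > pos)
      parts <- c(parts, evolve_sequence(substr(seq, pos + 1L, gc$start[i]), d))
    parts <- c(parts, evolve_cds(substr(seq, gc$start[i] + 1L, gc$end[i]), d))
    pos <- gc$end[i]
  }
  if (pos < nchar(seq))
    parts <- c(parts, evolve_sequence(substr(seq, pos + 1L, nchar(seq)), d))
  paste(parts, collapse = "")
}

# one ancestor chromosome: alternating intergenic spacers and stop-free genes
.make_chromosome <- function(cfg, chrom_idx) {
  codons61 <- .codon_tables()$codons
  n_genes <- cfg$genes_per_chromosome
  glen <- cfg$gene_length_codons * 3L
  ilen <- cfg$intergenic_length_bp
  parts <- character(2L * n_genes + 1L)
  coords <- data.frame(gene_key = sprintf("c%d_g%03d", chrom_idx, seq_len(n_genes)),
                       start = integer(n_genes), end = integer(n_genes))
  pos <- 0L
  parts[1L] <- random_dna(ilen); pos <- pos + ilen
  for (g in seq_len(n_genes)) {
    gene <- paste(sample(codons61, cfg$gene_length_codons, replace = TRUE),
                  collapse = "")
    parts[2L * g] <- gene
    coords$start[g] <- pos
    coords$end[g] <- pos + glen
    pos <- pos + glen
    parts[2L * g + 1L] <- random_dna(ilen); pos <- pos + ilen
  }
  list(seq = paste(parts, collapse = ""), coords = coords)
}

#' Simulate an allotetraploid genome with outgroup and ground truth
#'
#' Draws a random ancestor, evolves subgenomes A and B from it by `d_AB`/2
#' each, and evolves the outgroup so that the expected distance between each
#' extant subgenome copy and the outgroup is `d_out` (the quantity the
#' Ks-vs-outgroup comparison actually measures).  Gene coordinates are
#' identical across the three genomes.
#'
#' @param config a [simulation_config()].
#' @return list with `genome_a`, `genome_b`, `outgroup` (named character
#'   vectors of chromosome sequences), `truth` (a `truth_table`) and `config`.
#' @export
simulate_allotetraploid <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    truth <- new_truth_table()
    genome_a <- genome_b <- outgroup <- character(0)
    gene_rows <- list()
    pair_rows <- list()
    for (i in seq_len(config$n_chromosomes)) {
      anc <- .make_chromosome(config, i)
      a_id <- sprintf("tefA_chr%d", i)
      b_id <- sprintf("tefB_chr%d", i)
      r_id <- sprintf("ref_chr%d", i)
      genome_a[[a_id]] <- .evolve_chromosome(anc$seq, anc$coords, config$d_AB / 2)
      genome_b[[b_id]] <- .evolve_chromosome(anc$seq, anc$coords, config$d_AB / 2)
      # root sits (d_out - d_AB)/2 above the tef ancestor so that
      # E[d(A, outgroup)] = d_AB/2 + (d_out - d_AB)/2 + d_out/2 = d_out
      root <- .evolve_chromosome(anc$seq, anc$coords, (config$d_out - config$d_AB) / 2)
      outgroup[[r_id]] <- .evolve_chromosome(root, anc$coords, config$d_out / 2)
      for (lab in c("A", "B", "R")) {
        sid <- c(A = a_id, B = b_id, R = r_id)[[lab]]
        gene_rows[[paste0(lab, i)]] <- data.frame(
          seq_id = sid,
          gene_id = paste0("g", lab, "_", anc$coords$gene_key),
          start = anc$coords$start, end = anc$coords$end, strand = "+")
      }
      pair_rows[[i]] <- data.frame(
        gene_a = paste0("gA_", anc$coords$gene_key),
        gene_b = paste0("gB_", anc$coords$gene_key),
        distance = config$d_AB)
      truth$sequence_subgenome[[a_id]] <- "A"
      truth$sequence_subgenome[[b_id]] <- "B"
    }
    truth$gene_coordinates <- do.call(rbind, unname(gene_rows))
    truth$homeolog_pairs <- do.call(rbind, pair_rows)
    list(genome_a = genome_a, genome_b = genome_b, outgroup = outgroup,
         truth = truth, config = config)
  })
}

#' Fragment chromosomes into draft-assembly style scaffolds
#'
#' Cut points are drawn so scaffold lengths are approximately exponential
#' with the requested mean; any cut falling inside a gene is shifted to the
#' nearest gene boundary, so genes never straddle scaffolds and syntenic
#' anchors stay intact.  Concatenating the scaffolds of a chromosome in
#' truth-table order reproduces the chromosome exactly.
#'
#' @param genome named character vector of chromosome sequences.
#' @param mean_length target mean scaffold length (bp); must be at least
#'   twice the longest gene.
#' @param truth the `truth_table` holding gene coordinates for `genome`.
#' @param seed optional RNG seed.
#' @return list with `scaffolds` (named character vector) and the updated
#'   `truth` (scaffold layout, subgenome labels, per-scaffold gene
#'   coordinates appended).
#' @export
fragment_genome <- function(genome, mean_length, truth, seed = NULL) {
  stopifnot(is.character(genome), !is.null(names(genome)),
            inherits(truth, "truth_table"))
  gc <- truth$gene_coordinates
  gmax <- if (nrow(gc)) max(gc$end - gc$start) else 0L
  if (mean_length < 2L * gmax)
    stop("fragment_genome: mean_length (", mean_length,
         ") must be >= 2x the longest gene (", gmax, ")")
  with_seed(seed, {
    scaffolds <- character(0)
    layout <- list()
    gene_add <- list()
    for (sid in names(genome)) {
      len <- nchar(genome[[sid]])
      genes <- gc[gc$seq_id == sid, , drop = FALSE]
      cuts <- integer(0)
      if (mean_length < len) {     # mean >= length: whole chromosome stays one scaffold
        pos <- 0
        repeat {
          pos <- pos + max(1, rexp(1L, rate = 1 / mean_length))
          if (pos >= len) break
          cuts <- c(cuts, as.integer(round(pos)))
        }
      }
      if (length(cuts) && nrow(genes)) {
        for (j in seq_along(cuts)) {
          inside <- which(genes$start < cuts[j] & cuts[j] < genes$end)
          if (length(inside)) {
            g <- genes[inside[1L], ]
            cuts[j] <- if (cuts[j] - g$start <= g$end - cuts[j]) g$start else g$end
          }
        }
      }
      bounds <- unique(sort(c(0L, cuts[cuts > 0L & cuts < len], len)))
      for (j in seq_len(length(bounds) - 1L)) {
        s <- bounds[j]; e <- bounds[j + 1L]
        scf <- sprintf("%s_s%02d", sid, j)
        scaffolds[[scf]] <- substr(genome[[sid]], s + 1L, e)
        layout[[length(layout) + 1L]] <- data.frame(
          source_seq = sid, scaffold_id = scf, start = s, end = e)
        if (!is.na(truth$sequence_subgenome[sid]))
          truth$scaffold_to_subgenome[[scf]] <-
            unname(truth$sequence_subgenome[sid])
        hit <- genes[genes$start >= s & genes$end <= e, , drop = FALSE]
        if (nrow(hit)) {
          hit$seq_id <- scf
          hit$start <- hit$start - s
          hit$end <- hit$end - s
          gene_add[[length(gene_add) + 1L]] <- hit
        }
      }
    }
    truth$scaffold_layout <- rbind(truth$scaffold_layout,
                                   do.call(rbind, layout))
    rownames(truth$scaffold_layout) <- NULL
    if (length(gene_add)) {
      truth$gene_coordinates <- rbind(truth$gene_coordinates,
                                      do.call(rbind, gene_add))
      rownames(truth$gene_coordinates) <- NULL
    }
    list(scaffolds = scaffolds, truth = truth)
  })
}

#' Build a syntenic anchor table from ground truth
#'
#' Emits one anchor per (scaffold gene copy, orthologous outgroup gene)
#' pair, dropping each independently with probability `dropout` to emulate
#' imperfect synteny detection.
#'
#' @param truth a fragmented `truth_table` (scaffold gene coordinates
#'   present).
#' @param dropout per-anchor loss probability in \[0,1).
#' @param seed optional RNG seed.
#' @return an anchor `data.frame` in the standard dialect (see
#'   [read_anchor_table()]).
#' @export
make_anchor_table <- function(truth, dropout = 0, seed = NULL) {
  stopifnot(inherits(truth, "truth_table"))
  if (!(dropout >= 0 && dropout < 1))
    stop("make_anchor_table: 'dropout' must be in [0,1)")
  gc <- truth$gene_coordinates
  on_scaffold <- gc$seq_id %in% names(truth$scaffold_to_subgenome)
  scf <- gc[on_scaffold & grepl("^g[AB]_", gc$gene_id), , drop = FALSE]
  ref <- gc[grepl("^gR_", gc$gene_id), , drop = FALSE]
  key_scf <- sub("^g[AB]_", "", scf$gene_id)
  key_ref <- sub("^gR_", "", ref$gene_id)
  m <- match(key_scf, key_ref)
  keep <- !is.na(m)
  anchors <- data.frame(
    scaffold_id = scf$seq_id[keep],
    scaffold_start = scf$start[keep],
    scaffold_end = scf$end[keep],
    ref_chrom = ref$seq_id[m[keep]],
    ref_start = ref$start[m[keep]],
    ref_end = ref$end[m[keep]],
    scaffold_gene = scf$gene_id[keep],
    ref_gene = ref$gene_id[m[keep]],
    stringsAsFactors = FALSE)
  with_seed(seed, {
    if (dropout > 0 && nrow(anchors))
      anchors <- anchors[runif(nrow(anchors)) >= dropout, , drop = FALSE]
    rownames(anchors) <- NULL
    anchors
  })
}

#' Simulate error-free sequencing reads
#'
#' Reads are drawn uniformly from both strands of the input sequences
#' (sequences weighted by their number of valid start positions); the read
#' count is `ceiling(depth * G / read_length)` so total bases approximate
#' `depth` times the genome size.  No sequencing errors are introduced.
#'
#' @param genome named character vector of sequences.
#' @param depth target fold-coverage.
#' @param read_length read length (bp).
#' @param seed optional RNG seed.
#' @return named character vector of reads.
#' @export
simulate_reads <- function(genome, depth, read_length, seed = NULL) {
  stopifnot(is.character(genome), length(genome) >= 1L)
  lens <- nchar(genome)
  if (any(lens < read_length)) {
    warning("simulate_reads: ", sum(lens < read_length),
            " sequence(s) shorter than the read length contribute no reads")
  }
  elig <- which(lens >= read_length)
  if (!length(elig)) stop("simulate_reads: no sequence is long enough")
  G <- sum(lens)
  n_reads <- as.integer(ceiling(depth * G / read_length))
  with_seed(seed, {
    nstarts <- lens[elig] - read_length + 1L
    src <- elig[sample.int(length(elig), n_reads, replace = TRUE,
                           prob = nstarts)]
    start <- integer(n_reads)
    for (ei in unique(src)) {
      sel <- src == ei
      start[sel] <- sample.int(lens[ei] - read_length + 1L, sum(sel),
                               replace = TRUE)
    }
    minus <- runif(n_reads) < 0.5
    reads <- character(n_reads)
    for (ei in unique(src)) {
      sel <- src == ei
      reads[sel] <- substring(genome[[ei]], start[sel],
                              start[sel] + read_length - 1L)
    }
    if (any(minus)) reads[minus] <- revcomp(reads[minus])
    names(reads) <- sprintf("read%07d", seq_len(n_reads))
    reads
  })
}

#' Simulate divergent CDS pairs for divergence-estimator calibration
#'
#' Draws `n_pairs` random stop-free ancestor CDS of `n_codons` codons
#' (codons uniform over the 61 sense codons) and evolves two descendants
#' from each by `d/2` with [evolve_cds()], giving pairs with expected
#' pairwise divergence `d`.  Pairs are gap-free and pre-aligned by
#' construction.
#'
#' @param n_pairs number of pairs.
#' @param n_codons codons per sequence.
#' @param d expected pairwise substitutions/site between the two copies.
#' @param seed optional RNG seed.
#' @return list with character vectors `a` and `b` of length `n_pairs`.
#' @export
simulate_cds_pairs <- function(n_pairs, n_codons, d, seed = NULL) {
  stopifnot(n_pairs >= 1L, n_codons >= 1L, d >= 0)
  codons61 <- .codon_tables()$codons
  with_seed(seed, {
    a <- character(n_pairs)
    b <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      anc <- paste(sample(codons61, n_codons, replace = TRUE), collapse = "")
      a[[i]] <- evolve_cds(anc, d / 2)
      b[[i]] <- evolve_cds(anc, d / 2)
    }
    list(a = a, b = b)
  })
}

#' Insert a payload into a sequence
#'
#' Pure string insertion at a 0-based position; position 0 prepends and
#' position `nchar(seq)` appends.  Used to spike SSR arrays into DNA and
#' epitopes into proteins; recording the spike in a `truth_table` is done
#' with [truth_add_ssr()] / [truth_add_epitope()].
#'
#' @param seq a character string.
#' @param position 0-based insertion offset in `0:nchar(seq)`.
#' @param payload string to insert.
#' @return the modified string.
#' @export
spike_feature <- function(seq, position, payload) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (!(position >= 0 && position <= n))
    stop("spike_feature: position must be in [0, ", n, "]")
  paste0(substr(seq, 1L, position), payload,
         substr(seq, position + 1L, n))
}

#' @rdname spike_feature
#' @param truth a `truth_table`.
#' @param seq_id sequence the SSR was spiked into.
#' @param motif repeat motif as inserted.
#' @param repeat_count number of tandem copies inserted.
#' @export
truth_add_ssr <- function(truth, seq_id, position, motif, repeat_count) {
  truth$spiked_ssrs <- rbind(truth$spiked_ssrs, data.frame(
    seq_id = seq_id, position = as.integer(position),
    motif = motif, repeat_count = as.integer(repeat_count)))
  truth
}

#' @rdname spike_feature
#' @param protein_id protein the peptide was spiked into.
#' @param peptide amino-acid string inserted.
#' @export
truth_add_epitope <- function(truth, protein_id, position, peptide) {
  truth$spiked_epitopes <- rbind(truth$spiked_epitopes, data.frame(
    protein_id = protein_id, position = as.integer(position),
    peptide = peptide))
  truth
}
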