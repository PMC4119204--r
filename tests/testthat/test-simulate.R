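# Synthetic allotetraploid generator: substitution model calibration,
# determinism, fragmentation conservation, anchors, reads and spikes.

test_that("evolve_sequence honors the Jukes-Cantor mismatch probability", {
  set.seed(404)
  s <- random_dna(3000)
  expect_identical(evolve_sequence(s, 0, seed = 1), s)
  diff_frac <- function(a, b) {
    mean(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  }
  for (d in c(0.052, 0.47)) {
    q <- 0.75 * (1 - exp(-4 * d / 3))
    obs <- diff_frac(s, evolve_sequence(s, d, seed = 11))
    expect_lt(abs(obs - q), 3 * sqrt(q * (1 - q) / 3000))
  }
  # same seed -> identical output; different seed -> (almost surely) not
  expect_identical(evolve_sequence(s, 0.1, seed = 5),
                   evolve_sequence(s, 0.1, seed = 5))
  expect_false(identical(evolve_sequence(s, 0.1, seed = 5),
                         evolve_sequence(s, 0.1, seed = 6)))
})

test_that("evolve_sequence rejects non-ACGT input with a position report", {
  expect_error(evolve_sequence("ACGNT", 0.1, seed = 1), "position 4")
  expect_error(evolve_sequence("acgt", 0.1, seed = 1), "position 1")
})

test_that("evolve_cds keeps sequences stop-free and recovers divergence", {
  p <- simulate_cds_pairs(60, 120, 0.1, seed = 9)
  code <- Biostrings::GENETIC_CODE
  for (s in c(p$a, p$b)) {
    starts <- seq(1L, nchar(s), by = 3L)
    expect_false(any(code[substring(s, starts, starts + 2L)] == "*"))
  }
  # pairwise difference fraction matches the JC expectation at d = 0.1
  q <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  obs <- mapply(function(a, b) {
    mean(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  }, p$a, p$b)
  expect_lt(abs(mean(obs) - q), 3 * sd(obs) / sqrt(length(obs)))
  expect_error(evolve_cds("TAA", 0.1), "non-sense codon")
  expect_error(evolve_cds("ACGT", 0.1), "divisible by 3")
})

test_that("simulate_allotetraploid emits complete, reproducible truth", {
  cfg <- simulation_config(n_chromosomes = 1L, genes_per_chromosome = 10L,
                           gene_length_codons = 50L,
                           intergenic_length_bp = 100L, seed = 3L)
  sim <- simulate_allotetraploid(cfg)
  expect_equal(nrow(sim$truth$homeolog_pairs), 10L)
  # gene coordinates identical across the three copies
  gc <- sim$truth$gene_coordinates
  expect_equal(nrow(gc), 30L)
  key <- sub("^g[ABR]_", "", gc$gene_id)
  for (k in unique(key)) {
    expect_equal(length(unique(gc$start[key == k])), 1L)
    expect_equal(length(unique(gc$end[key == k])), 1L)
  }
  # d_AB = 0 makes the subgenomes identical
  cfg0 <- simulation_config(n_chromosomes = 1L, genes_per_chromosome = 5L,
                            gene_length_codons = 30L,
                            intergenic_length_bp = 50L, d_AB = 0,
                            seed = 4L)
  sim0 <- simulate_allotetraploid(cfg0)
  expect_identical(unname(sim0$genome_a), unname(sim0$genome_b))
  # byte-identical FASTA across two runs with the same config
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(simulate_allotetraploid(cfg)$genome_a, f1)
  write_fasta(simulate_allotetraploid(cfg)$genome_a, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("homeolog divergence calibrates to the closed-form JC fraction", {
  # distance calibration over >= 1000 gene pairs at the default d_AB
  d <- 0.052
  p <- simulate_cds_pairs(1000, 100, d, seed = 21)
  obs <- mapply(function(a, b) {
    mean(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  }, p$a, p$b)
  q <- 0.75 * (1 - exp(-4 * d / 3))
  expect_lt(abs(mean(obs) - q), 3 * sd(obs) / sqrt(length(obs)))
})

test_that("fragment_genome conserves sequence and never cuts genes", {
  cfg <- simulation_config(n_chromosomes = 1L, genes_per_chromosome = 30L,
                           gene_length_codons = 100L,
                           intergenic_length_bp = 200L, seed = 7L)
  sim <- simulate_allotetraploid(cfg)
  genome <- c(sim$genome_a, sim$genome_b)
  fr <- fragment_genome(genome, 3000L, sim$truth, seed = 8L)
  lay <- fr$truth$scaffold_layout
  for (sid in names(genome)) {
    rows <- lay[lay$source_seq == sid, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    expect_identical(paste(fr$scaffolds[rows$scaffold_id], collapse = ""),
                     genome[[sid]])
    expect_equal(sum(rows$end - rows$start), nchar(genome[[sid]]))
  }
  # every gene interval of a fragmented chromosome sits wholly inside a
  # single scaffold
  gc0 <- sim$truth$gene_coordinates
  gc0 <- gc0[gc0$seq_id %in% names(genome), , drop = FALSE]
  for (i in seq_len(nrow(gc0))) {
    rows <- lay[lay$source_seq == gc0$seq_id[i], , drop = FALSE]
    host <- rows[rows$start <= gc0$start[i] & rows$end >= gc0$end[i], ,
                 drop = FALSE]
    expect_equal(nrow(host), 1L)
  }
  # scaffold gene coordinates agree with the extracted sequences
  gs <- fr$truth$gene_coordinates
  gs <- gs[gs$seq_id %in% names(fr$scaffolds), , drop = FALSE]
  pick <- gs[c(1L, nrow(gs)), ]
  for (i in seq_len(nrow(pick))) {
    chrom_row <- gc0[gc0$gene_id == pick$gene_id[i], ]
    expect_identical(
      substr(fr$scaffolds[[pick$seq_id[i]]], pick$start[i] + 1L, pick$end[i]),
      substr(genome[[chrom_row$seq_id]], chrom_row$start + 1L, chrom_row$end))
  }
})

test_that("fragment_genome honors its boundary contracts", {
  cfg <- simulation_config(n_chromosomes = 1L, genes_per_chromosome = 5L,
                           gene_length_codons = 50L,
                           intergenic_length_bp = 100L, seed = 5L)
  sim <- simulate_allotetraploid(cfg)
  # mean >= chromosome length: one scaffold per chromosome
  fr <- fragment_genome(sim$genome_a, 10L * nchar(sim$genome_a[[1L]]),
                        sim$truth, seed = 1L)
  expect_length(fr$scaffolds, 1L)
  expect_identical(unname(fr$scaffolds), unname(sim$genome_a))
  # mean below twice the longest gene is rejected
  expect_error(fragment_genome(sim$genome_a, 200L, sim$truth, seed = 1L),
               "2x the longest gene")
})

test_that("anchor tables respect dropout and determinism", {
  toy <- make_toy_assembly(31L, dropout = 0)
  n_genes_on_scaffolds <- sum(grepl(
    "^g[AB]_",
    toy$truth$gene_coordinates$gene_id[
      toy$truth$gene_coordinates$seq_id %in% names(toy$scaffolds)]))
  expect_equal(nrow(toy$anchors), n_genes_on_scaffolds)
  expect_error(make_anchor_table(toy$truth, dropout = 1), "\\[0,1\\)")
  a1 <- make_anchor_table(toy$truth, dropout = 0.1, seed = 5L)
  a2 <- make_anchor_table(toy$truth, dropout = 0.1, seed = 5L)
  expect_identical(a1, a2)
  expect_lt(nrow(a1), nrow(toy$anchors))
})

test_that("simulated reads have the contracted count and origin", {
  set.seed(77)
  genome <- c(chrA = random_dna(20000), chrB = random_dna(10000))
  reads <- simulate_reads(genome, depth = 5, read_length = 100L, seed = 9L)
  expect_length(reads, ceiling(5 * 30000 / 100))
  expect_true(all(nchar(reads) == 100L))
  # every read is an exact substring of the genome or its reverse complement
  haystack <- paste(c(genome, revcomp(genome)), collapse = "#")
  for (r in reads[seq(1L, length(reads), by = 37L)]) {
    expect_true(grepl(r, haystack, fixed = TRUE))
  }
  expect_identical(reads,
                   simulate_reads(genome, 5, 100L, seed = 9L))
})

test_that("spike_feature inserts payloads at exact boundaries", {
  s <- "ACGTACGT"
  expect_identical(spike_feature(s, 0L, "TTT"), "TTTACGTACGT")
  expect_identical(spike_feature(s, 8L, "TTT"), "ACGTACGTTTT")
  expect_error(spike_feature(s, 9L, "T"), "position")
  arr <- strrep("AG", 6L)
  sp <- spike_feature(random_dna(200), 100L, arr)
  expect_identical(substr(sp, 101L, 100L + nchar(arr)), arr)
  # epitope recovery by slicing
  pep <- "QQPFPQQAYPQS"
  prot <- spike_feature(random_protein(80), 40L, pep)
  expect_identical(substr(prot, 41L, 40L + nchar(pep)), pep)
})
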