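# Scaffold ordering, overlap-based A/B partitioning, pseudo-chromosome
# assembly with AGP round-trip, and aligned identity.

mk_place <- function(id, start, end, chrom = "ref_chr1", ori = "+") {
  data.frame(scaffold_id = id, scaffold_length = end - start,
             ref_chrom = chrom, ref_start = start, ref_end = end,
             orientation = ori, n_anchors = 3L, stringsAsFactors = FALSE)
}

test_that("order_scaffolds sorts by start, end, then id", {
  p <- rbind(mk_place("c", 10L, 40L), mk_place("a", 5L, 30L),
             mk_place("b", 7L, 20L))
  expect_identical(order_scaffolds(p)$scaffold_id, c("a", "b", "c"))
  ties <- rbind(mk_place("x", 0L, 30L), mk_place("w", 0L, 20L))
  expect_identical(order_scaffolds(ties)$scaffold_id, c("w", "x"))
  idtie <- rbind(mk_place("n2", 0L, 10L), mk_place("n1", 0L, 10L))
  expect_identical(order_scaffolds(idtie)$scaffold_id, c("n1", "n2"))
  single <- mk_place("only", 3L, 9L)
  expect_identical(order_scaffolds(single), single)
})

test_that("overlap_fraction normalizes by the shorter interval", {
  expect_equal(overlap_fraction(c(0, 100), c(0, 100)), 1)
  expect_equal(overlap_fraction(c(0, 100), c(200, 300)), 0)
  expect_equal(overlap_fraction(c(0, 100), c(50, 250)), 0.5)
  # nested short interval counts as full overlap; symmetric
  expect_equal(overlap_fraction(c(10, 20), c(0, 100)), 1)
  expect_equal(overlap_fraction(c(0, 100), c(10, 20)), 1)
  expect_error(overlap_fraction(c(5, 5), c(0, 10)), "empty")
})

test_that("greedy_partition follows the literal first-to-A rule", {
  expect_identical(greedy_partition(mk_place("s1", 0L, 100L))$label, "A")
  twins <- rbind(mk_place("s1", 0L, 1000L), mk_place("s2", 0L, 1000L))
  expect_identical(greedy_partition(twins)$label, c("A", "B"))
  disjoint <- rbind(mk_place("s1", 0L, 100L), mk_place("s2", 500L, 700L))
  expect_identical(greedy_partition(disjoint)$label, c("A", "A"))
  # strict inequality at the threshold: exactly 75% overlap stays in A
  exact <- rbind(mk_place("s1", 0L, 100L), mk_place("s2", 25L, 125L))
  expect_identical(greedy_partition(exact)$label, c("A", "A"))
  over <- rbind(mk_place("s1", 0L, 100L), mk_place("s2", 24L, 124L))
  expect_identical(greedy_partition(over)$label, c("A", "B"))
  # overlap is tested against A members only: a scaffold nested in a B
  # scaffold (but clear of all A) still goes to A
  chain <- rbind(mk_place("s1", 0L, 1000L), mk_place("s2", 0L, 1000L),
                 mk_place("s3", 600L, 1000L))
  # s3 overlaps s1 (A) at 400/400 = 1 -> B; next case isolates the rule
  expect_identical(greedy_partition(chain)$label, c("A", "B", "B"))
  bcase <- rbind(mk_place("s1", 0L, 400L), mk_place("s2", 0L, 2000L),
                 mk_place("s3", 1500L, 1900L))
  # s2 vs s1: 400/400 -> B; s3 overlaps only s2 (B) -> stays A
  lab <- greedy_partition(bcase)
  expect_identical(lab$label, c("A", "B", "A"))
  amb <- greedy_partition(bcase, check_b = TRUE)
  expect_identical(amb$label, lab$label)
  expect_false(any(amb$ambiguous))
  expect_error(greedy_partition(rbind(mk_place("a", 0L, 10L),
                                      mk_place("b", 0L, 10L, chrom = "ref_chr2"))),
               "one reference chromosome")
})

test_that("pseudo-chromosomes assemble with exact layout and AGP round-trip", {
  set.seed(51)
  seqs <- c(m1 = random_dna(1000), m2 = random_dna(2000), m3 = random_dna(500))
  members <- data.frame(scaffold_id = c("m1", "m2", "m3"),
                        orientation = c("+", "-", "+"))
  ps <- build_pseudochromosome(members, seqs, gap_length = 100L,
                               name = "pseudo9")
  expect_equal(ps$length, 1000L + 2000L + 500L + 200L)
  expect_equal(nchar(ps$sequence), ps$length)
  expect_identical(substr(ps$sequence, 1L, 1000L), seqs[["m1"]])
  expect_identical(substr(ps$sequence, 1001L, 1100L), strrep("N", 100L))
  expect_identical(substr(ps$sequence, 1101L, 3100L), revcomp(seqs[["m2"]]))
  # single members, both orientations
  one <- data.frame(scaffold_id = "m3", orientation = "+")
  expect_identical(build_pseudochromosome(one, seqs)$sequence, seqs[["m3"]])
  one$orientation <- "-"
  expect_identical(build_pseudochromosome(one, seqs)$sequence,
                   revcomp(seqs[["m3"]]))
  expect_error(build_pseudochromosome(
    data.frame(scaffold_id = "nope", orientation = "+"), seqs), "nope")
  # AGP round-trips exactly
  path <- tempfile(fileext = ".agp")
  write_agp(ps$agp, path)
  expect_identical(read_agp(path), ps$agp)
  # coordinate lift-over is exact, including through reverse complement
  expect_equal(lift_to_pseudo(ps$layout, "m1", 0L), 0L)
  expect_equal(lift_to_pseudo(ps$layout, "m1", 999L), 999L)
  expect_equal(lift_to_pseudo(ps$layout, "m2", 0L), 1100L + 1999L)
  expect_equal(lift_to_pseudo(ps$layout, "m2", 1999L), 1100L)
  base_at <- function(pos) substr(ps$sequence, pos + 1L, pos + 1L)
  expect_identical(base_at(lift_to_pseudo(ps$layout, "m2", 7L)),
                   chartr("ACGT", "TGCA", substr(seqs[["m2"]], 8L, 8L)))
  expect_error(lift_to_pseudo(ps$layout, "m1", 1000L), "outside")
})

test_that("ab_identity counts only mutually ungapped columns", {
  expect_equal(ab_identity(list(c("ACGT", "ACGT"))), 100)
  # 7 mismatches over 100 comparable columns -> 93%
  set.seed(61)
  a <- random_dna(100)
  ch <- strsplit(a, "")[[1L]]
  flip <- sample.int(100L, 7L)
  ch[flip] <- vapply(ch[flip], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1L))
  b <- paste(ch, collapse = "")
  expect_equal(ab_identity(list(c(a, b))), 93)
  # gap columns (in either sequence) leave the denominator
  expect_equal(ab_identity(list(c("AC-GT-", "ACTG-A"))), 100 * 3 / 3)
  expect_equal(ab_identity(list(c("ACG-", "A-GT"))), 100)
  # weighting by compared columns across pairs
  expect_equal(ab_identity(list(c("AAAA", "AAAT"), c("CC", "CC"))),
               100 * 5 / 6)
  expect_warning(out <- ab_identity(list(c("--", "AA"))), "no comparable")
  expect_true(is.na(out))
})

test_that("homeolog scaffold pairs separate into different groups", {
  total <- c(pairs = 0L, separated = 0L)
  for (seed in c(201L, 202L)) {
    toy <- make_toy_assembly(seed, dropout = 0.1)
    pl <- place_scaffolds(toy$anchors, min_genes = 3L,
                          scaffold_lengths = nchar(toy$scaffolds))
    labels <- partition_all(pl)
    # first processed scaffold of every chromosome lands in A
    for (ch in unique(labels$ref_chrom)) {
      expect_identical(labels$label[labels$ref_chrom == ch][1L], "A")
    }
    total <- total + homeolog_pair_separation(pl, labels, toy$truth)
  }
  expect_gt(total[["pairs"]], 10L)
  expect_gte(total[["separated"]] / total[["pairs"]], 0.95)
})
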