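# SSR detection at MISA thresholds, in-silico PCR, and genetic-map
# linking.

test_that("find_ssrs applies per-motif-length minimum repeat counts", {
  left <- flank(60L, 1L); right <- flank(60L, 2L)
  # the separator base (absent from the motif) stops flanks from
  # extending the planted run, keeping boundary positions exact
  wrap <- function(core, sep) c(x = paste0(left, sep, core, sep, right))
  # boundary cases at the MISA minima
  expect_equal(nrow(find_ssrs(wrap(strrep("A", 9L), "C"))), 0L)
  a10 <- find_ssrs(wrap(strrep("A", 10L), "C"))
  expect_equal(nrow(a10), 1L)
  expect_equal(a10$repeat_count, 10L)
  expect_identical(a10$motif, "A")
  expect_equal(a10$start, 61L)
  expect_equal(nrow(find_ssrs(wrap(strrep("AG", 5L), "C"))), 0L)
  ag6 <- find_ssrs(wrap(strrep("AG", 6L), "C"))
  expect_equal(nrow(ag6), 1L)
  expect_equal(ag6$start, 61L)
  expect_equal(ag6$end, 73L)
  expect_equal(ag6$repeat_count, 6L)
  acg5 <- find_ssrs(wrap(strrep("ACG", 5L), "T"))
  expect_equal(nrow(acg5), 1L)
  expect_equal(acg5$motif_length, 3L)
  for (m in c("ACGT", "ACGTG", "ACGTGC")) {
    r <- find_ssrs(wrap(strrep(m, 5L), "T"))
    expect_equal(nrow(r), 1L, label = m)
    expect_equal(r$repeat_count, 5L, label = m)
  }
})

test_that("runs report at their shortest period and maximal extent", {
  left <- flank(50L, 3L); right <- flank(50L, 4L)
  # (AG)x8 must not additionally surface as AGAG or AGAGAG
  r <- find_ssrs(c(x = paste0(left, "C", strrep("AG", 8L), "C", right)))
  expect_equal(nrow(r), 1L)
  expect_identical(r$motif, "AG")
  expect_equal(r$repeat_count, 8L)
  # a mononucleotide run is not re-reported as AA
  r2 <- find_ssrs(c(x = paste0(left, "C", strrep("A", 14L), "C", right)))
  expect_equal(nrow(r2), 1L)
  expect_identical(r2$motif, "A")
  expect_equal(r2$repeat_count, 14L)
  # runs containing N terminate
  r3 <- find_ssrs(c(x = paste0(left, "C", strrep("AG", 6L), "N",
                               strrep("AG", 3L), "C", right)))
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$repeat_count, 6L)
})

test_that("SSR detection is invariant under reverse complement", {
  left <- flank(40L, 5L); mid <- flank(80L, 6L); right <- flank(40L, 7L)
  s <- paste0(left, strrep("AAG", 6L), mid, strrep("CT", 7L), right)
  fwd <- find_ssrs(c(x = s), max_interruption = 0L)
  rev <- find_ssrs(c(x = revcomp(s)), max_interruption = 0L)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(fwd$repeat_count), sort(rev$repeat_count))
  expect_equal(sort(fwd$motif_length), sort(rev$motif_length))
})

test_that("nearby SSRs merge into compound records", {
  left <- flank(60L, 8L); gap50 <- flank(48L, 9L); right <- flank(60L, 10L)
  s1 <- paste0(left, "C", strrep("AG", 6L), "C", gap50, "G",
               strrep("TC", 7L), "G", right)
  comp <- find_ssrs(c(x = s1))
  expect_equal(nrow(comp), 1L)
  expect_identical(comp$kind, "compound")
  expect_identical(comp$motif, "AG+TC")
  expect_equal(comp$repeat_count, 13L)   # interruption bases excluded
  # beyond max_interruption the records stay simple
  apart <- find_ssrs(c(x = s1), max_interruption = 30L)
  expect_equal(nrow(apart), 2L)
  expect_identical(apart$kind, c("simple", "simple"))
})

test_that("ssr_density divides genome length by qualifying SSR count", {
  ssrs <- data.frame(sequence_id = "x", start = c(0L, 100L), end = c(20L, 130L),
                     motif = c("A", "AG"), motif_length = c(1L, 2L),
                     repeat_count = c(20L, 15L), kind = "simple")
  expect_equal(ssr_density(1e5, ssrs), 5e4)
  expect_equal(ssr_density(1e5, ssrs, min_motif_length = 2L), 1e5)
  expect_warning(d0 <- ssr_density(1e5, ssrs[0L, ]), "undefined")
  expect_true(is.na(d0))
})

test_that("epcr_locate finds planted primer pairs on both strands", {
  set.seed(31)
  fwd <- random_dna(20L); rev <- random_dna(20L)
  backbone <- flank(600L, 11L)
  # plant forward at 100 and the reverse complement ending at 320
  s <- backbone
  substr(s, 101L, 120L) <- fwd
  substr(s, 301L, 320L) <- revcomp(rev)
  amp <- epcr_locate(c(chr = s), fwd, rev)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 100L)
  expect_equal(amp$end, 320L)
  expect_equal(amp$product_length, 220L)
  expect_identical(amp$strand, "+")
  # the same pair planted on the minus strand is found with strand '-'
  s2 <- as.character(revcomp(s))
  amp2 <- epcr_locate(c(chr = s2), fwd, rev)
  expect_equal(nrow(amp2), 1L)
  expect_identical(amp2$strand, "-")
  expect_equal(amp2$product_length, 220L)
  expect_equal(amp2$start, nchar(s2) - 320L)
  # forward present, reverse absent -> empty
  s3 <- backbone
  substr(s3, 101L, 120L) <- fwd
  expect_equal(nrow(epcr_locate(c(chr = s3), fwd, rev)), 0L)
  # products beyond max_product are rejected
  expect_equal(nrow(epcr_locate(c(chr = s), fwd, rev, max_product = 219L)), 0L)
  expect_error(epcr_locate(c(chr = s), "ACGTACG", rev), "at least 10")
})

test_that("epcr_locate tolerates mismatches only up to the budget", {
  set.seed(32)
  fwd <- random_dna(20L); rev <- random_dna(20L)
  s <- flank(400L, 12L)
  fwd_mut <- fwd
  substr(fwd_mut, 10L, 10L) <- setdiff(c("A", "C", "G", "T"),
                                       substr(fwd, 10L, 10L))[1L]
  substr(s, 51L, 70L) <- fwd_mut
  substr(s, 201L, 220L) <- revcomp(rev)
  expect_equal(nrow(epcr_locate(c(chr = s), fwd, rev, max_mismatch = 0L)), 0L)
  hit <- epcr_locate(c(chr = s), fwd, rev, max_mismatch = 1L)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$product_length, 170L)
  # overlapping-primer artifacts (product < len(f) + len(r)) never appear
  tight <- paste0(flank(50L, 13L), fwd, revcomp(rev), flank(50L, 14L))
  ok <- epcr_locate(c(chr = tight), fwd, rev)
  expect_true(all(ok$product_length >= 40L))
})

test_that("linkage groups assign by plurality with flagged ties and splits", {
  placements <- data.frame(
    marker_id = sprintf("m%d", 1:8),
    pseudo_chromosome = c("pseudo4", "pseudo4", "pseudo4",
                          "pseudo3", "pseudo3", "pseudo9",
                          "pseudo1", "pseudo2"))
  map <- data.frame(
    marker_id = sprintf("m%d", 1:9),
    linkage_group = c("LG23", "LG23", "LG23",
                      "LG3", "LG3", "LG3",
                      "LGtie", "LGtie", "LGlost"),
    position = c(0, 5, 10, 0, 4, 9, 0, 3, 2))
  out <- assign_linkage_groups(placements, map)
  expect_identical(out$pseudo_chromosome[out$linkage_group == "LG23"],
                   "pseudo4")
  expect_false(out$split[out$linkage_group == "LG23"])
  # 2 markers on pseudo3 vs 1 on pseudo9: plurality, flagged as split
  expect_identical(out$pseudo_chromosome[out$linkage_group == "LG3"],
                   "pseudo3")
  expect_true(out$split[out$linkage_group == "LG3"])
  # 2-2 style tie resolves to the smallest id and is flagged
  expect_identical(out$pseudo_chromosome[out$linkage_group == "LGtie"],
                   "pseudo1")
  expect_true(out$tie[out$linkage_group == "LGtie"])
  # groups with no located markers stay unassigned
  expect_true(is.na(out$pseudo_chromosome[out$linkage_group == "LGlost"]))
})

test_that("cm_per_mbp reports consecutive-pair ratios and undefined cases", {
  mk <- data.frame(marker_id = c("a", "b", "c", "d"),
                   linkage_group = "LG1", pseudo_chromosome = "pseudo1",
                   cm = c(0, 10, 10.003, 10.003),
                   bp = c(0, 2e6, 3e6, 3e6))
  r <- cm_per_mbp(mk)
  expect_equal(nrow(r), 3L)
  expect_equal(r$cm_per_mbp[1L], 5)
  expect_equal(r$cm_per_mbp[2L], 0.003, tolerance = 1e-9)
  expect_true(is.na(r$cm_per_mbp[3L]))   # coincident bp positions
  # zero cM over positive distance is zero, not undefined
  mk0 <- data.frame(marker_id = c("a", "b"), linkage_group = "LG1",
                    pseudo_chromosome = "pseudo1", cm = c(5, 5),
                    bp = c(0, 1e6))
  expect_equal(cm_per_mbp(mk0)$cm_per_mbp, 0)
})
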