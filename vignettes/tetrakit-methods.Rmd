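---
title: "Methods: comparative analysis of an allotetraploid draft genome"
author: "tetrakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of an allotetraploid draft genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

tetrakit re-implements, as tested reusable functions, the comparative
analyses typically layered on top of a draft allotetraploid grass genome
(the tef, *Eragrostis tef*, situation is the motivating case): ordering
scaffolds against a diploid reference by synteny, separating the two
homeologous scaffold copies into A and B pseudo-chromosome sets, dating the
subgenome split and the divergence from the reference with a synonymous
molecular clock, estimating genome size from the k-mer spectrum of raw
reads, finding SSR markers and linking them to a genetic map, and screening
predicted proteins for celiac-disease epitopes.  Assembly, annotation,
repeat masking, tree inference and primer design are out of scope.

Because the real data sets (hundreds of Mbp, external reference genomes)
are not reproducible at desk scale, the package carries a first-class
synthetic-data module: a forward simulator that emits an allotetraploid toy
genome with an outgroup reference and a complete ground-truth table, so
every downstream stage can be tested for *recovery* of known truth rather
than for agreement with memorized numbers.

# The synthetic allotetraploid

`simulate_allotetraploid()` draws a uniform-composition random ancestor
organized as alternating intergenic spacers and stop-free genes, duplicates
it into subgenomes A and B, and evolves each by `d_AB/2` expected
substitutions per site so the two extant copies sit at `d_AB` from each
other.  The outgroup branches `(d_out - d_AB)/2` above the A/B ancestor and
evolves a further `d_out/2`, so that the *extant* A (or B) copy is at
expected distance `d_out` from the outgroup — that is the quantity the
Ks-versus-outgroup comparison measures downstream, and it is what the
configuration parameter is named for.

Two substitution models are used deliberately:

* **Intergenic sequence** evolves under plain Jukes–Cantor
  (`evolve_sequence()`): each site independently changes to one of the
  other three bases with probability `q = (3/4)(1 - exp(-4d/3))`.
* **Genes** evolve under the same per-site substitution probability, but a
  substitution that would create a stop codon is redirected uniformly onto
  the remaining (sense) targets (`evolve_cds()`).  This is purifying
  selection against premature stops only — otherwise neutral, so
  synonymous and non-synonymous divergence both equal `d` in expectation.

The second model is a considered choice, not a convenience.  The
Nei–Gojobori site-counting scheme used for dating *defines* the mutational
opportunity of a codon position as its non-stop single-base changes.  If
the simulator let genes fix nonsense substitutions (plain JC everywhere),
the estimator's synonymous-site denominator would overstate the actual
opportunity and dS would systematically underestimate the true divergence
by ~4% — enough to push a distribution centred on 0.052 into the histogram
bin below it.  A functional gene's observable substitution process does
not, in fact, include fixed nonsense changes, so the redirected model is
both the biologically sensible one and the one under which the estimator is
calibrated.  The per-site difference fraction is unchanged (the excess
same-target collision probability is ~2e-5 at the default divergences),
so the closed-form JC calibration checks still apply to gene sequences.

No indels, no rate variation, no codon-usage bias, no repeats beyond the
spiked features: gene coordinates are identical across all three genomes,
which means homeologous CDS pairs are pre-aligned by construction and the
divergence machinery can be tested without invoking an aligner.

Default study conditions (`simulation_config()`): 2 chromosomes × 60 genes
of 200 codons with 400 bp spacers (~60 kb per chromosome, ~242 kb
assembly), `d_AB = 0.052` and `d_out = 0.47` (the Ks modes the clock maps
to ~4 and ~36 MY), exponential scaffold lengths with mean 6 kb, 10% anchor
dropout, 30× reads of 100 bp.  The divergences are anchored to the
empirical Ks modes; the structural sizes are desk-scale choices picked once
to give a few hundred genes and tens of scaffolds within seconds of
compute.

Fragmentation (`fragment_genome()`) cuts chromosomes at approximately
exponential spacings but shifts any cut that lands inside a gene to the
nearest gene boundary; anchors therefore stay intact, concatenating the
scaffolds reproduces the chromosome exactly, and a mean scaffold length
below twice the longest gene is rejected as unsatisfiable.  SSR arrays and
protein epitopes are spiked by pure insertion (`spike_feature()`) with
truth recorded; SSR spike positions are rejection-sampled until the spiked
run is recovered at its exact position, which is how "repeat-free flanks"
is made a guarantee rather than a hope.

# Synteny placement

An anchor is one syntenic gene pair: scaffold interval ↔ reference
interval (tab-separated, 0-based half-open; `read_anchor_table()` rejects
malformed rows by line number).  Placement follows three rules, each a
deliberate resolution of something the underlying procedure leaves
unstated:

* **Support filter**: a scaffold must have at least `min_genes` anchors
  (default 3, inclusive) *on its majority chromosome*; counting support on
  the winning chromosome prevents a translocation-split scaffold from
  passing on pooled counts.
* **Chromosome assignment**: majority of anchors, ties to the
  lexicographically smallest chromosome id; anchors on losing chromosomes
  are discarded before the interval is formed, preventing chimeric spans.
* **Orientation**: the sign of the Spearman rank correlation between
  anchor order on the scaffold and on the reference; a single anchor or a
  zero/undefined correlation defaults to `+`.  Rank correlation is robust
  to anchor dropout and to uneven gene spacing.

`count_copies()` implements the homology copy counter used for gene-family
census work: a hit counts iff its aligned query length is ≥ 70% of the
query (inclusive boundary), distinct target loci counted once.

# Pseudo-chromosomes and the A/B partition

Placed scaffolds are ordered by reference start (ties: end, then id) and
joined with 100 N between members into a pseudo-chromosome;
`build_pseudochromosome()` emits AGP v2.0 (gap type "scaffold", linkage
"yes", evidence "na") and an exact coordinate lift-over, and
`read_agp()`/`write_agp()` round-trip the layout bit-exactly.  The gap
length is arbitrary but fixed — what matters is that coordinates are
reproducible.

The A/B partition is the greedy rule: first scaffold → A; each subsequent
scaffold → B iff its reference interval overlaps that of *any*
already-labeled A scaffold by strictly more than 75%, else → A.  Three
details are choices the rule's one-sentence description leaves open, all
fixed here and exposed as parameters:

* overlap is normalized by the **shorter** interval, so a small scaffold
  nested inside a large homeolog counts as full overlap (the behaviour the
  sorting needs);
* the threshold comparison is **strict** ("more than 75%");
* only A-membership is tested — a scaffold overlapping an earlier B
  scaffold but no A scaffold still goes to A (`check_b = TRUE` flags, but
  does not relabel, doubly-overlapping scaffolds).

The partition separates homeologs; it does not identify which group is
which progenitor subgenome.  On simulated assemblies the testable property
is therefore *separation*: ≥95% of truth homeolog scaffold pairs whose
placed intervals overlap above the threshold receive different labels
(observed: 100% across the seeds exercised in the test suite).  Same-
subgenome scaffolds are disjoint on their chromosome, so they essentially
never overlap above threshold, which is why the simple rule works as well
as it does.

`ab_identity()` summarizes A/B similarity as matches over mutually ungapped
columns, weighted by compared columns across pairs — at `d_AB = 0.052` the
JC expectation is ~95%.

# Divergence estimation and clock dating

`ng86_pair()` implements Nei–Gojobori (1986) counting with Jukes–Cantor
correction — a self-contained, oracle-checkable stand-in for ML codon
models, which agree closely in the small-distance regime where all the
headline numbers live.  Per codon, each of the nine single-base changes is
classified; changes to stops are excluded from the denominator
position-wise (`codon_sites()`, verified in the tests against an
independent enumeration oracle).  Sites are averaged over the two
sequences; codon columns containing gaps, ambiguity characters or stops are
skipped pairwise.  Multi-hit codons are resolved by averaging over all
minimal substitution pathways, excluding pathways through stop codons; in
the rare case that every pathway is blocked the average falls back to all
pathways rather than silently dropping the codon.  `pS ≥ 3/4` leaves dS
undefined (saturation) — reported as such, never coerced to a number.

The Ks distribution is binned at width 0.01 over [0, 2); the mode is the
left edge of the maximal bin, ties to the smallest edge.  The binning
constants are reporting conventions chosen here (the left-edge convention
makes "a distribution centred at 0.052" print as 0.05); out-of-range and
saturated values are excluded and counted.  Dates follow `T = Ks / (2r)`
with `r = 6.5e-9` synonymous substitutions per synonymous site per year,
the standard plant nuclear rate: modes 0.05, 0.15 and 0.47 map to 4, 12
and 36 MY.

At the default pipeline scale (120 pairs × 200 codons) the per-pair dS
standard deviation is ~0.016 within-genome and ~0.07 versus the outgroup,
so the *mode* of that small histogram carries roughly ±0.01 and ±0.05 of
sampling error respectively; the end-to-end test asserts the implied dates
inside those honest bands, while the calibration suite does its mode
assertions at 1000 pairs × 1000 codons where the mode is stable.

`global_align()` (Needleman–Wunsch, linear gaps, deterministic
diagonal-up-left tie-break) is provided so real indel-bearing CDS pairs can
be fed to the estimator; simulator pairs never need it.  Its scores are
cross-checked in the tests against both exhaustive enumeration on toy
cases and the reference dynamic-programming implementation in Biostrings.

# Genome size from the k-mer spectrum

Canonical k-mers (a k-mer pooled with its reverse complement under the
lexicographically smaller encoding) are counted in C++ with a rolling
2-bit encoding (k ≤ 32; k-mers containing N are skipped).  The coverage
peak M relates to depth N by `M = N (L - K + 1) / L`, and genome size is
total bases / N.

Peak location (`find_coverage_peak()`) has two deliberate refinements:

* the search region starts at the first local minimum of the spectrum
  (skipping the sequencing-error spike); with error-free synthetic reads
  the spectrum is unimodal and the fallback (global argmax, with a
  warning, for monotonically decreasing spectra) is what gets exercised;
* within the region, the returned integer M is by default the
  count-weighted mean multiplicity over the window [0.6, 1.4] × the raw
  argmax, rounded.  The formula's M is the *expected* k-mer depth; for a
  Poisson-shaped peak whose mean sits at or near an integer the raw argmax
  is a coin flip between the two central bins (a half-unit downward bias
  on average, which alone is a 2.5% error in G at depth 50), while the
  local centroid estimates the mean consistently.  The window is wide
  enough to hold essentially all of the peak's mass at realistic depths
  yet narrow enough to exclude the second peak at 2M that k-mers shared
  between the two subgenomes of a polyploid produce — at `d_AB = 0.052`
  about a third of 21-mer loci are identical across A and B, and a
  whole-spectrum centroid would be pulled ~20% upward by them.
  `refine = FALSE` gives the raw argmax.

With error-free reads at ≥30× from a repeat-free genome the estimate lands
within 2% of truth (within ~0.3% in the end-to-end runs, where M is
recovered exactly).

# SSR markers, e-PCR and map linking

`find_ssrs()` follows the MISA convention: maximal tandem runs of 1–6 bp
motifs with minimum repeat counts 10/6/5/5/5/5 by motif length (the
published settings described as "more than" N times are MISA's *minimum*
counts — the tool's defaults — and are implemented as inclusive minima).
Motifs are reported as found (no canonical rotation); a run whose motif is
itself a repetition of a shorter motif is reported at the shortest period
only; two SSRs separated by ≤100 bp merge into a compound record whose
repeat count sums the members and excludes the interruption bases.
Detection is strand-symmetric (tested by reverse-complement invariance).
`ssr_density()` divides genome length by the qualifying SSR count, with
`min_motif_length = 2` reproducing the "dinucleotide or larger" convention
of genome-wide density figures.

`epcr_locate()` is deliberately simple in-silico PCR: full-length primer
matches, ≤ `max_mismatch` substitutions, no indels; the reverse primer's
reverse complement must land downstream on the same strand within
`max_product`, products shorter than the two primers laid end to end are
impossible by construction, both strands are searched, and coordinates are
always reported on the forward genome.

`assign_linkage_groups()` maps each linkage group to the pseudo-chromosome
holding the plurality of its located markers (ties to the smallest id,
flagged; groups split across chromosomes flagged as translocation-like;
unlocated groups left `NA`), and `cm_per_mbp()` reports |ΔcM| / |Δbp|
ratios per consecutive marker pair, with coincident physical positions
reported as undefined rather than infinite.  On the synthetic map the
absolute cM/Mbp values are inflated by the toy physical scale
(kilobase-sized chromosomes); the operations, not the magnitudes, are what
the synthetic run validates.

# Epitope scanning

`scan_proteome()` is exact substring matching of an epitope list against a
protein set: case-normalized, `*` terminators stripped, overlapping
occurrences counted separately (the conservative superset of "counted"),
output deterministically ordered.  Matching is protein-space only — no
six-frame translation search.  Summaries report both total occurrences and
distinct epitopes per species, and zero rows are emitted explicitly:
absence of the epitopes outside wheat/barley/rye-like proteomes is the
biological result, so the all-zero table must be visible, not silent.  The
shipped `extdata/epitopes_synthetic.txt` is a synthetic stand-in list
(length spectrum 11–20, proline/glutamine-rich) for demonstrations and
negative controls; it is not the published immunogenic peptide set.  The
scanner is validated against a naive O(n·m) oracle on random proteomes and
for zero false positives on proteomes generated epitope-free by rejection
sampling.

# Pipeline

`run_all()` executes simulate → synteny → scaffolding → molclock with
kmerstats, markers and peptides as independent branches, entirely through
plain-text intermediates in the run directory.  The report is assembled
only from those files, contains no timestamps, and is therefore
byte-identical across re-runs of the same configuration; a stage whose
outputs exist is skipped (`force = TRUE` overrides), so deleting one
stage's files regenerates exactly that stage from its cached inputs.  Every
per-stage seed is derived from the single configuration seed by small
fixed offsets.

# Numerical and testing choices

Coordinates are 0-based half-open internally and converted only at I/O
boundaries (AGP is 1-based inclusive per its standard; FASTA wraps at 60
columns).  Histogram bins are left-closed; all tie-breaks (mode, chromosome
majority, linkage plurality, alignment traceback, ordering) are specified
and deterministic.  Saturated dS, undefined densities and undefined cM/Mbp
ratios are reported as `NA` with context, never silently dropped or
zeroed.

Test problem sizes were chosen to make each property decisive in seconds:
calibration of the dS distribution at 1000 pairs × 1000 codons (the scale
at which the mode is stable), genome-size recovery on a 1 Mbp genome at
50× (the scale at which the 2% band is meaningful), partition separation
pooled over three simulated assemblies, and brute-force oracle comparisons
at dozens-of-sequences scale.  Every stochastic test runs under a fixed
seed.

# Known limitations

* NG86+JC underestimates dS as divergence grows (visible by ~4% at
  d ≈ 0.5); all headline quantities live at small distances where the
  approximation is tight, and no ML codon model is provided.
* The simulator's no-indel design means the aligner is exercised only by
  its own unit tests, not by the pipeline.
* The greedy partition is order-dependent by specification; permuting
  input order can relabel scaffolds (separation, not identity, is the
  guarantee).
* Compound SSR records concatenate member motifs and sum repeat counts; a
  MISA-style interruption annotation (`(AG)6nn(TC)7`) is not reproduced.
* In-memory k-mer counting targets desk-scale data; there is no streaming
  or probabilistic counting path.
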