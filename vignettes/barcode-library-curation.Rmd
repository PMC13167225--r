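---
title: "Methods: curating and validating a COI-5P barcode reference library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating and validating a COI-5P barcode reference library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coicurate)
```

## The curation problem

A barcode reference library maps specimens to species through a short
mitochondrial fragment (COI-5P, 658 bp). Its failure modes are well
catalogued: misidentified vouchers, cross-contaminated extracts,
sequencing of nuclear mitochondrial pseudogenes (NUMTs), truncated or
ambiguity-riddled reads, and — on the biological side — barcode sharing
between recently diverged species, introgression and incomplete lineage
sorting. A curation pipeline has to separate the operational errors
(removable) from the biological signal (reportable), and it has to do so
auditable: every removal traced to a rule or to an explicit reviewer
decision.

`coicurate` structures this as a two-pass workflow around
`curate_barcodes()`. Pass 1 applies the mechanical sequence-quality
filters and computes three independent read-outs of library health —
distance-based (barcode-gap statistics), topology-based (monophyly on a
tree) and cluster-based (BIN concordance). The reviewer examines the
flags and the intruder report and writes an exclusion list; pass 2 reruns
the identical chain without the excluded records and diffs the monophyly
statuses. Cases that resolve were operational; cases that persist are
biology and stay in the library, flagged.

## Filters

**Length window.** Records are kept when their *ungapped* length lies in
[`min_len`, `max_len`] = [500, 658] bp inclusive. Gaps are alignment
artifacts, not sequence, so they never count toward length; 658 bp is the
full fragment, 500 bp the conventional floor below which a partial
barcode loses diagnostic power. Bounds are inclusive because full-length
658 bp records are, by definition, valid barcodes.

**Stop-codon screen.** Each record is translated in all three frame
offsets under NCBI genetic code table 5 (invertebrate mitochondrial: only
`TAA`/`TAG` are stops; `TGA` = Trp, `AGA`/`AGG` = Ser, `ATA` = Met) and
kept iff at least one frame is stop-free. BOLD-style exports do not
announce the reading frame, and demanding a specific frame would discard
genuine barcodes whose 5′ trim landed off-frame; conversely a sequence
with stops in *every* frame cannot encode COI and is the canonical NUMT
signature. Codons containing ambiguity symbols translate to `X` and never
count as stops (an `N` must not condemn a record). The minimal-stop frame
of each kept record is reported for provenance. Because both filters
depend only on the record itself, they commute; the test suite asserts
this.

**Exclusion list.** `apply_exclusion_list()` is the only mechanism that
removes records for curation reasons. It warns on unknown ids rather than
failing, because exclusion lists are typically maintained by hand across
library versions.

## Haplotypes

Haplotypes are equivalence classes under exact equality of the full
aligned string, computed within species among records containing only
`A/C/G/T`. Exact matching is deliberate: after excluding gap- and
ambiguity-bearing records the survivors align end-to-end, and any looser
rule (trimming to a common core, N-tolerant matching) would make the
count depend on the composition of the rest of the library. A
consequence users should know: length variants of the same molecule
count as distinct haplotypes.

Ambiguous records still count toward `n_records` — the sampling-effort
axis — but not toward haplotypes; both counts are emitted so either
convention can be plotted. `richness_vs_effort()` reports the Pearson r
between effort and richness with the usual two-sided t-transform p-value,
erroring explicitly on degenerate inputs (fewer than 3 species, zero
variance) rather than returning `NaN`.

## Distances and the barcode gap

Distances are uncorrected p-distances under pairwise deletion: a site
enters a pair's comparison only when both sequences carry an unambiguous
base there, and the distance is mismatches over compared sites. Pairwise
(not complete-column) deletion preserves information in ragged 500–658 bp
data; no model correction is applied because the barcode-gap statistics
are conventionally computed on raw proportions. A pair with zero shared
sites is marked incomparable, never given distance 0, and is excluded
from min/max statistics.

Implementation note: the full matrix is computed via indicator-matrix
products (one 0/1 matrix per base plus a validity matrix), which is
algebraically identical to per-site enumeration — mismatch and site
counts are integers, so the two routes agree exactly, and the test suite
checks element-wise equality against a naive reimplementation on hundreds
of random alignments.

Per group (species, or BIN when labels are present) the pipeline derives
intra_dmax — the maximum within-group distance, `NA` for singletons — and
Dmin_NN, the minimum distance from any member to any non-member, with the
attaining group as nearest neighbor. Ties on Dmin_NN are broken to the
lexicographically smallest label, with all tied groups listed; the
convention is arbitrary but deterministic. Distances are stored as
proportions and reported as percents with two decimals.

Anomaly rules, applied at the species grouping with `threshold_percent =
2`: flag `NN_below_threshold` when Dmin_NN < 2% (the conventional
divergence floor below which COI cannot reliably separate species) and
`gap_violation` when Dmin_NN < intra_dmax (local barcode-gap collapse —
possible misidentification, introgression or cryptic structure). Either
flag marks the species for review. Distribution summaries of the four
value sets (species/BIN × dmax/Dmin_NN) use type-7 (linear interpolation)
quantiles so they are reproducible bit-for-bit.

## Monophyly and the curation loop

Trees enter as newick (`parse_newick()`, strict about balance, the
terminal semicolon and duplicate tips) and are assessed **rooted as
read**: the outermost newick node is taken as the root. Re-rooting can
change monophyly verdicts; a `root_mode = "midpoint"` option exists, and
the default deliberately leaves the input untouched so results are a
function of the tree the user inferred. Support values are parsed and
carried but never influence status — status is purely topological.

Tips resolve to species through the metadata when available, falling back
to splitting composite `ProcessID.Taxon_name` labels at the first dot;
unresolvable tips are listed, not guessed. A taxon with ≥ 2 tips is
monophyletic iff the MRCA of its tips has no foreign descendant tips;
1-tip taxa are `singleton` (not assessable, never counted
non-monophyletic) and 0-tip taxa `absent`.

For each non-monophyletic taxon, `intruder_report()` lists the foreign
tips and computes a *suggested* removal set greedily: repeatedly remove
the single tip whose removal most reduces the intruder count, until
monophyly is restored or a cap (10) is hit. Candidates are the focal
taxon's own tips (a mislabeled member stranded in a distant clade is the
common case, and removing it collapses the inflated MRCA) plus, when the
intruder set is small (≤ 50), the intruders themselves; ties prefer
intruders, so a clean single-intruder case suggests the intruder rather
than degrading the taxon to a singleton. Greedy rather than exact
set-cover is a deliberate choice: the output is advisory input to a human
reviewer, and the paper trail of actual removals runs exclusively through
the exclusion list.

When no tree is supplied, `nj_tree()` builds a neighbor-joining tree from
the p-distance matrix. This is a fallback that makes synthetic tests and
quick looks self-contained — NJ is exact on additive matrices and
reliable when species are well separated — not a replacement for
model-based inference on real data. Because NJ estimates an *unrooted*
topology whose stored basal node is an agglomeration artifact, assessing
it "as read" can place the root inside a species cloud and fabricate
paraphyly; the fallback tree is therefore midpoint-rooted before
assessment. With short intraspecific and long interspecific branches the
midpoint reliably falls between species clades, and the rooting is
deterministic. Supplied trees are never re-rooted by default.

## BIN concordance

BIN labels are consumed as metadata (re-deriving the clusters is out of
scope). Classification: `singleton` (1 record; takes precedence — a
single record can neither agree nor disagree), `concordant` (≥ 2 records,
one species), `discordant` (≥ 2 records, several species). The three
classes partition the distinct BIN labels on every input, a property the
tests enforce. Percentages use the distinct-BIN count as denominator.
Records lacking a species label inside a BIN are surfaced via a flag and
excluded from the species set rather than guessed; the per-species
summary reports BIN multiplicity and species with no BIN at all.

## The synthetic generator

The generator exists because curation pipelines are normally validated
on data whose errors are unknown. It emulates the statistical structure
the analyses assume, with every deviation recorded in a truth table.

*Species structure.* A two-level rooted species tree: designated sister
pairs form cherries diverging at `inter_divergence` (default 0.10
substitutions/site — a close congeneric pair), and all groups hang off
the root at `deep_multiplier × inter_divergence` (default 2, i.e. ~20%,
typical deep interspecific COI divergence). Substitution counts per
branch are Poisson(branch × length), placed at uniform sites with
Jukes–Cantor-style uniform base changes. A two-level topology rather
than a random birth–death tree keeps nearest-neighbor relationships
controllable by construction (sisters are mutual NNs), which is what the
distance tests need.

*Individuals.* A star model: each individual is its species ancestor
plus Poisson(`theta`) substitutions (default 2 sites ≈ 0.3%
intraspecific divergence). No within-species coalescent — the star model
produces haplotype-richness gradients and clean barcode gaps, which is
sufficient for validating the pipeline, but it does not produce
realistic within-species tree shape, geographic structure, or the
richness saturation real libraries show. Consequently the richness–effort
correlation on synthetic data is near-perfect, noticeably stronger than
in real libraries where per-species diversity varies.

*Selection.* Clean sequences are kept stop-free in frame 0 by resampling
any substitution that would create `TAA`/`TAG` — the simulated analogue
of purifying selection on a coding gene. Without it the stop-codon
screen would misfire on legitimate records, which is not how real COI
behaves.

*Error processes* (disjoint per-record classes, one uniform draw against
cumulative rates): `mislabel` swaps the observed species label (BIN stays
with the sequence, so mislabels create discordant BINs); `contamination`
copies another species' sequence (BIN follows the sequence);
`numt` applies a 1-base deletion with re-padding and then forces a stop
into every frame (frameshifted pseudogene); `short` truncates below
500 bp and gap-pads to keep the alignment rectangular; `ambiguous`
overwrites sites with `N`. Sharing pairs copy one haplotype verbatim
across two species (Dmin_NN = 0 on both sides). NUMT and short records
lose their BIN, as a repository would not assign one to a non-compliant
sequence.

All randomness flows through the single seed in the configuration;
identical configurations are byte-identical on disk.

*What passing tests show.* Perfect recall/precision of the filters
against the truth table shows the filters implement their definitions,
because the generator plants exactly the signatures the filters look
for. It does not show that real NUMTs always carry stops (they do not;
tree inspection remains necessary), nor that 2% is the right threshold
for any particular taxon.

## Numerical and degenerate-input choices

- Inclusive length bounds; length on ungapped characters.
- Ambiguity codons → `X`, never stops.
- Zero comparable sites → incomparable (`NA`), excluded and logged, never 0.
- Quantiles: type 7. Percent formatting: 2 decimals in reports, full
  precision in memory.
- NN ties: lexicographic winner, full tie list retained.
- NJ on degenerate (all-equal) matrices: deterministic output under
  ape's fixed agglomeration order; documented rather than randomized.
- Haplotype counting of an empty group returns 0, not an error; richness
  correlation on degenerate inputs errors loudly.
- The richness p-value needs ≥ 3 species; the fitted pass skips the
  correlation (with the reason retained) when the filtered library is
  degenerate, rather than failing the whole run.

## Problem sizes

The validation suite runs on libraries of up to 40 species × 20
individuals (800 records, ~320k distance pairs) and sweeps of hundreds
of small random alignments; the acceptance script additionally simulates
a 169-species library with skewed sampling effort (zero-truncated
negative binomial, mean 24, SD ≈ 31 — the effort profile typical of
regional barcode campaigns) for the richness–effort correlation. These
sizes exercise every code path at full fidelity while keeping a complete
run in minutes on one core; all components scale to real library sizes
(thousands of records), with the O(n³) NJ fallback and the per-taxon
intruder search as the practical bottlenecks.

## Known limitations

- Input must be pre-aligned; the package checks rectangularity but does
  not align.
- p-distances only; no model-corrected distances (K2P etc.) and no
  formal species delimitation (ASAP/GMYC-style methods are out of
  scope).
- The NJ fallback is not a substitute for ML inference on real data.
- The greedy removal suggestion is not minimal in the set-cover sense.
- The generator's star model and two-level tree understate real
  within-species structure; BIN labels equal true species, so BIN
  discordance on synthetic data arises only from injected errors.
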