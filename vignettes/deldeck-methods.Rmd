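---
title: "Models and methods behind deldeck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind deldeck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The screening workflow deldeck models

A DNA-encoded chemical library (DEL) built by split-and-pool synthesis on a
glutamic-acid scaffold attaches two diversity elements to every molecule: a
building block A (an amine coupled to the scaffold) and a building block B
(a carboxylic acid coupled as an amide, or an alkyne coupled as a triazole).
Each block is recorded in the molecule's single-stranded DNA tag by a
dedicated barcode — CodeA for set A, CodeB for set B — so that
high-throughput sequencing of an affinity-captured pool identifies which
(A, B) combinations survived selection against an immobilised protein
target. The full-scale design shipped as `gbdel_manifest()` carries 300 A
blocks (191 primary amines, 36 secondary amines, 72 heteroaromatic amines,
and one code reserved for an ammonia control), 611 B blocks (480
carboxylic acids, 131 alkynes), and two stereoisomers per combination:
2 x 300 x 611 = 366,600 compounds over a 300 x 611 = 183,300-cell code
grid. Stereochemistry is deliberately not DNA-encoded — both isomers share
one code pair and are only resolved at hit validation — so every
sequencing-level statistic in the package lives on the |A| x |B| grid.

## Barcode codebooks

No barcode oligo sequences are published for this library, so codebooks are
an artifact of the package: `generate_codebook()` performs a seeded greedy
random search for `n` sequences of length 8 nt with pairwise Hamming
distance >= 3. That is the smallest standard design in which any single
substitution still identifies a unique codeword (sphere packing), and it
leaves the decoder a clean contract: `max_mismatch` must stay strictly
below `d_min`, otherwise nearest-neighbour correction is not guaranteed
unique and the configuration is refused. The greedy search finds 611 codes
at this geometry in a few thousand candidate draws; an attempt budget
(default 500 per requested code) converts a genuinely infeasible request
into an actionable error suggesting longer codes. Codebook validity is
always re-verifiable through the independent `codebook_min_distance()`
O(n²L) scan, which manifest validation runs on every load.

Reads are laid out as `prefix (6 nt) + CodeA (8 nt) + spacer (4 nt) +
CodeB (8 nt) + suffix (6 nt)`, 32 nt in total. The flanking sequences are
arbitrary fixed strings: decoding locates code slots by offset, not by
adapter search, which is exact for simulator-generated reads and keeps
real-data adapter scanning out of scope.

## The selection and sequencing model

`simulate_capture()` models one round of affinity capture as independent
binomial thinning: member m with enrichment fold f_m >= 1 contributes
`Binomial(n0, min(1, p0 * f_m))` captured molecules, with defaults n0 = 1e7
copies per member (the documented input amount per selection aliquot) and
baseline capture probability p0 = 1e-5, i.e. an expected background of 100
molecules per member. In dual-pharmacophore (DP, "2+1") mode — the library
annealed to a complementary strand displaying a known hit moiety — the fold
is further multiplied by a per-combination synergy multiplier before
capping. PCR amplification is not modelled separately; any amplification
bias is folded into the capture weights, the simplest model that reproduces
the fingerprint statistics downstream analysis consumes.

`sequence_reads()` then draws exactly `depth` reads from a multinomial over
the per-pair capture weights (stereoisomer counts are summed first, since
isomers share a code pair), assembles each read from the layout above, and
applies i.i.d. per-base substitution errors. Indels are excluded by design:
the fixed-position layout keeps decoding well-posed, and indel robustness
is a non-goal. Every read's true code pair is written to a truth table, so
any decoding result can be audited against ground truth. All randomness
flows from explicit seeds; triplicate scenarios use seed, seed+1, seed+2.

The closed-form consequences used as oracles throughout the test suite:
the expected decoded count of pair i is `depth * w_i / sum(w)` with
`w_i = sum over stereoisomers of min(1, p0 * f)`, hence the expected
uniform-baseline enrichment factor is `N * w_i / sum(w)` (`expected_ef()`);
and with error rate e the probability that an 8-nt code slot stays
correctable (<= 1 substitution) is `(1-e)^8 + 8e(1-e)^7`.

### Scenario presets

`scenario_preset()` pins the study conditions the simulator emulates, with
depths taken from the published run totals:

* **unselected** — all folds 1, depth 17,046,900 (ACs 93 on the full grid);
* **sp_selection** — depth 232,900; one binder planted on the aromatic
  sulfonamide positive-control pair A94/B575 at fold 1000 on both
  stereoisomers. Closed-form expected EF ≈ 994, matching the reported
  sulfonamide enrichment scale (up to ~970-fold);
* **dp_maturation** — serum-albumin-style maturation: pair A24/B137 at SP
  fold 3 with DP multiplier 373 (effective DP fold 1119, the published
  SP 3 → DP 1119 exemplar), plus an independent binder A200/B244 at fold
  112 in both modes; depths 190,200 (SP) and 241,800 (DP);
* **triplicate** — the sp_selection truth sequenced three times at
  consecutive seeds.

All presets use substitution error rate 0.005, a typical short-read
substitution scale that exercises the error-correction path without
dominating the discard statistics. On manifests smaller than the full
design the planted exemplar codes fall back to the top corner of the grid.

## Decoding

`decode_fastq()` extracts both code slots by offset and assigns each to the
unique codeword within `max_mismatch` substitutions. Ties at the minimum
qualifying distance are never broken arbitrarily: the read is discarded as
`ambiguous`, protecting enrichment factors from systematic misassignment.
Discard accounting is exhaustive — every read is either assigned to one
grid cell or counted under exactly one reason (`ambiguous` takes precedence
within a slot; slot A is inspected before slot B), so
`assigned + discarded = reads processed` holds on every run. Exact matches
are resolved by hash lookup and only the non-exact residue enters the
Hamming search over unique observations, which keeps full-depth decoding
in seconds.

The summary statistics follow the field's fingerprint conventions: TCs
(total sequence counts) is the grid sum, ACs (average sequence counts) is
TCs divided by the 183,300 combinations. ACs is reported at full precision
and displayed rounded half-up to two decimals (integers unrounded). The
published captions are internally inconsistent between truncation and
rounding in one case (a 252,500-read run captioned 1.34 where the grid
arithmetic gives 1.378); the package pins the half-up convention, which
reproduces every arithmetically consistent caption including the one
(342,600 → 1.87) that truncation would get wrong.

## Enrichment statistics

The default enrichment factor is computed against the uniform baseline,
`ef_i = c_i * N / TCs`: the fold over-representation relative to the flat
expectation over the full grid, the same normalisation the ACs statistic
uses. Its grid mean is exactly 1 whenever TCs > 0, and it is invariant
under rescaling all counts — both properties are enforced in the test
suite. The exact supplementary formulas behind the published EF values are
not available in the main text, so the uniform baseline is this package's
definition, validated against the ACs arithmetic; a library-relative
baseline (selection frequency over unselected-library frequency, with
pseudocount 0.5 guarding unsampled reference cells) is provided as an
option for real unselected-library references.

Hit calling is thresholded ranking (`ef >= ef_min`, `count >= count_min`,
EF-descending with lexicographic tie-break), with replicate concordance
requiring every replicate to pass — the in-silico analogue of calling hits
only when all three selection replicates agree. No multiple-testing
correction is applied, matching practice for these fingerprints; instead
the empirical null behaviour (near-empty hit lists on background-only
simulations at ACs ≈ 1.3) is part of the test suite.

### Synergy classification

`synergy_analysis()` compares SP and DP enrichment per combination through
`synergy_ratio = ef_dp / max(ef_sp, 1)`; the denominator floor prevents
ratio inflation when the SP enrichment is sub-background. Default
thresholds `ratio_min = 5`, `ef_dp_min = 10` were chosen so the published
exemplars classify as narrated — SP 3 → DP 22 (ratio 7.3) and SP 3 →
DP 1119 (ratio 373) are synergistic, a strong binder with similar
enrichment in both formats (EF ≈ 112) is independent, and flat cells are
background — while sitting far from the background EF scale (≈ 1) so the
classes are robust to sampling noise. The four classes are mutually
exclusive and exhaustive by construction.

## Numerical and design choices

* **Determinism.** Member enumeration is stereo-major lexicographic;
  hit ranking breaks ties lexicographically; all stochastic steps take
  explicit seeds through one RNG scope (`withr::with_seed`), so pipeline
  outputs are bit-identical across re-runs with one configuration.
* **Degenerate inputs.** Empty FASTQ decodes to an all-zero matrix
  (TCs = ACs = 0); EF on an all-zero matrix is an error (TCs = 0);
  sequencing a depth > 0 from an all-zero capture is an error; capture
  probabilities above 1 are capped with a warning.
* **Problem sizes.** The test suite exercises the full 366,600-member
  design for enumeration, decoding and planted-binder recovery at
  selection-scale depths (2e5 reads, 20 repeated selections), and reduced
  grids (tens of blocks) where full scale adds nothing to the property
  under test. The 17M-read unselected depth is validated through the ACs
  arithmetic identity rather than by emitting 17 million reads, which the
  identity makes redundant.
* **Lipinski boundaries** are all inclusive (MW <= 500, HBD <= 5,
  HBA <= 10, logP <= 5), the conventional statement of the rule of five.
  Because the real structures are unpublished, `gbdel_manifest()` draws
  synthetic per-block property contributions (documented defaults:
  scaffold 212.2 g/mol, amide linkage −18.02, triazole 0; scaffold HBD 1,
  HBA 4, logP −0.5) centring the MW distribution near 480 g/mol with most
  members rule-of-five compliant — a stand-in emulating the drug-like
  profile, not a reproduction of it.

## What the simulations do and do not show

The generator reproduces the *count-level* structure of a selection
campaign: multinomial sampling noise at realistic depths, substitution
errors in barcodes, fold-driven enrichment, stereo-collapsed decoding, and
SP/DP synergy. Passing tests therefore demonstrate that the decoding and
enrichment machinery recovers known ground truth under this model. They do
not validate chemistry or binding biology: no PCR-bias or bead-level
stochasticity, no indels or quality-score information, no sequence-error
deconvolution beyond single-mismatch correction, and published EF values
that depend on the original raw reads (which are not deposited) are
matched in magnitude by construction of the presets, not reproduced.

## Example

```{r example}
library(deldeck)
manifest <- gbdel_manifest(seed = 1)
sc <- scenario_preset("sp_selection", manifest = manifest, seed = 1)
cap <- simulate_capture(sc$truth, sc$mode_sp, seed = 1)
sim <- sequence_reads(cap, manifest, sc$cfg, fastq = "reads.fastq")
counts <- decode_fastq("reads.fastq", manifest, max_mismatch = 1)
summary(counts)
hits <- call_hits(enrichment_factors(counts))
head(hits)
fingerprint_plot(counts, "pseudo2d")
```
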