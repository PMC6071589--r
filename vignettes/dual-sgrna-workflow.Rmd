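---
title: "Models and methods behind dualguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dualguide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualguide)
```

`dualguide` implements the computational chain of a dual-sgRNA CRISPR/Cas9
mutagenesis workflow in *Arabidopsis thaliana*: guide and cut-site
arithmetic, decomposition of mixed Sanger traces into indel spectra,
population statistics over edited T1 plants, repair-mechanism classification
of junctions, and Mendelian segregation logic for recovering Cas9-free
mutants in T2. This vignette explains the underlying models, the tunable
parameters, and the design decisions, in that order.

## Coordinates and cut-site arithmetic

All coordinates are 0-based, half-open, on the + strand; cut sites are
inter-base integers (the break lies between positions `cut - 1` and `cut`).
SpCas9 is modelled as a blunt cutter 3 nt 5' of the NGG PAM on the
protospacer strand: `cut = pam_start - 3` for + strand sites and
`cut = pam_end + 3` for − strand sites, both expressed in + strand
coordinates. A dual-guide deletion is the cut-to-cut interval; its length
mod 3 decides the frame call. We do not model staggered cuts or junction
micro-processing: the workflow's expected deletion sizes are cut-to-cut
distances, and that convention is applied uniformly. Protospacer
localisation is exact matching only (protospacer plus PAM, `N` in the PAM
matching any base, both strands); off-target scanning with mismatches is out
of scope, and ambiguous guides (several exact hits) are returned as multiple
sites for the caller — the command line refuses them unless `--site-index`
is given.

Genomic sequence for the targeted genes is not redistributed. For worked
examples and acceptance checks, `synthetic_locus()` builds *synthetic
stand-in loci*: a random background in which a real protospacer+PAM pair is
embedded at a designed cut-to-cut spacing (247, 459 and 1953 bp for the
three bundled guide pairs). The localisation, strand mapping and deletion
arithmetic are fully exercised; the spacings themselves are design inputs of
the fixture, not measurements.

## Trace decomposition

A leaf of an edited T1 plant is a mixture of cell files carrying different
repair alleles, so a Sanger read across the cut site degenerates into
superimposed peaks downstream of the break. The decomposition model: an
allele with net indel size $k$ contributes, at reference position $i$
downstream of its junction, the reference base at $i - k$. Over a
decomposition window $W$ the expected four-channel signal is therefore

$$y_{i,b} \;=\; \sum_{k=-K}^{K} w_k \, T^{(k)}_{i,b}, \qquad w_k \ge 0,$$

where $T^{(k)}$ is the shifted-reference indicator template and $w_k$ the
frequency of indel size $k$. `decompose_trace()` row-normalises the observed
heights, solves the non-negative least squares problem with
`pracma::lsqnonneg`, and normalises $w$ to sum to one. Editing efficiency is
$1 - w_0$ (the fraction of cells not wild type) and fit quality is reported
as $R^2$.

Numerical choices:

* `max_indel` ($K$) defaults to 50 — the practical detection limit of the
  approach; larger deletions fall outside the basis and are invisible.
* The window starts `window_offset = 5` positions 3' of the cut and spans
  `window_len = 100` positions. Positions of an insertion allele still
  inside the inserted (unknown) bases contribute a uniform 0.25 across the
  four channels; with the 5-base offset this only matters for insertions
  longer than 5 nt, which are rare in this system.
* Weights below `min_freq = 0.5%` are zeroed and the spectrum renormalised;
  no per-indel significance test is performed. The 1% floor used by the
  downstream statistics is applied separately.
* Base substitutions do not shift the downstream register and are therefore
  counted in $w_0$: SNV alleles are invisible to decomposition by design.
* An all-zero window is an error; a singular fit is reported via the
  `degenerate` flag and a warning, not an exception.

Genotype calling (`call_genotype()`) treats spectrum entries at or above
`allele_floor = 10%` as alleles: one allele is `WT` or `homozygous`, two are
`heterozygous` (one wild type) or `bi_allelic`, three or more `chimeric`;
if no entry clears the floor, or the floored entries sum below
`min_total = 0.7`, the call is `ambiguous`.

## Cohort statistics

`efficiency_summary()` reports the arithmetic mean and median of per-plant
efficiencies on the percent scale. `chimerism_index()` counts spectrum
entries at or above 1%, *including* the wild-type entry — the bundled
per-guide chimerism values (about 3–8) are consistent with either reading,
so the choice is explicit and configurable (`include_wt`). A plant is
chimeric at three or more alleles. `indel_incidence_matrix()` counts, per
guide and indel size, the plants carrying that size at ≥ 1%, and
`recurrent_deletions()` flags deletions strictly larger than 6 bp seen in
five or more plants — recurrence of one particular deletion size across
independent plants is the microhomology-repair signature.

## Repair-junction classification

A junction is a deleted interval plus an inserted string on a reference with
a known cut. Because flanking repeats make the placement ambiguous,
junctions are stored maximally 5'-shifted; the reconstructed product is
invariant under shifting. The flanking microhomology of a deletion is the
longest $k$ with `ref[s:s+k] == ref[e:e+k]`, evaluated in both the 5'- and
(mirrored) 3'-maximal placements and maximised, which makes the value
invariant under reverse complementation of the whole problem.

The synthesis-dependent MMEJ model: after resection, a primer repeat
(P1 + P2, P2 break-proximal) anneals intramolecularly — loop-out when P1 is
a same-strand direct copy of P2, snap-back when P1 is its reverse
complement — with P1 at most `W` bp from the break. A polymerase elongates
the 3' end along the template next to P1 until a microhomology (MH1) is
synthesised whose counterpart (MH2) flanks the break on the far side. The
product then carries a diagnostic direct (loop-out) or inverted (snap-back)
repeat with

$$\mathrm{repeat} = \mathrm{mh} + \mathrm{insert} + \mathrm{p},
\qquad \mathrm{elongation} = \mathrm{insert} + \mathrm{mh}.$$

`enumerate_sdmmej()` searches primer repeats on both sides, in both modes.
A subtlety: the same product string can be written as representations of
different indel arity (a 3-bp deletion with a 2-bp templated insertion can
equal a 1-bp pure deletion when the inserted bases match the reference), so
the enumerator derives *all* representations within the resection bound from
the product's common prefix/suffix with the reference and searches each.
This makes it exactly equivalent to `sdmmej_oracle()`, a brute-force forward
generator of every reachable product under the same bounds, which the test
suite uses as the independent check (soundness: every reported mechanism
reconstructs the product and is oracle-reachable; completeness: every
oracle product yields at least one mechanism).

Defaults and their rationale:

* `W = 30` bp — the proposed limit of the P1 distance from the cut,
  motivated by the single-stranded-DNA binding footprint of RPA;
  configurable.
* `mh_min = 1`: a single-base synthesised microhomology still fits the
  model. `p_min = 1`, with `p_len` reported so users can filter.
* `max_elong = 20` bounds insert + mh; `max_resect` defaults to `W`.
* The MMEJ call for deletion-only junctions requires flanking microhomology
  of at least 2 bp (`mmej_min_mh`); a 1-bp repeat is uninformative.

Classification cascade (`classify_junction()`): a bare +1 insertion is
cNHEJ-consistent (the classic staggered-cut fill-in); a deletion without
insertion is MMEJ at flanking mh ≥ 2 and cNHEJ-consistent otherwise; a
junction with inserted bases is SD-MMEJ if any mechanism explains it
(loop-out preferred over snap-back, longest diagnostic repeat first) and
unexplained otherwise. All mechanisms found are always reported, flagged
`co_consistent` when the top class is cNHEJ/MMEJ. Snap-back is implemented
and enumerated but reported as its own class, since loop-out is the
mechanism with direct experimental support here. Substitutions should be
posed as equal-length deletion + insertion before classification.

## Synthetic data generator

The generator produces every input the pipeline consumes, with ground truth
attached, and its defaults are the study conditions the package is tested
under:

* Mechanism mix per mutant allele: +1 cNHEJ 0.55, cNHEJ deletion 0.30, MMEJ
  0.10, SD-MMEJ 0.05 (loop-out 0.04, snap-back 0.01) — the observed somatic
  landscape is dominated by +1 insertions, followed by deletions of
  increasing size, with microhomology-driven events at lower levels.
* +1 insertions duplicate the base immediately 5' of the cut (the common
  staggered-cut signature; only the predominance of +1 is observed, the
  base identity is a modelling choice).
* cNHEJ deletion sizes are truncated geometric, mean 3 bp, maximum 50 bp
  (matching the decomposition's detection range).
* MMEJ draws a flanking direct-repeat pair (mh ≥ 2, both copies within
  20 bp of the cut) and collapses it; SD-MMEJ alleles are drawn uniformly
  from the forward-enumerated event set within bounds (p 2–6, insert 1–4,
  mh 1–2, resection ≤ 12 bp) so that every simulated allele is recoverable
  by the classifier.
* A T1 plant carries `1 + Poisson(3)` alleles (wild type always present,
  capped at 8) with symmetric Dirichlet(1) frequencies; identical repair
  products are merged, which pulls realised allele counts slightly below
  the Poisson expectation. No quantitative within-plant frequency
  distribution has been published; these are documented, tunable defaults.
* Traces are frequency-weighted indicator mixtures of allele sequences with
  optional Gaussian channel noise (sd 0.05 of a unit peak, truncated at 0).
  Real chromatogram artefacts — dye blobs, mobility shifts, degrading
  signal — are *not* emulated, so passing tests demonstrate correctness of
  the decomposition model, not robustness to real-world chromatogram
  pathology.
* T2 families segregate a single hemizygous unlinked T-DNA locus (0/1/2
  copies with probability 1/4, 1/2, 1/4; resistant when ≥ 1 copy) and the
  target genotype by independent 1:2:1 transmission.

Randomness uses the session RNG; set `set.seed()` (or `--seed` on the
command line) for reproducibility.

## Segregation testing

`segregation_test()` is a Pearson chi-squared test with 1 df of
resistant:sensitive counts against 3:1, without continuity correction (a
Yates-corrected variant is available via `correct = TRUE`); the
single-locus call is `p >= alpha` with `alpha = 0.05`. One consequence of
count discreteness worth knowing: at the workflow's family size of 64
seedlings the exact size of the uncorrected test is 5.9% (the rejection
region is |resistant − 48| ≥ 7), not 5.0%, and the Yates variant is
conservative at 2.9%. The calibration test in the suite computes both the
exact law and the Monte-Carlo rate, and the corresponding acceptance check
is expected to sit near 5.9%.

`in_silico_pcr()` requires each primer to match exactly once in the correct
orientation and returns the forward-start to reverse-end distance;
`dual_guide_screen()` evaluates it over every allele at or above a 10%
band-detection floor (gel sensitivity; tunable) and calls WT/deletion bands
within a ±10 bp size tolerance. `expected_genotype_yield()` provides the
closed-form Mendelian expectations (1/4 null-segregants; 1:2:1 among them
for a heterozygous germline).

## Problem sizes used by the tests and the acceptance script

Simulations are sized to be decisive yet quick: decomposition recovery uses
a 420-nt reference with a 100-position window and 100 noisy replicates;
classifier–oracle equivalence uses 80-nt references (50–100 of them, with a
sample of 20 oracle products and 10 random junctions each, resection bound
8, p ≤ 6, elongation ≤ 10); segregation calibration uses 10,000 families of
64; T2 Mendelian checks use 10,000 seedlings; the simulated guide cohort
has 15 plants, the cohort size of the underlying screening design.

## Known limitations

* Decomposition cannot see substitutions, indels beyond ±K, or distinguish
  same-size alleles with different junctions; reported efficiencies are
  accordingly lower bounds in the presence of SNV alleles.
* The SD-MMEJ search requires the primer repeat and its template to be
  retained in the product (template within the unresected flank), so
  mechanisms whose evidence was resected away are not enumerable even if
  physically possible.
* Exact-match protospacer localisation will miss sites under sequence
  variation between the reference and the transformed accession.
* The synthetic loci are stand-ins; results on them validate arithmetic and
  plumbing, not properties of the real gene sequences.
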