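---
title: "Quantifying uORF-mediated translational repression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying uORF-mediated translational repression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfrepress)
```

## The problem

Upstream open reading frames (uORFs) — AUG-to-stop ORFs whose start codon
lies in the 5′ leader of an mRNA — can repress translation of the downstream
coding sequence (CDS), because scanning preinitiation complexes that initiate
at a uORF are no longer available to the CDS, and reinitiation after uORF
translation is inefficient when the uORF ends close to the CDS. `uorfrepress`
quantifies this repression genome-wide from two inputs: transcript models
(sequence plus leader/CDS/3′-UTR boundaries) and single-nucleotide P-site
alignments from ribosome profiling, together with transcript abundances
(FPKM). All coordinates in the package are 0-based, half-open and
transcript-relative.

## ORF discovery

Every ATG opens an ORF that runs to the first in-frame stop; no minimum
length is imposed at discovery (an initiating ribosome cannot know how long
an ORF will be), so two in-frame AUGs sharing a stop are two distinct uORFs.
ORFs are classified by where the ATG lies and where the stop falls:
`uORF_nonoverlapping` (entirely within the leader), `uORF_overlapping_cds`
(start upstream, stop at or beyond the CDS start), `CDS`, `cds_internal` and
`utr3_orf`. ATGs with no in-frame stop anywhere on the transcript are
excluded and counted. ORF ends are exclusive and include the stop codon, so
the 21-nt minimum uORF length used in quantification corresponds to six
codons plus the stop; whether published length thresholds include the stop is
ambiguous, so the thresholds are configuration values (`min_uorf_len = 21`,
`min_cds_len = 100`).

## Translation efficiency and repressiveness

The TE of an ORF is its P-site read density over `[start, end - 10)` divided
by the transcript's FPKM; the last 10 nt are omitted because terminating
ribosomes pile up at stop codons. No reading-frame filter is applied to
P-sites. uORF repressiveness is the ratio of a uORF's TE to its cognate
CDS's TE; 5′-leader repressiveness is the leader-to-CDS read-density ratio.
Ratios with a zero denominator are recorded as absent rather than dropped
silently, and TEs of 0 are retained in tables but excluded from log-space
analyses (with counts reported) since their logarithm is undefined. Length
filters (21/100 nt) apply only when translation is quantified — discovery
and positional analyses use all ORFs.

## Initiation contexts: the WRENT score

The initiation context of an AUG is the 23-nt window spanning 10 nt on
either side of the codon. A weighted PSSM is trained on the CDS contexts of
transcripts lacking uORFs, each context weighted by `log(1 + TE)` (natural
log; the published log base is unstated, and any base only rescales all
weights equally, which the construction is invariant to). Column
frequencies use a per-base pseudocount (default 0.01 per column, also a
choice the source text does not pin down; it is configurable and recorded in
outputs). The background is the weight-pooled frequency over the 20
flanking positions; the three AUG columns are excluded from both the
background and the score because they are invariant and would shift every
score by the same constant. The WRENT score of a context is the summed
`log2` likelihood ratio over the 20 flanking positions, in bits, and the
per-position relative entropy (the motif-logo letter height) is the usual
Kullback–Leibler term per column.

## Secondary structure profiles

Ensemble free energies (EFE, kcal/mol) are computed in sliding windows
(default 35 nt, step 1; 25/30/40 supported) by a pluggable folding engine.
The default thermodynamic engine shells out to ViennaRNA's `RNAfold -p` at
its default 37 °C parameters (the parameter set used in the original
analyses is unstated; the engine records its parameters in run metadata).
Two deterministic toy engines — a constant engine and a GC-counting proxy —
make every structural computation testable without the external tool.
Anchor EFEs for an ORF are the windows *starting* at `orf_start - 25` and
`orf_start + 1`; note the off-by-one hazard: "+1" is the window beginning
one nucleotide after the A of the AUG, not a window centered there. Region
mean EFEs average only windows lying entirely inside the leader or CDS
(strict containment), and transcripts containing `N` are excluded from
structure profiling since folding is undefined for them.

## Positional statistics

Trinucleotide bias at a leader position is the observed frequency of the
trinucleotide across transcripts divided by the expected frequency from that
position's marginal nucleotide frequencies — a conservative measure of
positional depletion because the expectation uses position-specific
backgrounds. Stop-codon bias can be restricted to stops that actually
terminate a uORF (an in-frame upstream ATG with no intervening stop).
Depletion of uORF ends near the CDS uses a shuffle null: each leader is
permuted (mononucleotide shuffle preserving the exact base multiset; the
published method says only "shuffled", and a dinucleotide-preserving variant
matters mainly for structure statistics, which this test does not use),
uORF ends are re-detected on every shuffled copy, and the observed/expected
end-count ratio is reported with a 24-nt moving average (the same default
window is used for the bias profiles, where the published smoothing width is
not stated). The shuffle seed is mandatory configuration (default 1663) and
profiles are bit-reproducible given it. A zone test compares the observed
end count in an interval with its shuffle distribution,
`p = (1 + #{shuffles <= obs}) / (n_shuffles + 1)`.

## Linear models

Features are Z-scored against their endogenous variation (sample SD), and
responses — `log(uORF TE / CDS TE)` or `log(CDS TE)`, natural logs — are fit
by ridge regression with an unpenalized intercept. The ridge penalty is not
stated in the source analyses; the default here is `alpha = 1` on Z-scored
features, every report records it, and an alpha sweep is a one-line loop
over `model_report()`. The combined score of a transcript is the
coefficient-weighted sum of its Z-scored features. Reported per model:
Pearson r of response vs combined score with a two-sided t p-value (no
multiple-testing correction, mirroring how such model p-values are
conventionally reported), in-sample RESS, leave-one-out PRESS via the exact
ridge hat-matrix identity (an explicit n-refit implementation is exported as
`press_explicit()` and agrees to numerical precision), and the fold change
in the response across the 2.5th–97.5th percentile range (type-7 quantiles)
of the combined score, `exp(slope * range)`, using the fitted slope of the
response on the score. The analysis subsets mirror the study design:
transcripts with exactly one non-overlapping, length-passing uORF for
repressiveness models (uORF identity is unambiguous there), and expanded
subsets (all / with / without uORFs) for CDS-TE models, where uORF burden
enters as log uORF density with a pseudocount of 0.1 uORFs for transcripts
lacking them (the pseudocount exists precisely to make the log defined).
Rows with any absent feature are dropped and counted; a common cause is a
uORF starting fewer than 25 nt from the 5′ cap, which has no −25 anchor
window.

## Cross-species conservation

One-to-one orthologs are compared at the transcript level (per gene, each
species' selected transcript). Read-based quantities (transcript level, CDS
read density, CDS and leader TE, leader repressiveness) enter as natural
logs; each quantity is Z-normalized within the paired subset, and divergence
is the signed difference `z_a - z_b` — signed, not absolute, because the
divergence models need direction. Divergence of CDS read density is modelled
on divergences of CDS TE, leader TE and transcript level with the same
ridge/PRESS machinery.

## The synthetic-data generator

Because the original ribosome-profiling datasets are external, every stage
is exercised on synthetic data whose generative structure inverts the
analysis. `sim_config()` defaults describe the emulated conditions, chosen
once to reflect either published observations or field-typical values:

* leader lengths log-normal (median ≈160 nt, min 30), CDS lengths log-normal
  (median ≈480 nt, floored at 120 nt, codon-rounded), GC 45% — mammalian-like
  at desk scale;
* a Kozak-like initiation motif planted at CDS starts with per-transcript
  strength, providing realized WRENT variance (the planted consensus is a
  sharpened parameterization of published initiation-context preferences,
  not a claim about any fitted PSSM);
* uORFs planted as complete ATG…stop ORFs (7–25 codons) at
  Poisson(`uorf_rate`) per leader on top of chance AUGs, with an end-zone
  survival multiplier of 0.4 in `[-100, 0)` emulating selection against
  uORF ends near the CDS — applied both as thinned placement of planted
  uORFs and as probabilistic stop-codon disruption of realized (chance)
  ends, since observed depletion reflects selection on all AUG–stop pairs,
  not only on some designated subset;
* log CDS TE follows a linear model over Z-scored *realized* features with
  the sign structure of the fitted models (uORF density and uORF WRENT
  repressive; CDS WRENT and the region mean EFEs — less stable structure —
  beneficial), plus Gaussian noise (sd 0.5) and a shared per-transcript
  translational activity (sd 0.6) that also scales uORF TEs, reproducing the
  observed positive correlation between leader and CDS translation;
* uORF TE scale 0.08 and background leader read rate 0.05 put the
  leader-TE increase associated with uORFs in the published 33–71% range;
* P-site counts are independent Poissons, uniform within each translated
  ORF (rate `te * fpkm * depth` per nt) plus background — no stop-codon
  peak, no frame periodicity, no overdispersion.

Ground truth stores realized features re-measured with the pipeline's own
extractors (reference PSSM, GC toy engine), so conventions can never drift
between generator and analysis. Ortholog pairs share a latent bivariate-
normal translation state at correlation `rho`; sequences are drawn
independently per species because sequence-derived features cannot be
meaningfully correlated across independently generated sequences, so
cross-species recovery targets the read-based quantities. Everything is
reproducible from `(config, seed)`.

What passing tests on this generator do **not** show: robustness to
overdispersed counts, ribosome pausing and stop-codon peaks, frame
structure, isoform ambiguity, or non-AUG initiation (deliberately excluded
throughout, as in the source analyses).

## Numerical and design choices

* Ridge solves penalized normal equations on the augmented `[1, X]` design;
  `alpha = 0` on a singular design errors with advice rather than
  pseudo-inverting.
* LOO-PRESS uses the exact hat-matrix identity for a fixed penalty; the
  explicit refit path never re-estimates Z-scalers, which is what makes the
  two routes agree exactly.
* Quantiles are type 7; sample SDs use the `n - 1` denominator; tie-breaks
  in isoform selection fall back to the lexicographically smallest
  transcript id for determinism.
* Degenerate inputs (empty regions, zero-variance features, leaders shorter
  than a codon, transcripts shorter than the folding window) return typed
  absent values or fail with the offending filter named.
* Problem sizes in the shipped tests and acceptance script (hundreds to a
  few thousand transcripts, 50–1000 shuffles) are the package's desk-scale
  defaults; all constants scale up unchanged.

## Known limitations

Genome-to-transcript projection (GTF exon arithmetic) is out of scope: the
annotation contract is transcript-relative spans. P-site offset calibration
is upstream of the package. The shuffle null is mononucleotide; the
dinucleotide-preserving option is not implemented because no analysis here
depends on shuffled structure. Real n in single-uORF subsets is governed by
read depth and leader geometry and will differ from any fixed target.
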