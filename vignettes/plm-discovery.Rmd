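---
title: "Preferentially located motifs: model, design decisions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preferentially located motifs: model, design decisions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plmscan)
```

## The model

A promoter set is a collection of DNA sequences aligned on the
transcription start site: every record carries a fixed upstream extent
(1 kb by default) and its own 5'UTR of at least 50 bases. The TSS base is
position 0; a motif's position is the position of its first base. All
motifs are exact strings (IUPAC degeneracy is expanded to a finite motif
set); there are no weight matrices anywhere in the package — positional
specificity, not binding energetics, is the object of study.

For one motif the detector builds a positional distribution: for each
window `[p, p+w-1]` it counts the promoters with at least one occurrence
starting in the window. Counting promoters rather than occurrences is
deliberate: microsatellite-like motifs occur in runs, and occurrence
counts would let a handful of repeat-rich promoters dominate a window.
A promoter contributes to a window only if its sequence fully covers it,
and per-window coverage is tracked because 5'UTR lengths vary.

The background model is an ordinary least-squares line fitted to the
counts over the learning region `[-1000, -300]`, far enough upstream that
core-promoter elements contribute nothing. The line gives the base line;
peaks are judged against an upper bound

`bound(p) = baseline(p) + z* · s · sqrt(1 + 1/n + (p - pbar)^2 / Sxx)`

with `s` the residual standard deviation. Two choices here are ours and
matter:

* **Family-wise level.** `z*` is the one-sided normal quantile at
  `1 - (1 - ci_level)/m`, with `m` the number of searched windows (801 by
  default). A pointwise 99% bound would be exceeded by pure noise in about
  eight of the 801 windows of every scan, so each of the 4096 hexamer
  scans would report a "peak"; taking the level family-wise makes "the
  peak exceeds the 99% bound" a single statement about the whole scan.
  Under a null simulation (motif planted uniformly across all positions)
  the detector then reports a PLM in only a few percent of runs, which the
  test suite checks.
* **Skew correction.** Window counts are Poisson-like and right-skewed; a
  plain normal quantile under-covers the far tail exactly where the
  family-wise quantile lives. `z*` therefore carries a Cornish–Fisher
  third-moment correction, `z + gamma (z^2 - 1)/6`, with `gamma` the
  residual skewness estimated from the learning region and clamped at 0 so
  a left skew can only widen, never tighten, the bound. The
  `sqrt(1 + 1/n + ...)` factor is the standard prediction-interval
  widening; it matters only at the region edges.

The **score of maximal square** at the search-region maximum `p*`,

`SMS = (count(p*) - baseline(p*)) / (bound(p*) - baseline(p*))`,

measures the peak in units of the bound height; `SMS > 1` is exactly
"peak above the bound". When the learning region is noiseless and flat the
denominator is zero and a condition of class `plm_zero_denominator` is
signalled; callers treat the motif as not preferentially located, since a
distribution with no background variability offers no scale to judge a
peak against.

## Window escalation

The sliding-window size starts at 1 and grows while the learning region
looks unlearnable: it must contain no empty window (an all-zero tail makes
the regression meaningless for rare motifs) and no window above the bound
(a peak inside the learning area would contaminate the base line). The
zero trigger is monotone in the window size, so the minimal zero-free size
is computed in closed form from the gaps between occurrence positions and
the escalation loop usually fits the model once. The size is capped at
`max_window = 100`; rare motifs (8-mers and longer at a few thousand
promoters) hit the cap and are scanned at 100 with the zeros they have.

This coupling fixes the learning-region mean count near the zero-free
threshold (about `log` of the number of learning windows) regardless of
motif length — a point that shapes the extension rule below.

## Peaks, positions, ties

The search-region maximum is located with ties broken toward the most
downstream window start. The functional window is the maximal contiguous
above-bound run containing the maximum, reported in base positions
`[first start, last start + w - 1]`; its width necessarily grows with `w`,
because a window of size `w` smears a point source over `w` consecutive
starts. The reported **preferential position** is therefore refined: the
width-1 counts are re-examined inside the maximal window itself and their
argmax (ties again downstream-most) is reported. A motif planted at a
single position `q` is then localised at exactly `q` for any window size,
which the recovery tests exploit; and because the refinement is local to
the peak window, a distant secondary signal merged into the same
above-bound run cannot pull the reported position away from the peak top.

Positional acceptance in the cascade and the extension step — "sharply
positioned in the TATA region" — is the refined preferential position
lying inside `target = [-39, -26]`. We deliberately do not require the
functional window to be contained in the target region: window width
scales with `w`, and `w` is dictated by background sparsity (1–2 at
genome-scale promoter counts, 15–50 at the few-thousand scale the test
suite uses), so containment would couple a biological criterion to an
algorithmic artefact. The peak-top position is the `w`-invariant summary.

## The discovery cascade

`run_cascade()` mirrors the subtraction design: detect the canonical
TATA-box pattern TATAWA in both species, remove the promoters carrying it
inside its detected functional window, then scan the Hamming rings at
distance 1, 2 and 3 from the TATAWA expansion on the shrinking sets, then
the 16 dinucleotides, and finally all 4096 hexamers on the TA-less sets.
Acceptance always requires an in-target PLM in **both** species —
identical preferential positions are not required. Motifs accepted within
one stage are subtracted simultaneously, which makes the within-stage
order immaterial; subtraction uses each species' own functional window.
The distance-2 ring of TATAWA contains 210 motifs by exhaustive
enumeration (rings partition the 4096-hexamer space as 2/32/210/720/1350/
1296/486), and the suite pins these counts.

Two empirical behaviours the cascade reproduces, and which motivated the
synthetic designs below: a broad pyrimidine (TC-microsatellite) signal
downstream of the TSS can hide a sharply positioned upstream TC peak until
the TATA-class promoters are removed; and hexamers overlapping a planted
element by five bases pick up quarter-strength phantom peaks through their
one random flanking base.

## Extension

`extend_plm()` grows a PLM one base at a time (eight candidates per round:
four bases on either side), accepting the best candidate that is an
in-target PLM with an SMS at least 1.1 times the current one. Candidate
SMS values are evaluated **at the starting PLM's window size**. This is a
considered deviation from re-detecting each candidate adaptively: the
escalation rule pins the learning-region mean near the zero-free threshold
for every motif length, so adaptively detected SMS values are nearly
scale-free in motif length and a genuine signal would never clear a
1.1-fold hurdle. At a common window size the comparison is between like
quantities, and a true one-base extension roughly doubles its SMS because
the background rate drops four-fold while the planted signal is retained.
Growth is one base per step (no simultaneous two-sided growth), greedy,
with lexicographic tie-breaking — deterministic for a fixed set.

## What the generators emulate — and what they do not

`sim_promoters()` produces i.i.d.-background promoters (composition
configurable, uniform by default), 5'UTRs uniform on 50–500 bases,
plantings that overwrite the background at a point, uniformly over an
interval, or with truncated Gaussian jitter, and an optional downstream
pyrimidine tract built from repeat units. Defaults were chosen once to
match the promoter architecture the detector assumes:

* 1 kb upstream extent and a minimum 50-base 5'UTR are the validation
  rules of the input format itself.
* The cascade test plants the TATA-box jittered over `[-38, -27]` and a
  TC-element as the 9-base pyrimidine repeat TCTTCTTCT jittered over
  `[-39, -29]` in a disjoint subset — embedding the hexamer in pyrimidine
  context matters, because all-pyrimidine shifted hexamers are at least 4
  substitutions away from TATAWA and so cannot leak into the TATA rings,
  whereas a bare hexamer with random flanks scatters quarter-strength
  phantoms into the distance-3 ring.
* The tract mixes `TC` and `TTTC` repeat units: together they give the
  dinucleotides TC, CT and TT a broad downstream signal (so the
  dinucleotide stage, like the real analysis, rejects them as positionally
  unconstrained) while containing no TCTTCT occurrence that would mask the
  planted element in the TA-less scan. The masking test, by contrast,
  plants a `TCT`-repeat tract precisely because it is dense in TCTTCT.

The backgrounds are independent across positions and promoters; real
promoters are not (isochores, TA/CpG skews, nucleosome signals), their
element positions are not uniform within the functional window, and their
count dispersion exceeds Poisson. Passing the synthetic suites therefore
demonstrates the correctness of the computations and the qualitative
behaviours (masking, subtraction, extension), not calibrated error rates
on genomic data. SMS magnitudes in particular depend on the background
dispersion and are not comparable across data sources.

## Statistical procedures

Enrichment comparisons are one-sided Fisher exact tests on 2×2 tables with
an explicit Bonferroni family size `m` — explicit because no default
family is defensible across tables; significance is adjusted p < 0.05.
Rank comparisons use the Wilcoxon–Mann–Whitney test, exact whenever there
are no ties and the combined size is at most 200 (the exact tail is what a
rank permutation converges to; the normal approximation can be tens of
percent off at p below 0.01), normal with tie and continuity correction
otherwise. Orthologue conservation compares observed `c/(a+c)` with
chance-expected `b/(N-a-c)` and tests the co-occurrence table one-sided.
Expression classification fits a cubic baseline by least squares; HE is
strictly above the line (points on it, within numerical roundoff, are LE),
SR/WR are fixed 15%/85% breadth thresholds, and the HE+/LE+ extremes lie
outside a central 60% residual band, normal-quantile by default with an
empirical-quantile alternative (`band = "empirical"`) since the band's
construction is a modelling choice, not a derived quantity.

## Problem sizes and determinism

The test suite and the acceptance script run on synthetic sets of 250–2000
promoters of about 1.05–1.5 kb — sizes chosen so the full suite, including
two complete two-species cascades (each scanning roughly 6000 motifs per
species through a keyed hexamer position index), completes in a few
minutes on one CPU. All generators take explicit seeds and restore the RNG
state; identical configuration and seed give byte-identical FASTA. Graph
construction, cascade staging and extension are deterministic given their
inputs (lexicographic orderings, downstream-most tie-breaks, simultaneous
within-stage subtraction).

## Known limitations

* Exact-string matching only; a single mismatch in an element makes it a
  different motif (by design, but worth restating).
* No multiple-testing control across the 4096 hexamer scans beyond the
  per-scan family-wise bound; the two-species conservation requirement is
  the de-facto filter.
* The learning region must be fully covered by every promoter; sets with
  shorter upstream extents are rejected rather than rescaled.
* Dinucleotide-stage subtraction can, in architectures unlike the ones
  profiled here, remove promoters carrying longer elements that share
  dinucleotides with them; the cascade reports its ledger precisely so
  such removals are visible.
* `motif_graph()` merging of a degenerate pattern into one node sums the
  member counts unless a de-duplicated count is supplied for the label;
  promoters containing several members are then double-counted.
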