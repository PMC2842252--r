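# plmscan

Core promoter elements are defined as much by *where* they sit as by what
they spell: the canonical TATA-box is found almost exclusively 26–39 bases
upstream of the transcription start site (TSS). **plmscan** finds such
Preferentially Located Motifs (PLMs) ab initio in promoter sets aligned on
the TSS, and implements the full discovery workflow used to chart the plant
core promoter: iterative subtraction of motif classes (TATA-box → TATA
variants → dinucleotides → TC-elements in the TA-less set), two-species
conservation filtering, motif distance graphs with seed motifs, greedy
motif extension, initiator-spacing profiles, expression-class analysis and
orthologue conservation statistics. It is aimed at regulatory genomicists
working with TSS-annotated promoter collections (plants especially), and at
anyone who wants a tested, synthetic-data-validated reference
implementation of positional k-mer enrichment.

## The method

For a motif *m* and a promoter set aligned on the TSS (position 0, upstream
negative), plmscan counts in a sliding window of size *w* (one-base shift)
the number of **distinct promoters** with an occurrence of *m* whose first
base lies in the window `[p, p+w−1]` — occurrences are never double-counted
within a window. The distal region `[−1000, −300]` is used to learn a
background model by simple linear regression of the counts on the window
start,

    baseline(p) = a + b·p,   bound(p) = baseline(p) + z·s·√(1 + 1/n + (p−p̄)²/Sxx)

where `s` is the residual standard deviation and `z` a one-sided
normal quantile taken family-wise over the searched windows (with a
third-moment Cornish–Fisher correction for the right skew of count
residuals). The window size is escalated from 1 while the learning region
contains an empty window or a window above the bound (up to 100). Within
`[−300, 500]` a motif is a PLM when its count maximum exceeds the bound;
its strength is the **score of maximal square**

    SMS = (peak − baseline) / (bound − baseline),   PLM ⇔ SMS > 1.

Each PLM is reported with its preferential position (peak top, refined at
width 1 inside the maximal window), functional window (the contiguous
above-bound run), SMS and matching promoters.

The discovery cascade then runs on two species at once: TATAWA (W = A/T)
is detected and its promoters subtracted; Hamming rings at distance 1, 2, 3
from the TATAWA expansion are scanned on the shrinking sets; then the 16
dinucleotides; finally all 4096 hexamers are scanned in the TA-less sets.
A motif is accepted when it is a PLM in **both** species with its
preferential position inside the TATA target region `[−39, −26]`.

## A worked example

```r
library(plmscan)

# a synthetic promoter set: 1000 promoters, 1 kb upstream + variable 5'UTR,
# TATAAA planted at -32 in 20% of them
sim <- sim_promoters(1000, plantings = list(planting("TATAAA", -32, 0.2)),
                     seed = 42)
rec <- detect_plm(sim$set, "TATAAA")
rec
#> PLM TATAAA: position -32, functional window [-51, -13], window size 20
#>   SMS 24.50 (peak 207, baseline 4.00, upper bound 12.29); 209 promoters
```

The detector recovered the planted position exactly: the peak holds 207
promoters against a background base line of 4 per window, 24.5 times the
99% bound height — an unambiguous PLM. `plot(rec)` draws the distribution
with base line and bound.

Extension grows a PLM one base at a time while the SMS improves at least
1.1-fold per step:

```r
sim <- sim_promoters(2000, plantings = list(planting("TCTTCTTCT", -33, 0.25)),
                     seed = 71)
extend_plm(sim$set, "CTTCTT")
#> PLM extension from CTTCTT (window 11, factor 1.10):
#>      motif length       sms position n_promoters
#>     CTTCTT      6  44.17236      -32         507
#>    TCTTCTT      7  66.66328      -33         500
#>   TCTTCTTC      8 100.62582      -33         500
#>  TCTTCTTCT      9 149.11033      -33         500
#> final motif: TCTTCTTCT
```

Starting from the internal hexamer, the chain recovers the planted
9-base pyrimidine element; the SMS grows at every step because the
background rate of the lengthening motif falls four-fold per base while
the planted signal stays.

Conservation arithmetic for orthologue pairs:

```r
conservation_stats(393, 343, 82, 5805)
#> conservation: observed 17% vs expected 6% (a=393, b=343, c=82, N=5805); p = 2e-14
```

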