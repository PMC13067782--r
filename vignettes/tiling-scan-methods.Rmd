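---
title: "Tiling-screen simulation and functional-domain scanning: methods"
author: "tilescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiling-screen simulation and functional-domain scanning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilescreen)
```

## The problem

A CRISPR tiling screen ("CRISPR scanning") mutagenizes a coding sequence at
every targetable position and reads out which positions a cell population
cannot afford to lose. A saturating sgRNA library — one guide per SpCas9
NGG protospacer-adjacent motif (PAM) on either strand — is transduced at
low multiplicity into Cas9-expressing cells, the pool is grown under a
selective condition (here: in vivo tumor growth) alongside an in vitro
reference culture, and each guide's change in frequency is measured by
sequencing. Guides whose cut sites fall in residues required for fitness
deplete more strongly than guides in dispensable residues; smoothed along
the protein, the per-guide depletion signal localizes functional domains
at near-residue resolution.

`tilescreen` implements the full desk-side arm of that experiment: library
design, a generative model of the screen (so the analysis can be validated
against known truth), depletion scoring, smoothing, and region calling.

## Guide design and coordinates

SpCas9 cuts bluntly between protospacer positions 17 and 18, i.e. 3 bp
5' of the PAM. We record `cut_nt`, the first nucleotide 3' of the cut on
the coding strand: a plus-strand PAM whose first base sits at CDS position
`p` gives `cut_nt = p - 3`; a minus-strand PAM (a `CCN` on the coding
strand starting at `q`) gives `cut_nt = q + 6`. The guide is attributed to
the residue whose codon contains `cut_nt`, `floor((cut_nt - 1)/3) + 1`,
with no half-codon splitting — the simplest rule that is exactly testable.
A candidate whose 20-nt protospacer overhangs the CDS is completed from
flanking context when provided, otherwise dropped and logged; the PAM and
cut site must always lie inside the CDS. No off-target or efficiency
filtering is applied: a saturating library is the point.

Non-targeting controls are seeded random 20-mers rejected if they occur on
either strand of the target. Their count is configurable; tiling-scale
libraries in this field typically carry on the order of one control per
few targeting guides.

## The diploid repair-outcome model

After a double-strand break, error-prone end joining produces a frameshift
allele with probability 2/3 and an in-frame indel with probability 1/3,
independently per allele. A frameshift destroys the allele. An in-frame
indel destroys it only when the deleted/inserted residues matter — we give
each residue a disruption probability $d \in [0,1]$, the knob that
separates critical domains ($d \to 1$) from dispensable sequence
($d \to 0$). With editing efficiency $e$ (default 1) the per-allele
loss probability is $e\,(2/3 + d/3)$, and for a cell of ploidy $k$
(default 2, alleles independent) the fraction of guide-receiving cells
with **zero** functional alleles is

$$ f(d) = \left[e\left(\tfrac{2}{3} + \tfrac{d}{3}\right)\right]^k . $$

At the defaults this spans $f(0) = 4/9 \approx 44\%$ (only frameshifts
matter) to $f(1) = 1$ (every edit is a knockout) — the dynamic range the
scan exploits. Cells with at least one functional allele are treated as
fully functional; no haploinsufficiency state is modeled.

Under selection, loss-of-function cells grow with relative fitness
$1 - s$ per generation. A guide's expected abundance after $T$
generations in condition $c$ is $A_c = f(1-s_c)^{T_c} + (1-f)$, and the
expected depletion is $\log_2 (A_{\mathrm{scr}}/A_{\mathrm{ref}})$,
floored at $-10$ so downstream smoothing always sees finite numbers.

## The synthetic screen

`simulate_screen()` forward-simulates the protocol: per guide, `coverage`
cells; per cell, per-allele repair outcomes with $d$ looked up at the
guide's residue (controls cut nothing); `T_pre` generations of shared
pre-depletion culture at `s_ref`; then the screened arm — optionally
thinned by a binomial engraftment bottleneck — grows `T_scr` generations
at `s_scr` while the reference arm continues at `s_ref`; finally each
sample is one multinomial read draw of size `depth` over guides.

Defaults are chosen once to mirror a realistic in vivo dropout screen:
`T_pre = 21` (three weeks at one division per day), `T_scr = 20`
(three to four weeks in vivo), `coverage = 1000` cells per guide,
`depth = 1e6` reads, `s_scr = 0.3`, `s_ref = 0`. The default propagation
mode is deterministic in expectation, with stochasticity at the bottleneck
and at sequencing; this isolates the signal the scan must detect. A full
Wright-Fisher mode (`mode = "wright-fisher"`, constant population,
per-generation multinomial resampling) adds within-passage drift when the
question is robustness to noise. Screened replicates are independent
selection realizations (separate animals); reference replicates are
sequencing draws from the single shared culture. One guide per cell is
assumed (low-MOI transduction); immune-compartment dynamics, spatial
growth, and guide-guide interactions are deliberately out of scope, so a
passing recovery test says the analysis works *when the screen behaves
like this model*, not that any real screen does.

`make_itgb1_like_fixture()` builds the recovery benchmark: a synthetic
random-codon 2394-nt CDS (798 residues), its full tiling library, and a
truth implanting five domains at residues 153–171, 248–254, 280–295,
305–314 and 359–363, the first given $d = 1$ and the others $d = 0.8$ —
strong but submaximal disruption, so exactly one domain is expected to
dominate the ranking. The CDS is synthetic; only the interval coordinates
and the screen scale are modeled on a real experiment.

## Depletion scoring

Counts become frequencies with a pseudocount of 0.5 (standard zero
handling), log2 ratios are taken per replicate pair, centered on the
median of the non-targeting controls, averaged across pairs, and
re-centered so the control median is exactly zero. The robust z-score
divides by `1.4826 × MAD` of the control distribution. Centering on
controls rather than on all guides matters in a tiling screen: when the
target gene itself is required, *every* targeting guide depletes (by at
least $f(0) = 4/9$ worth of knockouts), and only the controls identify
the no-effect baseline.

The gene-level mode (`score_genes()`) is a deliberately simple
median-z-with-permutation ranking for multi-guide-per-gene libraries:
the null is built from same-size random control-guide sets,
$p = (1 + \#\{\text{null} \le \text{obs}\})/(B+1)$, BH-adjusted across
genes. It is not an α-RRA/MAGeCK reimplementation and is documented as
such. Null sets are drawn independently per gene: sharing one null
sample across genes makes all gene p-values rise and fall together with
that sample's quirks, which wrecks any uniformity diagnostic; the price
is that p is monotone in score only up to permutation noise.

## Smoothing and region calling

The per-residue track is a Nadaraya–Watson estimate with a Gaussian
kernel, default bandwidth $h = 5$ residues — wide enough to pool the
roughly one guide per 3–4 residues a saturating NGG library yields, narrow
enough to resolve the shortest domain of interest (5 residues). The kernel
mass (`support`) is reported per residue and low-support residues are
masked rather than extrapolated.

Significance comes from a score-permutation null: guide z-scores are
shuffled over the fixed guide positions (preserving the library's spatial
density), the track is re-smoothed $B$ times (default 1000), and the
one-sided empirical p-value is the add-one rank. Regions are called by BH
adjustment at level `alpha` over supported residues, merging significant
runs across gaps of at most `max_gap = 2` residues and dropping regions
shorter than `min_len = 3` — defaults chosen so a genuine 5-residue domain
is never precluded. Region score is the mean smoothed signal (ranked most
depleted first) and region p the minimum member adjusted p.

The choice $B = 1000$ is not cosmetic. With $\sim$800 tested residues and
a single standout domain occupying $\sim$25 of them, the smallest
BH-adjusted p attainable at the add-one floor is roughly
$\frac{1}{B+1}\cdot\frac{800}{25}$; at $B = 300$ that is $\approx 0.10$
and no region can ever clear $\alpha = 0.05$, however strong the signal.
$B$ must exceed $\sim$600 for the floor to clear; 1000 leaves margin.

Consensus across screens (e.g. two engraftment models) defaults to
interval intersection — the strictest reading of "consensus" — with a
union mode behind a flag. Recovery against simulated truth is scored by
inclusive-residue Jaccard; a domain counts as recovered at Jaccard
$\ge 0.5$.

## Calibration diagnostics and their design

Two null diagnostics back the method. Per-residue: on a fully neutral
simulated screen the empirical p-values should be uniform; because
smoothing correlates residues within $\sim h$, the KS test is applied to
residues spaced $3h$ apart (near-independent), not to all residues, which
would overstate the evidence against uniformity. Gene-level: 500 null
genes of 5 guides each. Here the control pool size is the critical design
parameter: all gene p-values share the same finite control sample, so
control-pool sampling noise ($\sim 1.25/\sqrt{n_{\mathrm{ctrl}}}$ on the
null median) shifts them coherently, and with a few hundred controls the
KS test rejects a perfectly correct implementation most of the time. The
calibration therefore uses a control pool equal in size to the targeting
set, keeping pool noise below the KS resolution at 500 genes. Real
libraries have far fewer controls; their gene p-values should be read as
rankings with approximate calibration, not exact ones.

## Problem sizes and numerical choices

The shipped tests run the recovery benchmark at coverage 500, depth
$10^6$, $B = 1000$ and 20 neutral seeds for the false-positive check, and
the calibrations at $B = 500$ (residue) and $B = 200$ (gene) — sizes at
which every stochastic check has comfortable statistical margin while the
whole suite stays interactive. Determinism is enforced end to end: a
single run seed feeds named per-stage substreams, TSV/JSON writers emit
LF/UTF-8 with locale-independent ordering, and rerunning a configuration
reproduces every artifact byte-for-byte.

Known limitations: residue attribution ignores that an indel disrupts a
window of residues, not one codon; $d$ is constant within an implanted
domain; selection coefficients are constant over time; and the
permutation null conditions on the observed z-distribution, so gross
global artifacts (e.g. a failed reference sample) must be caught upstream
at scoring, not by the scan.
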