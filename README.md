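# tilescreen

Saturating CRISPR tiling screens ("CRISPR scanning") map which parts of a
protein a cell population needs: one sgRNA per NGG PAM along a coding
sequence, pooled selection (e.g. in vivo tumor growth) against an in vitro
reference, and per-guide depletion smoothed along the protein to call
functional domains at near-residue resolution. `tilescreen` is an R
package for the desk-side arm of such screens, aimed at people designing,
simulating, or analyzing tiling libraries:

- **Library design** — enumerate every SpCas9 NGG site on both strands of
  a CDS, map each blunt cut (3 bp 5' of the PAM) to its residue, add
  seeded non-targeting controls.
- **Repair-outcome model** — the diploid loss-of-function arithmetic that
  powers the scan's dynamic range. Per allele, a cut repairs to a
  frameshift with probability 2/3 or an in-frame indel with probability
  1/3; an in-frame indel disrupts function with residue-dependent
  probability *d*. The fraction of guide-receiving cells with zero
  functional alleles is

  f(d) = [e·(2/3 + d/3)]^k,   (editing efficiency e, ploidy k)

  spanning 4/9 ≈ 44 % at *d* = 0 up to 100 % at *d* = 1 for a diploid
  with full editing.
- **Forward simulation** — pre-depletion culture, optional engraftment
  bottleneck, selection over generations (deterministic expectation or
  Wright–Fisher), multinomial sequencing; ground truth ships with the
  counts so recovery is measurable.
- **Scoring and scanning** — control-anchored log2 fold-changes and
  robust z-scores, Gaussian-kernel smoothing over residues, a
  score-permutation null with BH-controlled region calling, consensus
  across screens, and Jaccard-based recovery metrics.

## Worked example

Simulate a tiling screen of a synthetic 798-residue receptor with five
implanted functional domains (strongest at residues 153–171), then try to
find them again:

```r
library(tilescreen)

loss_fraction(repair_outcome_model(), c(0, 0.5, 1))
#> [1] 0.4444444 0.6944444 1.0000000

fx <- make_itgb1_like_fixture(seed = 1)
fx$truth
#> <sim_truth> 798 aa, 5 domain(s); s_scr=0.3 s_ref=0 T_pre=21 T_scr=20
#>             coverage=500 depth=1e+06

sc <- simulate_screen(fx$library, fx$truth, n_replicates = 2, seed = 11)
gs <- score_guides(sc, fx$library)
tr <- permutation_null(smooth_track(gs, fx$library), B = 1000, seed = 12)
(calls <- call_regions(tr, alpha = 0.05))
#>   start_aa end_aa     score          p rank
#> 1      153    177 -401.8524 0.03188811    1

evaluate_calls(calls, fx$truth)$per_domain
#>   start_aa end_aa best_jaccard
#> 1      153    171         0.76
#> 2      248    254         0.00
#> ...
```

Reading the output: every targeting guide depletes somewhat (frameshifts
knock the gene out anywhere along the CDS — that is the 44 % floor), so
scores are measured against the non-targeting controls. The top-ranked
called region (153–177, mean smoothed z ≈ −402, region p = 0.032)
recovers the implanted 153–171 domain with Jaccard 0.76; the weaker
*d* = 0.8 domains fall below the region-calling threshold under these
screen conditions, which is the expected behavior of a scan whose null is
dominated by the strongest signal. The methods vignette
(`vignettes/tiling-scan-methods.Rmd`) explains the model, parameter
defaults, and calibration diagnostics.

A YAML-driven end-to-end run (`run_pipeline()`) and a small CLI
(`inst/cli/tilescan.R`, subcommands `design`/`simulate`/`score`/
`genescore`/`scan`/`evaluate`/`run`) chain the same stages and write
library/counts/scores/track/region artifacts plus a manifest; identical
configuration and seed reproduce every file byte-for-byte.

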