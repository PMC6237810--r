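# northernlights

Simulation and densitometric quantification of DNA damage on 2D
strandness-dependent electrophoresis (2D-SDE) gels — the computational core
of the Northern Lights Assay (NLA).

## The problem

The NLA detects and distinguishes the major structural DNA lesions in one
run. A DNA specimen is analyzed as a pair: one aliquot undigested, one
digested with Mbo I (a 4-cutter that cleaves both ssDNA and dsDNA at
`GATC`). Dimension 1 separates native molecules by length, strandness and
damage-induced conformation; the gel is then heat-denatured in place and
dimension 2 separates the resulting single strands by length alone — unless
interstrand crosslinks keep the two strands covalently attached. Each lesion
type therefore lands in a characteristic part of the 2D plane:

| signal | gel position | lesion |
|---|---|---|
| unmigrated | near the well | intact high-MW DNA (undigested aliquot) |
| dsDNA arc | diagonal, co-migrating with the Cy5 ladder | intact duplex fragments |
| behind the arc | left of the arc at the same dimension-1 position | interstrand crosslinks (strands stay joined: effective dimension-2 size ≥ 2×) |
| in front of the arc | right/above the arc | intrastrand crosslinks and monoadducts (bent duplexes), ssDNA, strands released by nicks |
| horizontal streak | along the limiting-mobility row | single-strand breaks in high-MW DNA |

No public image data accompany the assay, so this package provides both
sides: a forward simulator (molecule-level damage model + phenomenological
mobility model + two-channel raster rendering with known ground truth) and
the quantification pipeline (ladder band detection, monotone size
calibration, the five diagnostic regions, background-corrected fraction
percentages, size distributions, apoptosis-ladder peak calling), plus an
alkaline comet assay simulator/scorer (tail moment = fraction of DNA in the
tail × tail length) and repair statistics (pooled-variance Student's *t*).

## The mobility model

Migration distance follows a semi-log law on the resolving range
(L_min = 50 nt to the limiting-mobility size L_sat = 20 kb):

    d(L) = d_lim + (d_max − d_lim) · clamp( log(L_sat/L) / log(L_sat/L_min), 0, 1 )

Dimension 1 multiplies `d` by `ss_d1_factor` (0.85) for single strands and
by `1/(1 + bend_kappa · n_bend)` (κ = 0.15) for adduct-bent duplexes;
dimension 2 applies the bare law to the single-strand (or crosslink-network)
length. See the methods vignette for every default and its rationale.

## Worked example

```r
library(northernlights)

sim <- simulate_experiment("cisplatin-dose", params = list(dose = 8), seed = 42)
q   <- quantify_gel(sim$digested)
q$report[, c("region", "percentage")]
#>       region percentage
#> 1 undigested       0.00
#> 2      dsDNA      45.63
#> 3     behind       1.96
#> 4      front      48.41
#> 5 ssb_streak       4.00
round(sim$truth$digested, 3)
#> unmigrated     ds_arc     behind front_bent   front_ss ssb_streak
#>      0.000      0.439      0.050      0.414      0.096      0.000
```

At 8 µM roughly half the digested material still runs on the intact dsDNA
arc (45.6% quantified vs 43.9% true), the bent/denatured material dominates
the front fraction (48.4% vs 41.4 + 9.6%), and a small interstrand-crosslink
arc appears behind the dsDNA. The comet comparator:

```r
b <- comet_batch(100, fraction_in_tail = 0.3, tail_length = 60, seed = 1)
mean(b$percent_dna_in_tail)  #> 29.6
mean(b$tail_moment)          #> 17.76
```

Gel rasters are written as 16-bit PGM pairs plus PNG previews
(`write_gel_image()`); a command-line interface wraps the pipeline:

```sh
Rscript inst/cli/nla.R simulate --scenario apoptosis --seed 7 --out run1
Rscript inst/cli/nla.R quantify --image run1/undigested
```

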