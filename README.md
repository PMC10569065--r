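# mosaicscan

Tools for two analyses that recur in studies of bacterial quorum-sensing
peptide transport:

1. **Mosaic-locus detection.** Some loci — such as the *app*
   oligopeptide-permease operon of the *Bacillus subtilis* group — are
   mosaics: their flanking genes follow the species phylogeny while an
   internal segment was acquired horizontally and exists as a small
   number of deeply divergent alleles. `mosaicscan` finds such segments
   by sliding a window (default 500 bp advancing in 50 bp steps) along a
   multi-strain nucleotide alignment, building a neighbor-joining tree
   per window from Jukes–Cantor distances, and comparing trees with the
   branch-length-aware *K tree score*: the comparison tree is rescaled
   by the factor

   K\* = Σ b_c b_r / Σ b_c²

   over the union of bipartitions (missing branches count 0), and the
   score is √Σ (K\* b_c − b_r)². Windows incongruent with a reference
   species tree are segmented into contiguous regions with breakpoint
   estimates, and strains are clustered into alleles within the
   incongruent region.

2. **Peptide import dose-response.** Reporter expression as a function
   of signalling-peptide concentration *c* is modeled with an erf
   curve with floor `Emin`, plateau `Emax`, half-maximal concentration
   `K` (µM) and log-width `n`:

   Y = Emin + (Emax − Emin) · (1 + erf(log10(c/K)/n)) / 2

   fitted by multi-start nonlinear least squares (a `literal`
   convention, Y = Emin + (Emax − Emin)·erf(log10(c/K)/n), is also
   available). `compareK()` turns two fits into a fold ratio of
   half-maximal concentrations with a log-scale standard error.
   `logFoldChange()` provides the companion statistic for replicate
   sporulation efficiencies: a geometric-mean fold change with
   logarithmic standard error, geometric ±1 SE interval and Welch
   t-test.

Every input the pipeline consumes can be simulated with known ground
truth (`simulateMosaicAlignment()`, `simulateDoseResponse()`,
`simulateEfficiencies()`), so all claims are testable end to end.

## Worked example

```r
library(mosaicscan)

## a 24-strain locus whose appA+appB segment (2800-5300 bp) was
## acquired from a divergent donor with two alleles
sim <- simulateMosaicAlignment(nStrains = 24, donorDivergence = 0.3,
                               seed = 101)
res <- scanAlignment(sim$alignment, sim$speciesTree)

res$call$regions
#>   region      status startBp endBp nSegments
#> 1      1   congruent       0  2900         1
#> 2      2 incongruent    2450  5700         6
#> 3      3       mixed    5250  5800         1
res$call$breakpoints
#> [1] 2625 5525
res$alleles
#> AlleleAssignment: 2 cluster(s) over 24 strains in [2950, 5200) bp
#> (gap statistic 2.5)
```

The scan calls exactly one incongruent region (region bounds quote the
outermost windows of their segments, which overlap by width − step, and
a transition zone can be called mixed); the flag-transition breakpoints
(2625, 5525) bracket the true transfer boundaries (2800, 5300) to
within half a window, and the strains inside the region core split into
the two simulated donor alleles.

```r
## dose-response: the Opp permease importing hepta-PapR
m <- doseResponseModel(Emin = 1, Emax = 109, K = 1.5)
dat <- simulateDoseResponse(m, doseDesign(1.5), replicates = 3,
                            noiseCV = 0.1, seed = 1)
fitDoseResponse(dat)
#> Dose-response fit (halfmax convention)
#>   K = 1.547 uM (SE log10 K = 0.0842)
#>   Emax = 110.5 AU, Emin = 1.786 AU, n = 0.9842
#>   RSS = 105 over 8 concentrations

## sporulation efficiency fold change
g <- simulateEfficiencies(trueRatio = 30, log10SD = 0.2, nPerGroup = 4,
                          seed = 1)
logFoldChange(g$a, g$b)
#> Fold change 28.6 (21.2-38.6, geometric +/- 1 SE; se_log10 = 0.13)
#>   Welch t = 11.2, p = 9.44e-05 (n = 4, 4)
```

A single noisy experiment lands near the generating values (K = 1.5 µM,
Emax = 109 AU, ratio 30); across many replicate simulations the median
estimates converge to them (see the methods vignette,
`vignettes/mosaicscan-methods.Rmd`).

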