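# rna2array

Computational companion to the enzymatic conversion of DNA microarrays into
RNA microarrays. The wet-lab method turns any surface-bound DNA template
array into an RNA array in three steps: a 5′-psoralen 2′-*O*-methyl RNA
primer is hybridized to a shared primer-complement block on every template
and photocrosslinked under 365 nm light; T7 RNA polymerase extends the
crosslinked primer along the template's variable region; and DNase degrades
the DNA template, leaving single-stranded RNA tethered to the surface
through the crosslink and a short dT linker. `rna2array` implements
everything around that chemistry that is computation: designing convertible
template libraries, encoding images as arrays of template truncations,
planning maskless photolithographic synthesis, simulating scans, and
quantifying them.

It is written for array facilities and nucleic-acid labs that design
convertible DNA libraries (for ink-jet vendors or in-house maskless
photolithography) and analyze the resulting GenePix-style scans.

## The model in brief

Every transcribable probe reads, 5′→3′,

```
variable (template) region | revcomp(primer) | dT linker -> surface
```

so each extension product is `primer + revcomp(variable)` as RNA.
Untranscribable controls carry `revcomp(variable) + dT linker` — the RNA
product sequence as DNA — and hybridize the same labelled detection probe,
serving as ssDNA references. The quantification module implements the
published analysis recipe: replicate averaging, subtraction of the matched
control signal, normalization to the highest corrected signal, and the
ratio estimators

* conversion efficiency = mean(RNA signal) / mean(ssDNA reference signal),
* degradation residual = mean(treated) / mean(buffer),
* positional profile = corrected, normalized Cy3-rU intensity re-expressed
  relative to the surface-proximal (position 1) dA-walk variant,

each with a seeded bootstrap confidence interval. The scan simulator
provides the signal structure these estimators assume (saturating
duplex-length response `L/(K+L)`, surface-distance decay
`max(decay^(pos−1), plateau)` for incorporated labels, lognormal
multiplicative noise), so every estimator is testable end-to-end without
instrument data.

## Worked example

```r
library(rna2array)
tpl <- makeTemplate("TCAACCCAGGTCCAATTTCC", 5, defaultPrimer(), probeId = "green")
tpl
#> TemplateSpec 'green' (transcribable), dT5 linker, 40 nt
#>   5'-TCAACCCAGGTCCAATTTCCTTCGCCGTGTCCCTATTTTT-3'
```

The 20 nt green-channel variable region gains the 15 nt primer-complement
block and a dT5 linker (40 nt total). Its predicted extension product is
the psoralen-tethered primer plus the RNA complement of the variable
region — the sequence the Cy3-labelled detection probe recognizes:

```r
predictedProduct(tpl, defaultPrimer())
#> ChimericOligo, 35 nt in 2 segment(s) [5'psoralen / 3'none]
#>   [OMe] UAGGGACACGGCGAA
#>   [RNA] GGAAAUUGGACCUGGGUUGA
validateCrosslinkSite(tpl)[c("duplexLen", "pass")]
#> $duplexLen
#> [1] 15
#> $pass
#> [1] TRUE
```

A dA-walk experiment — 21 templates placing a single templated Cy3-rU at
every third extension position of a 61 nt product — can be simulated and
quantified in a few lines:

```r
dw  <- daWalkSeries()
lay <- replicateLayout(dw, 85, nCols = 60, seed = 1)
sc  <- simulateScan(lay, dw, simParams(cv = 0.2, seed = 1), list(armCy3Walk()))$cy3walk
pr  <- positionalProfile(sc, dw)
head(pr$profile, 3)
#>   position corrected normalized relative
#> 1        1     10150      1.000    1.000
#> 2        4      8926      0.879    0.879
#> 3        7      7855      0.774    0.774
pr$final20Mean
#> [1] 0.700
```

The profile decays with distance from the surface and levels off: the mean
relative intensity over the final 20 extension positions (here 0.70) is
the plateau diagnostic of predominantly full-length RNA synthesis.

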