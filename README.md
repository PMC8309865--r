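# flipim

Fuzzy logarithmic image processing: a one-parameter family of bounded
graylevel arithmetics for R.

## The problem

Digital images live on a bounded graylevel range `[0, D)`. Ordinary
arithmetic ignores the bound: adding two images, amplifying contrast or
accumulating filter responses routinely overflows the physical range and has
to be clipped, destroying information. Logarithmic image processing (LIP)
models fix this by redefining addition, subtraction and scalar
multiplication through a logarithmic isomorphism with the reals, so results
never leave the range. This matters most for images formed by transmitted or
absorbed light — X-ray, transmission microscopy, underexposed photographs —
where intensities combine multiplicatively, but the bounded algebra is
useful for any image pipeline that must avoid clipping.

Several such models coexist: the classical LIP of Jourlin–Pinoli, the
homomorphic model on the symmetric range (−1, 1), and the pseudo-LIP.
`flipim` implements the *FLIP* framework that unifies them: graylevels are
fuzzified to tones `v = g/D ∈ [0, 1)` and their addition is modeled as fuzzy
accumulation by the Hamacher T-conorm, whose additive generator

```
f_p(x) = (1 − x)/x                 p = 0
f_p(x) = log((p + (1 − p) x)/x)    p > 0
```

induces a continuum of LIP models indexed by the order `p ≥ 0`:

```
v1 ⊕p v2 = 1 − (1 − v1)(1 − v2) / (1 − (1 − p) v1 v2)     addition
α ⊗p v   = T⁻¹(α T(v)),   T(v) = f_p(1 − v)               amplification
v1 ⊖p v2 = (v1 − v2) / (1 + (1 − p) v1 v2 + (p − 2) v2)   subtraction
```

`p = 0`, `1`, `2` recover the pseudo-LIP, classical LIP and homomorphic
models exactly; every other `p` is a new model. On top of the algebra the
package implements four application procedures: dynamic-range-maximizing
enhancement (jointly optimizing the amplification factor α and the order p),
FLIP neighborhood averaging for noise reduction, FLIP Sobel/Laplacian edge
detection with Otsu binarization and Pratt figure-of-merit evaluation, and
weighted image blending — plus seeded synthetic-image generators (constant +
Gaussian noise, step edges, smooth textures) for all experiments.

## A worked example

```r
library(flipim)

flipAdd(0.5, 0.5, p = 1)    # classical LIP sum
#> [1] 0.75
flipAdd(0.5, 0.5, p = 10)   # sums grow with the model order
#> [1] 0.9230769

## an underexposed synthetic image: tones squeezed into [1/256, 0.35]
u <- underexposedImage(0.35, size = 64, seed = 7)
range(tones(u))
#> [1] 0.00390625 0.35000000

## jointly optimize the dynamic range over amplification and order
optimizeAlphaP(min(tones(u)), max(tones(u)))
#> DynamicRangeResult for tones [0.0039, 0.3500]
#>   joint optimum: DR = 0.98376 at alpha = 2.7053, p = 100
#>   classical (p = 1) optimum: DR = 0.94911 (ratio 1.0365)

e <- enhanceImage(u)        # applies alpha ⊗p v at the optimum
diff(range(tones(e)))
#> [1] 0.9837627
```

For this dark image a high-order model stretches the tone range to 0.984 —
3.7% wider than the best the classical LIP can do — with no clipping at
either end. Sweeping all (min, max) graylevel pairs of a 6-bit plane shows
how often that happens:

```r
drSweep(levels = 64, stride = 4)
#> FlipSweep: D = 64, stride 4, 120 (gmin, gmax) pairs
#>   improved by p > 1: 63.3% of pairs
#>   beat classical by any order: 100.0% of pairs
#>   DR increase over improved pairs: mean 8.46%, min 0.45%, max 43.54%
#>   DR increase over all pairs: mean 13.29%
```

About two thirds of graylevel configurations are best served by a model
order above 1, with a mean dynamic-range gain of ~8% over the classical
optimum; some order always at least matches it (p = 1 is in the grid).

Edge detection and filtering work the same way — see `flipSobel()`,
`flipLaplacian()`, `flipConvolve()`, `flipBlend()` and the
`*Experiment()` harnesses; `vignettes/flip-models.Rmd` walks through the
model and every tunable constant. A command-line front end for shell use
ships in `inst/scripts/flip.R`:

```sh
Rscript inst/scripts/flip.R enhance in.png out.png
Rscript inst/scripts/flip.R blend a.png b.png out.png --w1 .5 --w2 .5 --p 10
```

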