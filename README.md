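# fishloc

Where does an RNA live inside a bacterium — in the nucleoid, the
cytoplasm, or at the membrane? `fishloc` answers this question
quantitatively from single-cell RNA FISH microscopy of rod-shaped
bacteria such as *E. coli*. The inputs are 2-D grayscale images: a
phase-contrast channel that outlines the cells, a DAPI channel that
stains the nucleoid, and one or two fluorescent-probe channels carrying
the RNA signal. The outputs are per-cell localization scores and
population-level statistics.

## The statistic at the core

For each segmented cell, the top fraction `F_T` of pixels by intensity is
selected independently in the RNA channel and in the reference (DAPI)
channel. With `n_sel` selected reference pixels, the *observed overlap*
is `|sel_RNA ∩ sel_DAPI| / n_sel`; under a uniform null the *expected
overlap* equals `F_T`. The **threshold overlap score (TOS)** rescales
their ratio to `[-1, +1]`:

    TOS = 0                                          observed = expected
    TOS = observed/expected - 1                      observed < expected
    TOS = (observed/expected - 1) / (1/expected - 1) observed > expected

so −1 means no overlap with the nucleoid center (anticolocalization), 0
means chance-level overlap, and +1 maximal overlap. The default
`F_T = 0.1` is not arbitrary: `selected_fraction_power()` reproduces the
power calculation (two-sided one-sample proportion test, α = 0.05,
power = 0.8, 30 cells × 300 pixels, 30% detectable effect) that yields
F_T ≈ 0.089, rounded to 0.1. A *membrane TOS* applies the same score to
the second-outermost pixel layer of each cell after the outermost layer
is discarded (it suffers a point-spread "edge effect").

The package also implements the polymer scaling model that links RNA
length to nucleoid access: `Rg = a·N^ν` fitted by Levenberg–Marquardt
(`fit_power_law()`), sphere-diameter conversion `2√(5/3)·Rg`, and a
penetrance classification (RNAs with Rg below ≈80 Å enter the nucleoid
freely; above ≈114 Å they are excluded).

Because no raw micrographs are distributable, a synthetic scene
generator (`make_geometry()`, `render_channels()`) draws spherocylinder
cells with interior nucleoids, renders phase/DAPI/RNA channels under five
ground-truth localization modes (uniform, nucleoid-excluded,
nucleoid-enriched, membrane, polar) with PSF blur, Poisson/Gaussian
noise and channel offsets — so every pipeline stage is testable against
known truth.

## Worked example

```r
library(fishloc)
sc  <- simulate_scene(n_cells = 30, mode = "nucleoid_excluded", seed = 42)
res <- score_scene(sc$images, f_t = 0.1, sb_cutoff = 1.3)
head(res[, c("cell_id", "area", "aspect_ratio", "observed", "tos", "membrane_tos")], 3)
#>   cell_id area aspect_ratio observed tos membrane_tos
#> 1       1  586     3.153725        0  -1    0.5962733
#> 2       2  547     3.506705        0  -1    0.6001918
#> 3       3  559     2.833563        0  -1    0.5870442
summarize_tos(res$tos[res$included])
#>    n median_tos mean_tos sem sem_defined fraction_positive
#> 1 30         -1       -1   0        TRUE                 0
```

Every cell of this nucleoid-excluded scene scores TOS = −1: its
brightest RNA pixels never touch the DAPI top decile — the signature of
an mRNA shut out of the nucleoid. (The positive membrane TOS is real
too: signal confined to the cytoplasmic rim overlaps the membrane
layer.) The scaling model side:

```r
m <- rg_model(a = 3.66, nu = 0.50)
predict_rg(m, 102, digits = 1)     # 37.0 (Angstrom, a 102-nt sRNA)
sphere_diameter(predict_rg(m, 976), digits = 1)  # 295.2 (full-length reporter mRNA)
selected_fraction_power()          # 0.0897 -> rounds to F_T = 0.1
```

A small CLI wraps the same steps:
`fishloc simulate --n-cells 30 --mode membrane --seed 1 --out scene/`,
`fishloc score --scene scene/ --ft 0.1`, `fishloc rg predict --n 102`,
`fishloc ft`.

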