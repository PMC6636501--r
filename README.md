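# jclrrsr

Automatic brain-lesion segmentation from co-registered, skull-stripped
multisequence MR images by **joint constraints of low-rank representation
and sparse representation** (JCLRRSR).

## The problem and the model

Radiologists read several MR sequences (T1, T2, PD, FLAIR, ...) side by
side because each renders lesions with different contrast. This package
treats all brain tissue — white matter (WM), grey matter (GM) and
cerebrospinal fluid (CSF) — as *background* that can be represented over a
dictionary of normal-tissue patch features, and lesions as *abnormalities*
that cannot.

For every in-brain pixel `j`, the `ω × ω` neighborhoods from the `k`
sequences are flattened and stacked into a feature vector of length `kω²`,
giving a feature matrix `Y ∈ R^{kω² × M}`. A background dictionary
`D ∈ R^{kω² × S}` holds the features of `S` training pixels drawn 3:1:1
from WM, GM and CSF of a tissue-labelled normal reference image. The
decomposition solves the convex program

    min_{A,E}  ||A||_* + β ||A||_1 + α ||E||_{2,1}   s.t.   Y = D A + E

where `||·||_*` (nuclear norm) makes the coefficients low-rank — pixels of
a tissue live in a common subspace, capturing global structure — `||·||_1`
keeps each pixel's coding sparse and local, and the `ℓ2,1` norm (sum of
column norms of `E`) makes abnormality *column-sparse*: whole pixels are
either explained by the dictionary or flagged. With `β = 0` the model is
plain low-rank representation (LRR).

The program is solved by a **linearized alternating direction method with
adaptive penalty** (LADMAP): singular value thresholding for `A`,
element-wise soft thresholding for the auxiliary copy `U`, column-wise
`ℓ2,1` shrinkage for `E`, then multiplier ascent with a growing penalty.
The abnormality response of pixel `j` is `T(x_j) = ||e*_j||_2`; pixels with
`T` above a threshold (Otsu on the in-brain responses by default) form the
lesion mask, which is restricted to the brain and cleaned of specks.

Because the clinical datasets the method is usually evaluated on are
external accessions, the package ships a seeded multisequence brain-phantom
generator (nested-ellipse WM/GM/CSF geometry, per-sequence tissue intensity
profiles, partial-volume smoothing, Gaussian noise, planted lesion discs)
that exercises every stage without any download.

## Worked example

Segment the fixed tumor-like phantom preset (128 × 128, three sequences,
one large lesion) with a dictionary trained on a lesion-free reference
phantom:

```r
library(jclrrsr)

spec <- phantom_presets()$tumor_like
cfg  <- preset_run_settings("tumor_like")   # S = 300, omega = 5, alpha = 0.1, beta = 0.05
run  <- segment_phantom(spec, S = cfg$S, omega = cfg$omega,
                        alpha = cfg$alpha, beta = cfg$beta,
                        min_size = cfg$min_size)
print(run)
```

```
JCLRRSR run: 7468 pixels, S = 300, omega = 5, alpha = 0.1, beta = 0.05
  solver: 15 iterations, final rel. residual 8.42e-05
  threshold (otsu): 202.6; lesion pixels: 1035
  Dice vs truth: 0.8701
```

7468 in-brain pixels were scored; the Otsu threshold on the abnormality
response selected 1035 lesion pixels against 797 planted truth pixels,
giving a Dice overlap of 0.87. `run$response$scores` is the per-pixel
response image, `run$lesion$mask` the binary mask, and `run$fit` the full
solver trace. On real data, use `read_image()` + `normalize_intensity()` +
`sequence_stack()` to assemble the input, `sample_tissue_pixels()` +
`build_dictionary()` on a labelled normal reference, and
`segment_lesions()`; `inst/cli/jclrrsr.R` wraps the same chain as a
command line (`phantom`, `build-dict`, `segment`, `sweep`, `evaluate`).

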