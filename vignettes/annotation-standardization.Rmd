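---
title: "Standardizing X-ray body-part annotations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing X-ray body-part annotations: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrannotate)
```

## The problem

Radiographs extracted from a hospital PACS carry body-part descriptions in
the `Body Part Examined (0018,0015)` DICOM tag as free text. In practice
that text is a mixture of hospital abbreviations, German and Latin
clinical terms, laterality and view qualifiers, typographic variants — and
in a sizable fraction of images it is absent altogether. `xrannotate`
standardizes this annotation layer: raw terms are normalized onto a
compact SNOMED CT vocabulary, a convolutional classifier predicts the
examined (single-label) or visible (multi-label) body parts directly from
pixels, and the two annotation sources are fused at retrieval time.

## Vocabulary and hierarchy

The packaged vocabulary (`load_vocabulary()`) maps hospital abbreviations
to 33 SNOMED CT body-part concepts plus two sentinels: `UNKNOWN` (code
−1) for absent or unmappable descriptions, and `REPORT` (−2) for
documents mis-stored as radiographs (e.g. bone-density reports). The
source mapping table announces 36 body parts but yields 35 transcribable
rows; the package ships the 35 and records the discrepancy in
`load_vocabulary()$metadata` rather than inventing a row. Where companion
tables print conflicting codes for a handful of classes, the declared
mapping table is treated as canonical.

Each class carries a three-level path (`load_hierarchy()`): level 1 is
the broad body region (Cranium, Abdomen, Chest, Spine, Unknown, Upper
extremity, Lower Extremity), level 2 a sub-region (e.g. Hand, Pelvis),
and level 3 the leaf class itself. As typeset in the source table the
`REPORT` sentinel sits under `Unknown` at level 1 (path Unknown → Report
→ Report); the package follows that reading literally. Deeper levels
refine shallower ones — every level-2 label has exactly one level-1
parent — and `validate_hierarchy()` checks this refinement property plus
path coverage for any replacement tables a site might supply.

**Term normalization** is deterministic and exact: uppercase, punctuation
to spaces, whitespace collapsed, then laterality/view tokens (LINKS,
RECHTS, LEFT, RIGHT, BDS, AP, PA, LAT, SEITLICH, …) stripped from the
ends, followed by exact lookup against abbreviations, SNOMED preferred
names and a packaged synonym table. No fuzzy matching is performed: a
term either maps auditable-exactly or resolves to `UNKNOWN`. This makes
the mapping reproducible and reviewable, at the cost of missing
creative misspellings — which the classifier route is there to catch.

## The hierarchical loss

For one observation with binary leaf targets $y$ and predicted leaf
probabilities $p$, the per-level loss is the binary cross-entropy over
that level's $N_n$ labels,
$$lloss_n = -\sum_{c=1}^{N_n} y_{o,c}\, \log p_{o,c},$$
and the total loss is the weighted sum
$$J(\theta) = 0.4\, lloss_1 + 0.3\, lloss_2 + 0.3\, lloss_3 .$$
The weights (0.4, 0.3, 0.3) give slightly more influence to errors at
the broadest anatomical level; because they sum to one, equal per-level
losses pass through unchanged. A prediction that confuses a hand with a
finger keeps levels 1–2 correct and is charged only at level 3; one
that confuses a hand with an abdomen is charged at all three levels.

Two details are not fixed by the loss formula and are package decisions:

* **Leaf→level aggregation.** Coarse-label probabilities are the sums of
  member-leaf probabilities, clipped to [0, 1]; coarse targets are the
  logical OR of member indicators (`project_to_level()`). For the
  disjoint groups of a tree the sum preserves probability mass and is
  the simplest consistent choice. Whether the original networks used
  per-level output heads instead is unknowable from the description;
  projection keeps a single leaf head and derives the rest.
* **Numerical guards.** Probabilities are clamped to
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-7}$ before the
  logarithm, so a perfect prediction scores $\approx 10^{-7}$ rather
  than exactly 0 and an impossible one stays finite. Batch reduction is
  the arithmetic mean over observations; in multi-label mode the inner
  sum simply runs over all positive labels.

## Image ingestion

`read_image()` parses flat Part-10 explicit-VR little-endian DICOM files
(the variant the synthetic generator writes; sequences and compressed
transfer syntaxes are rejected with explicit errors). Absent tags stay
absent — nothing is imputed at the I/O layer. `headers_to_table()`
collects one CSV row per readable file and logs unreadable ones without
failing the batch.

**Polarity.** Inverted radiographs (light background) are normalized by
$v \mapsto max - v$, with $max$ the stored bit-depth ceiling when the
header declares it. The trigger is the `MONOCHROME1` photometric
interpretation; when that tag is absent, an image is deemed inverted if
the median of a 5%-wide border exceeds the global *mean* intensity. The
mean — not the median — is the reference because the border and global
medians tie exactly whenever background dominates the image area, which
is the common case for collimated films; the mean is pulled toward the
foreground and stays informative. Normalization updates the header, so
the operation is idempotent.

**PNG export** uses 8-bit min–max scaling (bit depth is a package
convention; the pipeline consumes relative contrast, not absolute
units), with constant images mapped to mid-gray 128 so the export is
total and deterministic.

## Preprocessing alternatives

Three preprocessing options beyond plain bilinear resizing are
implemented and composable (`preprocess` config / CLI):

* **Otsu background removal.** The threshold maximizes the between-class
  variance $var(T) = P_0(T)\,P_1(T)\,(m_0(T)-m_1(T))^2$ over a 256-bin
  histogram regardless of input bit depth (wider inputs are mapped
  linearly onto the grid); ties resolve to the smallest maximizing $T$.
  Pixels below $T$ are zeroed; foreground pixels are returned
  bit-identical.
* **Top/bottom-hat enhancement** adds the top-hat and subtracts the
  bottom-hat residual with a disc structuring element (default radius 15
  px at 224×224 — the upstream literature gives no parameters, so the
  default is sized to typical bone-detail scale and configurable). The
  output clip range is a parameter rather than the input maximum so that
  genuinely enhanced detail can exceed the input's brightest value.
* **Cartoon–texture decomposition** blends a Gaussian low-pass
  ($\sigma = 3$ by default) with the original according to the local
  total-variation reduction rate, with a soft ramp on [0.25, 0.5]; the
  decomposition is exactly additive (cartoon + texture = input). The
  exact algorithm of the prior art is not recoverable from its citation,
  so these defaults are declared, not inferred.

## Augmentation

`augmentation_config()` defaults encode the training protocol: dihedral
transform with probability 0.5; with probability 0.75 each, an extra
rotation of up to 10°, a zoom in [0.9, 1.1] with perspective warping of
corner magnitude 0.2, and a brightness/contrast change of maximal scale
0.2; plus an always-on random resize-crop with scale in [0.9, 1.0], and
random polarity inversion with probability 0.5. Geometric operations are
composed into a single homography and resampled bilinearly once. The
warp magnitude is interpreted as the maximal corner displacement
fraction, matching the convention of the augmentation framework the
protocol derives from. Per batch, transforms precede inversion, with
independent draws; everything is reproducible under a fixed seed.

**SMOTE.** Tail classes are oversampled by interpolating between a
random member and one of its $k$ nearest same-class neighbors
($x_{new} = x + u(x_{nn} - x)$, $u \sim U(0,1)$), originals retained.
Every class below the target count (default: the largest class) is
brought exactly to it, yielding the uniform distribution the protocol
aims for. Whether the original work ran SMOTE on pixels or on learned
embeddings is unstated; the package default is flattened 32×32 pixel
space, and any feature matrix (e.g. `predict(fit, x, type =
"embedding")`) can be passed instead.

## Training harness

The bundled backbone is a small 4-block CNN (3×3 convolutions, ReLU,
2×2 max-pooling after the first three blocks) with global average
pooling and a linear classifier, implemented in RcppArmadillo so the
full harness trains on a single CPU in seconds to minutes. The GAP head
is what makes class activation maps exact. Larger pretrained backbones
can replace it behind the same `predict()`-style embedding interface but
are deliberately not bundled.

Protocol defaults mirror the experiment setup: at most 50 epochs with
early stopping at patience 8 (best-validation-epoch weights returned),
batch 64, shuffling, stratified 5-fold grid-search cross-validation.
Choices the protocol leaves open, fixed here as package defaults: Adam
with learning rate from the grid {1e−3, 1e−4}; the early-stopping
validation set is one of the four training folds, rotating with the
evaluation fold; multi-label decisions threshold per-class sigmoid
probabilities at 0.5; grid search ranks configurations by mean
validation accuracy (the first-reported metric of the comparison
tables). Training is deterministic in the seed on fixed hardware.

Stratified splitting deals each class's shuffled members cyclically
across folds, guaranteeing per-class fold counts within one of
$n_{class}/k$; classes smaller than $k$ are assigned round-robin with a
warning.

## Evaluation

`compute_metrics()` reports accuracy plus macro-averaged precision,
recall and F1 with a per-class report (precision/recall/F1/support).
Macro averaging is the default because a long-tailed archive otherwise
hides tail-class failures inside the majority classes — the
characteristic pattern of high accuracy with much lower precision;
micro averaging is available by flag. Multi-label accuracy is subset
(exact-match) accuracy by default with Hamming accuracy behind a flag;
both conventions are labeled because the exact definition behind
published summary accuracies of this kind is generally not recoverable.
`confusion_counts()` gives per-class TP/FP/TN/FN (and the cross-class
table in single-label mode). `tsne_projection()` is an exact $O(n^2)$
t-SNE (perplexity-calibrated Gaussian affinities, early exaggeration,
momentum descent), seed-deterministic and intended for corpus-scale
inspection. `class_activation_map()` upsamples the classifier-weighted
final feature maps and min–max normalizes to [0, 1].

## Retrieval and annotation fusion

`build_index()` is an in-process stand-in for a search-engine index with
identical query semantics (and a JSON-lines export for external
engines): per image it stores the DL examined prediction, the DL visible
set, the normalized header class, and an optional embedding vector.
`keyword_search()` retrieves by class over one source; `cosine_search()`
ranks embeddings by cosine similarity with the study's two thresholds
(0.55 strict, 0.3 permissive) as defaults; `intersect_results()` fuses
two routes by intersection — ids wrongly retrieved by only one source
drop out, which is why DL∩header outperforms either source when their
error sets are disjoint. Ties order by ascending image id throughout, so
results are deterministic.

## The synthetic generator: scope and honesty

`generate_corpus()` emulates the *statistical* structure of a clinical
X-ray archive: a long-tailed (Zipf) class distribution; 13% of images
with no body-part header; non-blank headers drawn from a >100-form
non-standard surface vocabulary (abbreviations, German synonyms, case
variants, laterality suffixes) that normalizes back to truth unless a
corruption rate is set; ~70/30 CR/DX modality mix; and half of the
images stored with inverted polarity (`MONOCHROME1`). Visible label sets
are the examined class plus, at a configurable rate, an anatomically
adjacent structure from the same level-1 region. Each class draws a
distinct geometric motif (capsules for long bones, rib-like arcs, an
ellipse-with-orbits skull, vertebral stacks, …), so classes are
separable by construction.

What the generator does **not** emulate: photorealistic anatomy and
texture, pathology, implants, exposure artifacts, or inter-annotator
subjectivity. Passing the pipeline's tests therefore demonstrates
*mechanical correctness and parameter recovery under the stated
archive statistics* — that the loss, training loop, stratification,
normalization and fusion do what they claim on data whose ground truth
is known — not clinical-grade accuracy. Published accuracies on
restricted clinical datasets are neither reproducible nor claimed here.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale by
design: corpora of 100–1,000 images, 64-px phantoms, 32-px model
inputs, 8 training classes, up to 30 epochs. These sizes were chosen so
the full suite completes in minutes on one CPU while still exercising
every component end to end; all of them scale up through configuration
alone. Degenerate inputs are handled explicitly: constant images have
no Otsu threshold (error), constant images export as mid-gray PNGs,
single-member classes fall back to duplication in SMOTE (with a
warning) and to round-robin assignment in stratification.

## Known limitations

* The DICOM layer reads the flat explicit-VR little-endian subset it
  writes; clinical archives with compressed transfer syntaxes need a
  transcoding step upstream.
* Exact-match normalization will not catch unseen misspellings — by
  design; extend the synonym table or rely on the classifier route.
* The reference CNN is a testing-scale backbone; clinical-scale accuracy
  requires attaching a pretrained backbone through the embedding
  interface.
* The exact t-SNE is quadratic in sample count; subsample beyond a few
  thousand points.
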