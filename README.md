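# xrannotate

Standardized body-part annotation for X-ray DICOM archives.

Hospital picture archives accumulate millions of radiographs whose `Body
Part Examined (0018,0015)` headers are free text: the same anatomy appears
under dozens of spellings, abbreviations and languages, and a substantial
fraction of images carries no body-part description at all. That makes the
archive nearly unsearchable for secondary use. `xrannotate` is a toolkit
for fixing this at the annotation layer:

* **Vocabulary standardization** — a packaged mapping from heterogeneous
  hospital terms to a compact SNOMED CT body-part vocabulary (33 coded
  classes plus `UNKNOWN`/`REPORT` sentinels), with deterministic
  normalization of free-text header terms.
* **Hierarchical classification loss** — the vocabulary is organised in a
  three-level anatomical hierarchy (body region → sub-region → leaf). A
  classifier is trained with the weighted per-level binary cross-entropy

  $$J(\theta) = 0.4\,lloss_1 + 0.3\,lloss_2 + 0.3\,lloss_3,\qquad
    lloss_n = -\sum_{c=1}^{N_n} y_{o,c}\,\log p_{o,c},$$

  so that confusing a hand with a finger is penalized less than confusing
  a hand with an abdomen.
* **A complete training pipeline** — DICOM reading and header extraction,
  polarity normalization (inverted, light-background films), PNG export,
  the three preprocessing alternatives (Otsu background removal,
  top/bottom-hat contrast enhancement, cartoon–texture decomposition),
  training-time augmentation (random batch transforms, random inversion,
  SMOTE oversampling of tail classes), stratified 5-fold splitting, grid
  search, and a compiled CPU-scale reference CNN with a
  global-average-pooling head.
* **Evaluation and retrieval** — macro/micro metrics with per-class
  reports, multi-label confusion counts, t-SNE projections, class
  activation maps, and an annotation-fusion retrieval index where
  keyword hits from the deep-learning annotations and the original
  headers are intersected so that their disjoint error sets cancel.
* **A synthetic phantom generator** — class-specific geometric motifs
  with the statistical structure of a clinical archive (long-tailed
  classes, ~13% missing headers, a >100-term non-standard vocabulary,
  mixed CR/DX, half-inverted polarity), so every component is testable
  without restricted clinical data.

## Worked example

```r
library(xrannotate)
vocab <- load_vocabulary()
hier  <- load_hierarchy()

# heterogeneous header terms, as found in a PACS archive
normalize_term("Daumen links", vocab)$name
#> [1] "Thumb structure"
normalize_codes(c("THORAX LIEGEND", "hws", "", "XX-UNBEKANNT-3"), vocab)
#> [1]  51185008 122494005        -1        -1
expand_to_levels(76505004, hier)
#>            level1            level2            level3
#> "Upper extremity"            "Hand"           "Thumb"

# a 300-image synthetic corpus: generate, ingest, train, evaluate
dir <- file.path(tempdir(), "demo")
truth <- generate_corpus(synthetic_config(n = 300, seed = 42), dir)
ds <- load_corpus(dir)
fit <- train_classifier(list(x = ds$x, y = ds$y),
                        training_config(loss = "hierarchical",
                                        max_epochs = 15, seed = 42))
fit
#> Reference CNN ( examined task, hierarchical loss): 8 classes; best epoch 15
#> (val loss 0.4619, val accuracy 0.932)

pred <- predict(fit, ds$x, type = "class")
compute_metrics(as.character(ds$y), as.character(pred))
#> accuracy 0.940 | precision 0.833 | recall 0.839 | F1 0.830 (8 classes)
```

The first block shows the standardization layer: German terms, case
variants, laterality qualifiers and view positions all collapse onto
SNOMED codes, while blanks and unmappable tokens resolve to the `UNKNOWN`
sentinel (−1). The second block runs the full loop on synthetic phantoms —
write DICOMs, read them back, normalize polarity, train the hierarchical
classifier — and reports standard metrics (accuracy, macro precision,
recall and F1).

A command-line front end is installed with the package
(`<library>/xrannotate/exec/xrannotate`) with subcommands `vocab`,
`simulate`, `ingest`, `preprocess` and `search`.

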