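# readrsa

Model-based representational similarity analysis (RSA) of single-word
reading.

Two long-standing computational accounts of how readers turn spelling into
sound make different claims about neural coding. Distributed connectionist
models learn the orthography-to-phonology mapping in a feedforward network
whose hidden layer forms graded, non-symbolic word representations.
Dual-route models instead posit explicit symbolic machinery, in particular
a serial grapheme-phoneme correspondence (GPC) rule route. The two
accounts are hard to separate behaviorally, but they predict different
*representational geometries*: if stimuli are points in each model's
internal code, the matrix of pairwise dissimilarities between them is a
fingerprint that can be compared — via second-order (rank) correlation —
with the same fingerprint computed from multivoxel fMRI patterns, sphere
by sphere across the brain. `readrsa` implements that entire comparison
pipeline, plus the synthetic data needed to exercise and validate it end
to end:

- **Slot codes** (`lexicon_codec`): monosyllables segmented into
  onset/vowel/coda; binary orthographic vectors (105 units at the standard
  scale: 30 onset + 27 vowel + 48 coda, multi-letter graphemes activate
  their constituent letters too) and phonological vectors (61 units;
  compound phonemes such as /ps/ activate their constituents).
- **Feedforward reading network** (`ann_*`): 105-100-61 logistic network
  trained by online backpropagation (cross-entropy) for 400 epochs, with
  an external input to target phoneme units that ramps up with training as
  `g * e/(e+k) * ln(1+f)/ln(1+f_ref)` — a frequency-linked stand-in for a
  growing semantic contribution. Word representations are the hidden-layer
  activations.
- **GPC rule route** (`apply_gpc`, `gpc_representation`): serial
  left-to-right scan firing the largest matching grapheme's rule; a word's
  representation is the sparse binary vector of fired rules, optionally
  concatenated with one-hot orthographic/phonological lexicons
  (2,033 + 2,998 + 2,998 = 8,029 units at the standard scale).
- **RDMs** (`compute_rdm`, `rdm_spearman`, `rdm_partial_spearman`):
  correlation distance (1 − Pearson r) over z-scored stimulus features;
  rank-based second-order correlation; partial rank correlation for
  model-vs-model comparison:
  `(r_tm − r_tc r_mc) / sqrt((1 − r_tc²)(1 − r_mc²))` on ranks.
- **Searchlight RSA** (`searchlight_map`, `group_inference`): radius-3
  spheres (123 voxels at 3 mm isotropic) over a gray-matter mask, plain or
  partial Spearman per sphere; 6 mm FWHM smoothing, Fisher z, one-sample
  group t, voxelwise p < 0.001 with 234.9 mm³ cluster-extent thresholding.
- **Synthetic data** (`generate_lexicon`, `generate_nonwords`,
  `generate_beta_series`, `make_dataset`): Zipf-frequency artificial
  lexicons with a controlled exception-word fraction, nonword test sets
  with multiple acceptable pronunciations, rule tables derived by majority
  vote, and multi-subject beta-series volumes in which chosen regions
  carry a noisy linear embedding of a chosen model's features.
- **Pipeline** (`run_pipeline`, `readrsa_cli`): JSON-configured stages
  `simulate`, `train-models`, `rsa`, `report`, `all`
  (see `inst/cli/readrsa.R`).

## Worked example

```r
library(readrsa)
lex <- generate_lexicon(synth_lexicon_spec(n_words = 200, p_exception = 0.1, seed = 1))
X <- encode_lexicon(lex, "orthography"); P <- encode_lexicon(lex, "phonology")
cfg <- ann_config(n_input = ncol(X), n_output = ncol(P), seed = 101)
fit <- ann_train(initialize_model(cfg), X, P, frequencies(lex))
tail(fit$history$accuracy, 1)
#> [1] 1
hid <- hidden_representations(fit$model, X, P, frequencies(lex))
rules <- generate_rules(lex)
rdms <- list(orthography = compute_rdm(zscore_features(X)),
             phonology   = compute_rdm(zscore_features(P)),
             ann_hidden  = compute_rdm(zscore_features(hid)),
             gpc         = compute_rdm(zscore_features(gpc_representation(lex, rules))))
round(build_correlation_table(rdms, "spearman"), 2)
#>             orthography phonology ann_hidden  gpc
#> orthography        1.00      0.58       0.73 0.31
#> phonology          0.58      1.00       0.72 0.26
#> ann_hidden         0.73      0.72       1.00 0.21
#> gpc                0.31      0.26       0.21 1.00
```

The table is the model-comparison summary: the network's hidden layer sits
between orthography and phonology (0.73 / 0.72), and correlates only
moderately with the symbolic rule route (0.21), so the two models make
distinguishable predictions about neural dissimilarity structure. On this
200-word lexicon the trained network reads 100% of training words and 58%
of novel nonwords correctly under the Jaccard nearest-pronunciation
criterion (chance is far lower; every error is a plausible mispronunciation
scored against the full pronunciation pool).

Planting the hidden-layer geometry into synthetic beta volumes
(`generate_beta_series`, gain 2, 18 subjects) and running
`searchlight_map` + `group_inference` recovers the planted region as the
peak group-t cluster, and the partial analyses reproduce the directional
asymmetry: ANN-controlling-GPC stays strongly positive in-region while
GPC-controlling-ANN collapses toward zero (see the methods vignette for
what "toward" means quantitatively).

## Layout

- `R/`, `src/` — implementation (R surface, C++ kernels)
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/methods.Rmd` — the model, estimator and generator choices
- `inst/extdata/` — fixture slot schemes (TSV)
- `inst/cli/readrsa.R` — command-line wrapper
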