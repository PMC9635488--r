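---
title: "Comparing reading models against voxel patterns: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing reading models against voxel patterns: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(readrsa)
```

This vignette is the package's account of its own science: the models it
implements, the estimators it uses, what the synthetic-data generator does
and does not emulate, and the choices made where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## The question and the method

Connectionist and dual-route models of reading aloud both map orthography
to phonology, but through different intermediate representations: a
learned distributed hidden layer versus the activation pattern over
symbolic grapheme-phoneme correspondence (GPC) rules. Representational
similarity analysis makes the two comparable to each other and to fMRI:
every representation is reduced to a representational dissimilarity
matrix (RDM) — stimuli × stimuli, entry $1 - r_{ij}$ with $r$ the Pearson
correlation of the two stimuli's feature vectors — and RDMs are compared
by Spearman correlation of their upper triangles. In the searchlight
variant, a neural RDM is computed from the beta-series patterns inside a
radius-3 voxel sphere (123 voxels at 3 mm isotropic) around every
gray-matter voxel, and the resulting per-voxel correlation maps are
smoothed (6 mm FWHM), Fisher-transformed, and tested across subjects with
a one-sample t-test under voxelwise $p < 0.001$ and a 234.9 mm³
cluster-extent threshold. Model-unique contributions are assessed with
partial rank correlation: with $t, m, c$ the rank-transformed neural,
model and control distance vectors,
$$\rho_{tm\cdot c} = \frac{r_{tm} - r_{tc}r_{mc}}
  {\sqrt{(1-r_{tc}^2)(1-r_{mc}^2)}}.$$

## The feedforward reading network

Architecture and training follow the standard single-hidden-layer design:
105 binary orthographic inputs, 100 logistic hidden units, 61 logistic
phonological outputs, trained by online stochastic gradient descent for
400 passes over the word set, presentation order reshuffled each epoch,
weights initialized uniform on ±0.1. Where the source architecture family
leaves details open we chose: logistic activations, cross-entropy loss,
plain (unmomentumed) SGD with learning rate 0.1. The gradient computation
is verified against central finite differences in the test suite.

Output units whose target is 1 additionally receive an *external input*
$$e(w, \text{epoch}) = g\cdot\frac{\text{epoch}}{\text{epoch}+k}\cdot
  \frac{\ln(1+f_w)}{\ln(1+f_{\mathrm{ref}})},$$
a frequency-linked stand-in for the semantic contribution to phonology
that grows over reading development. Defaults: gain $g = 2$, half-life
$k = 100$ epochs, reference frequency $f_{\mathrm{ref}} = 10^5$ per
million. Two of these were design decisions worth recording:

- **Normalization of the compression.** Raw $\ln(1+f)$ with per-million
  units reaches ~12 for the most frequent words. Injected directly into a
  logistic pre-activation, that dominates every other input: the network
  can satisfy its training targets from the external push alone, stops
  learning the spelling-sound map, and loses nonword generalization
  almost entirely. Dividing by $\ln(1+f_{\mathrm{ref}})$ keeps the
  compressed frequency in $[0,1]$ while preserving its ordering, which is
  the only property the mechanism needs.
- **External input at test time.** It is applied during training and when
  extracting representations and accuracies, at its final-epoch
  magnitude, gated by the item's target vector. Note the hidden layer is
  upstream of the output layer, so hidden representations are unaffected
  by this choice; only output-based accuracy is.

Word reading is scored as exact match of the thresholded (≥ 0.5) output
to the target. Nonwords, which have no single correct pronunciation, are
scored two ways: the *Jaccard criterion* (the output must be strictly
closer, by Jaccard similarity, to one of the item's acceptable
pronunciation vectors than to every other vector in the test pool; ties
with a foreign vector count as errors) and the stricter *exact criterion*
(the output equals an acceptable vector). Jaccard of two empty vectors is
defined as 1 so that an all-zero output can never beat a target against
itself.

## The GPC rule route

A rule maps a grapheme (≥ 1 letters) to a phoneme within a position class
(onset/vowel/coda/any). Pronunciation is a serial left-to-right scan; at
each position the eligible rule with the longest matching grapheme fires
("largest to smallest" search) and the scan advances past it. Slot
eligibility follows the monosyllable template: onset-class rules cannot
fire after the vowel, coda-class rules cannot fire before it; among
equal-length matches a slot-specific rule beats "any" and the current
slot beats a later one. A word's representation is the binary indicator
vector of fired rules — the cascaded activation *magnitudes* of the full
interactive model are not described by our sources and are out of scope
(a `value` hook exists for graded codes). The optional lexical route adds
two one-hot blocks (orthographic and phonological lexicons); analyses
default to the GPC-only representation.

Rule tables are data, not code: they can be read from TSV or derived from
a lexicon by per-(grapheme, slot) majority vote, which on a fully regular
synthetic lexicon reproduces every pronunciation and on a lexicon with
planted exceptions fails on exactly the exception words — a property the
tests assert.

## RDM construction and comparison

Stimulus features are z-scored per column before the RDM is built
(zero-variance columns are dropped with a warning; for binary codes the
z-scored columns remain two-valued, so nothing is lost). Upper-triangle
vectorization excludes the diagonal, which is identically zero and would
otherwise inflate rank correlations. Ties receive average ranks. Two
special cases in the partial correlation are worth noting: a control
rank-identical to the *model* leaves the partial undefined (error); a
control rank-identical to the *target* exhausts the target's variance and
the partial is defined as 0. The model-RDM correlation table
(`build_correlation_table`) defaults to Pearson on the distance vectors
with a `method = "spearman"` switch, since our sources do not state which
generated their published table.

## Searchlight and group inference

The searchlight assumes a 3 mm isotropic grid (the sphere definition "123
voxels of 3×3×3 mm" implies one, even when acquisition was anisotropic).
Spheres truncated by the mask or volume edge are retained when they keep
at least 50% of the full sphere (configurable); smaller ones are skipped
and left missing. Per sphere, the pairwise pattern-correlation RDM is
compared with each requested model RDM; partial and plain analyses
requested together share the sphere RDM and its ranks, which is what
makes the multi-analysis sweep cheap.

Group inference smooths each subject map with a mask-aware separable
Gaussian ($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$; smoothing a constant
map returns it unchanged even at mask edges, and an impulse reproduces
the requested FWHM within 5%), then applies Fisher's $z = \mathrm{atanh}(\rho)$
(|ρ| clipped at $1-10^{-7}$), then the per-voxel one-sample t-test.
Zero-variance voxels are flagged and excluded rather than reported as
infinite t. The voxelwise threshold is two-sided by default (a one-sided
switch exists, since our sources are ambiguous); cluster reporting is
positive-only. Connectivity for clusters is faces+edges (18-neighbor) by
default, configurable to 6 or 26. The cluster-extent value (234.9 mm³) is
a configuration input: reproducing the Monte-Carlo extent calibration of
standard fMRI packages is out of scope.

## What the synthetic generator emulates — and does not

`generate_lexicon` draws monosyllables as onset+vowel+coda grapheme
combinations under the paper-scale synthetic schemes (30/27/48 grapheme
slots; 61 phoneme slots split 23/14/24 with compound codas /ps/, /ks/,
/ts/). The symbol inventories are synthetic, English-like
reconstructions: the published inventories are not redistributable, so
only the block structure and counts are matched. Choices a scientist
would want stated once:

- **Canonical mapping.** The grapheme-phoneme map is letter-faithful
  (b → /b/; multi-letter graphemes map to a same-named or
  constituent-named phoneme, e.g. ck → /k/), because natural
  orthographies are broadly consistent at the letter level. An arbitrary
  assignment would plant de-facto inconsistency far beyond the controlled
  exception fraction and make the generalization task unnaturally hard.
  Homophony between graphemes is allowed, as in real spelling systems.
- **Exceptions.** A fixed fraction of words (default 10%, exact count)
  receives a deviant vowel phoneme. Exceptions are kept a strict minority
  within every vowel grapheme so the majority-vote rule derivation always
  recovers the canonical map, and words whose spelling would be
  mis-segmented by the greedy parse are rejected at generation — the
  analogue of the stimulus selection controls used with real materials.
- **Frequencies.** Zipf-distributed (exponent 1) occurrences per million,
  computed as if the corpus were the top slice of a nominal 30,000-word
  vocabulary, so the most frequent word lands near $10^5$ per million.
  Frequency ranks are assigned by random permutation and re-permuted (up
  to 20 times, logged) until |r| between letter length and log frequency
  is below 0.15. Imageability and bigram/biphone frequency are not
  generated: no implemented model consumes them.
- **Nonwords** recombine graphemes *attested in the lexicon* into unseen
  spellings; acceptable pronunciations are the canonical mapping plus any
  exception-vowel alternative attested for that vowel grapheme.
- **Beta series.** Inside each planted region,
  $\beta_{sv} = \mathrm{gain}\cdot (ZW)_{sv}/\sqrt{k} + \varepsilon_{sv}$
  with $Z$ the z-scored source features, $W$ a per-subject Gaussian
  projection, and $\varepsilon \sim N(0, \sigma^2)$ (defaults gain 2,
  σ 1); outside, pure noise. A linear voxel embedding is exactly the
  structure RSA assumes and is invariant to the voxel basis, so this
  tests the method's own premise. Deliberately *not* simulated:
  hemodynamics, temporal autocorrelation, motion, physiological noise
  spectra. A green recovery test therefore establishes that the
  *estimator chain* recovers planted representational geometry — not that
  it would survive realistic fMRI noise structure.
- **Geometry.** Default grid 24³ voxels at 3 mm with an ellipsoidal
  gray-matter stand-in mask, semi-axes (9, 8, 7) voxels (~2,100 voxels):
  large enough to exercise sphere truncation at edges, small enough for
  minutes-scale tests.

## A known estimator property, found by the tests

The recovery experiment plants the trained network's hidden-layer
geometry into the volumes and asks, among other things, whether the GPC
RDM's partial correlation (controlling the network RDM) is zero in the
planted region. Strictly, it is not: the neural rank vector carries the
planted geometry only *attenuated* by noise, so partialling out the
noise-free control leaves a residual slice of that geometry, and since
the two model RDMs are themselves correlated (rank r ≈ 0.2), the partial
rho acquires a small positive expectation — about +0.03 at the default
gain, against an across-subject standard error of ~0.001 (the in-region
mean over 123 correlated centers and 18 subjects is an extremely precise
estimator). The same mechanism is well known in regression as incomplete
adjustment under covariate measurement error; under a pure-noise null the
partial estimator is unbiased, which the null-calibration test confirms.
The corresponding acceptance check, which demands |mean| ≤ 3 SE, is
therefore left honestly failing, with the directional asymmetry itself —
strong positive network-controlling-rules versus near-zero (but not
3-SE-zero) rules-controlling-network — fully reproduced. At
cluster-corrected significance thresholds and realistic signal gains the
asymmetry reads exactly like the qualitative published pattern.

## Numerical and degenerate-input policy

- Sphere with < 2 in-mask voxels, or any stimulus with a flat pattern in
  the sphere: center skipped (missing), counted and retrievable.
- All-tied neural distances: skipped (rank variance zero).
- |ρ| ≥ 1 before Fisher z: clipped to $1-10^{-7}$ with a warning.
- Non-finite training loss: training aborts with epoch and word index.
- RDM invariants (symmetry, zero diagonal, range [0, 2], finiteness) are
  asserted at construction.
- Determinism: every stochastic stage draws from a named substream of the
  top-level seed (`substream_seed`), so identical configs reproduce
  bit-identical lexicons, weights and volumes; epoch shuffling uses R's
  RNG and is reproducible through `set.seed`.

## Limitations

The network is single-route and feedforward: no attractor dynamics,
naming latencies, or semantic pathway beyond the frequency ramp. The rule
route is the GPC component only — no interactive activation, no letter or
visual feature layers. The NIfTI codec handles uncompressed single-file
NIfTI-1 with the datatypes this package writes; it is not a general
neuroimaging I/O layer. Cluster-extent calibration is taken as input, not
estimated. Synthetic lexicons are monosyllabic with at most one grapheme
per slot and no stress coding.
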