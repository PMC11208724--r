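---
title: "Activity-cliff-guided single-atom ligand optimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-cliff-guided single-atom ligand optimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative structure–activity relationship (QSAR) modelling assumes that
similar molecules have similar activities. Activity cliffs (ACs) are the
places where this assumption fails: pairs of near-identical ligands whose
potencies against the same target differ by an order of magnitude or more.
The sharpest cliffs are *matched molecular pair* (MMP) cliffs in which the
two ligands differ at exactly one atom — a single element swap worth ten- to
hundred-fold in potency. Cliffs are both the main source of QSAR prediction
error and, read the other way, a recipe for optimization: if the model can
tell *which* atom to change and *into what*, a low-activity anchor can be
moved across the cliff deliberately.

`cliffopt` implements a method that does both jobs with one model. A graph
neural encoder and a bioactivity predictor are trained jointly with a graph
*reconstruction* decoder; an adversarial perturbation of the molecular
embedding — the direction in representation space along which the
prediction is most unstable — is decoded into a posterior over "which atom,
which element", from which a single chemically valid substitution is
selected.

## Model

### Encoder and predictor

Molecules are heavy-atom graphs over a fixed 16-symbol element vocabulary
(`element_vocabulary()`). Atom features are a 29-dimensional block
(one-hot symbol, degree, formal charge, aromaticity, implicit-hydrogen
count); bonds carry order, conjugation and ring membership. The encoder is
an attentive message-passing network: `L = 2` rounds of neighborhood
attention followed by a GRU state update, in the style of attention-based
molecular fingerprint networks. The molecular embedding is the plain sum of
the atomic embeddings,

$$ f \;=\; \sum_{i=1}^{N_a} h_i^L , $$

which makes `f` permutation-invariant and — important for the decoder —
an *atomic aggregate* that can be decomposed back onto atoms.

The predictor `N(·,·)` is a two-slot feed-forward network on the
concatenation of two molecular embeddings. During training the first slot
always receives the clean embedding; the second receives either the clean
(`N(f,f)`, the actual activity prediction) or a perturbed one. Regression
predicts on the pActivity scale (`pIC50`/`pEC50`/`pKi`/`pKd`, i.e.
−log10 molar); classification emits a logit.

### The adversarial perturbation

A random Gaussian probe `r`, rescaled to the sphere of radius `epsilon`,
is applied to the second predictor slot, and the gradient of the squared
prediction discrepancy

$$ g \;=\; \nabla_r \, D\big(N(f,f),\, N(f,f+r)\big), \qquad
   D(x,y) = (x-y)^2 $$

is rescaled to norm `eta`: `d = eta * g / ||g||`. Minimizing
`D(N(f,f), N(f,f+d))` during training (the stabilization loss) makes the
predictor locally smooth around each molecule, which is precisely what
tempers cliff-induced error; the *vector* `d` doubles as the optimization
cue — it points along the direction in embedding space where the model's
opinion changes fastest.

Two choices here deserve comment.

* **Sphere versus ball.** The probe's norm constraint is read as "on the
  sphere" (exact radius `epsilon`) rather than "inside the ball", so the
  probe scale is deterministic given the seed.
* **Sign of `d`.** `D` is symmetric, so the gradient construction fixes
  only the *line* of `d`; its sign flips with the random probe. The
  optimization pipeline needs "forward = toward higher activity", so the
  selection code orients `d` by the sign of `N(f,f+d) − N(f,f)`
  (`orient_perturbation()`) before using `f + d` (forward) or `f − d`
  (reverse). `adversarial_perturbation()` itself returns the unoriented
  gradient-aligned vector, which is what the finite-difference direction
  tests verify.

### The reconstruction decoder

The decoder maps `{f + s·d, H}` (with `s ∈ {+1, 0, −1}`) back to per-atom
element probabilities in four stages:

1. **Decomposition.** `gamma = softmax_i ⟨f + s·d, h_i⟩` quantifies each
   atom's responsibility for the (possibly perturbed) molecular embedding.
2. **Molecule-to-atom.** Atom states start at `g_i = gamma_i (f + s·d) + h_i`
   and are refined `T = 1` times by an elu relationship layer plus a GRU.
3. **Atom-to-atom.** `L = 2` rounds of attention over bonded neighbors with
   separate directed-edge states, each round ending in a GRU update. A
   single-atom molecule has no neighborhood; its context vector is zero.
4. **Generation.** A 16-way softmax per atom; optionally (off by default) a
   bond head with a 4-way order softmax and sigmoid flags.

With `s = 0` the decoder reconstructs the input (`P_f(k|i)`); with
`s = ±1` it produces the optimization posterior (`P_{f±d}(k|i)`). The two
branches share every parameter, so zero perturbation reproduces the
reconstruction branch bit for bit — an identity the test suite asserts.

### Reconstruction loss

Atom-symbol reconstruction uses a weighted cross-entropy: atom `i` of
element `k` contributes `(1 − N_k/N_a) · (−log p̂_{i,k})`, down-weighting
abundant elements (carbon, typically) so the informative heteroatoms
dominate. We read the loss as a nonnegative weighted negative
log-likelihood; a literal reading of a leading minus sign in front of a
positive cross-entropy would produce an unbounded-below "loss", so the
standard orientation is used. Bond-feature reconstruction is implemented
(`include_bonds = TRUE`) but off by default: the optimizer only ever edits
atom symbols, and dropping the bond term roughly halves decoder cost.

### Selection of the substitution

From the two posteriors, the key atom and replacement element are chosen by
a maximum-posterior rule with a confidence threshold `P0`:

* the *confusable set* of atom `i` is `K_i = {k : P_f(k|i) ≥ P0}` — its own
  element plus anything the decoder systematically confuses with it;
* the key atom `i*` maximizes, over atoms, the best optimization confidence
  among elements *outside* `K_i`;
* the replacement `k*` is the most confident element at `i*` with
  `P_{f+d}(k|i*) ≥ P0` and `k ≠` the original element; if none clears the
  threshold nothing is emitted.

`P0` defaults to 0.5 — "confident" in the literal sense of a majority of
the posterior mass; it is exposed in the configuration. Ties break toward
the lowest atom and symbol index for determinism. The catch-all `"other"`
class is never a legal replacement. A selected assignment still has to pass
the valence check below; invalid selections are penalized during training
by `−log(1 − P_{f+d}(k*|i*))` (a confidently proposed impossible element
costs more) and filtered at generation time, which is why the number of
generated molecules can be smaller than the number of anchors.

The printed form of the validity objective averages a summand that does not
depend on the summation index; we implement it as the single-term penalty
on the selected pair, and document that reading here.

### Training

The joint objective is

$$ L_{\mathrm{bio}} + \lambda_1 L_{\mathrm{afse}}
   + \lambda_2 (L_{\mathrm{recon}} + L_{\mathrm{val}}) $$

with `lambda1 = 0.6`, `lambda2 = 0.3` (the published balance), minimized by
Adam under a linear warm-up / linear cool-down schedule (the published
setting names warm-up and cool-down but not the shape; linear–linear is the
simplest realization). The inner maximization over the perturbation is
realized solely by the one-step gradient construction — there is no inner
ascent loop. The perturbation is detached: its value, not its gradient,
flows into the stabilization loss and the decoder. One fresh perturbation
is drawn per molecule per pass, both in training and at inference, always
from the run's seeded generator.

Per epoch the training-set *reconstruction rate* (fraction of molecules
with every atom's argmax correct) and *validity rate* (fraction of selected
substitutions passing the valence check, among molecules with a selection)
are recorded; the model kept is the epoch maximizing their sum (earliest on
ties). When no molecule has a selection the validity rate is not applicable
and is reported as `NA`; for the best-model score it contributes zero.

## Chemistry conventions

* Vocabulary: B, C, N, O, F, Si, P, S, Cl, As, Se, Br, Te, I, At and a
  catch-all `"other"`, with maximum valences
  {3, 4, 3, 2, 1, 4, 5, 6, 1, 5, 6, 1, 6, 1, 1, 4}.
* Explicit valence counts aromatic bonds as 1.5 and the validity check
  rounds *up* — deliberately conservative, at the price of refusing some
  legal five-ring heteroaromatic substitutions. The identity assignment is
  always valid.
* Aromatic ring positions additionally accept only aromatic-capable
  replacement elements (B, C, N, P, As): plain valence arithmetic would
  admit, e.g., sulfur at a benzene carbon, which no sanitizer accepts. The
  combined rule was validated against an independent toolkit: on >700
  random accepted substitutions, sanitization succeeded for every one.
* Formal charges are preserved through substitution; the check charges the
  budget by `|formal charge|` against the neutral-atom maximum valence, so
  chemically dubious charged anchors are simply rejected.
* Implicit hydrogens after substitution are recomputed from the *typical*
  neutral valence of the new element (S gets 1 H at a terminal site, not
  5); serialization lets the toolkit re-derive hydrogen counts, so
  canonical SMILES stay conventional.
* Stereochemistry is dropped on parse (no stage of the model uses it) and
  multi-fragment inputs are rejected. SMILES interpretation, aromaticity
  perception and canonicalization are delegated to OpenBabel/ChemmineR;
  the package never parses SMILES text itself.

## The synthetic study system

Real cliff-rich assay collections are large, proprietary-ish downloads;
the package instead ships a generator (`generate_fixture()`) whose defaults
define the study conditions used throughout the tests:

* 60 *paired* scaffolds — random C4–C10 alkyl chains or carbocycles with up
  to two methyl decorations and one marked substitution site — each emitted
  once with O and once with S at the site;
* a planted rule: activity = scaffold base (uniform 5–7) + element effect
  (O: +0, S: +2 log units) + Gaussian assay noise (0.2 log units), so every
  pair is a genuine 100-fold MMP-cliff and the ground-truth cliff list is
  known exactly;
* 80 *background* scaffolds emitted with a single variant each. Screening
  libraries are dominated by non-cliff ligands, and the background plays
  that role; it also matters structurally: under an optimization-mode
  activity-cliff split (cliff highs held out), the background is the only
  training exposure the decoder gets to the high-side element, without
  which no method could name it.

Scaffolds are deduplicated on the canonical form of their site-masked
skeleton. Because every non-site atom is carbon, an accidental
matched-pair between different scaffolds would have to align site with
site, which the dedup rules out — so the planted list is provably the
complete MMP set, and the miner can be tested for *exactness*.

What the fixture does **not** emulate: real pharmacophores and binding
chemistry, scaffold diversity beyond small alkyl/carbocyclic skeletons,
multi-site structure–activity interactions, heteroatoms outside the site,
assay heterogeneity, or activity distributions of real screening decks.
Passing the planted-rule tests shows the machinery — encoding, adversarial
perturbation, decoding, selection, validity filtering, mining, splitting,
matching — recovers a clean single-site signal at desk scale; it does not
certify performance on real GPCR data.

## Numerical choices

* `hidden_dim`: 64 by default; the shipped studies use 32, which is
  sufficient for the fixture and halves run time.
* `eta = 5`: on a trained fixture model the molecular embedding norm is
  ~12 and the displacement between the two sides of a planted pair is ~3.
  The perturbation must reach that scale — with `eta` an order of magnitude
  smaller, `f + d` never leaves the anchor's reconstruction basin and the
  optimizer emits (correctly, but uselessly) nothing. `eta` is the main
  user knob and should be recalibrated per dataset against the typical
  embedding distance between matched pairs.
* `epsilon = 0.01`: the probe only picks the linearization point; any small
  value on the smooth predictor works, and the direction test verifies the
  gradient at exactly this scale.
* `base_lr = 5e-3`, batch 32, 100 epochs default (the studies use 60 with
  the option of stopping early once the reconstruction rate crosses 0.95).
  At desk scale `1e-3` stalls: the reconstruction rate plateaus near 0.5
  (backbone carbons learned, site heteroatoms not) within a 100-epoch
  budget, while `5e-3` reaches a perfect training reconstruction rate by
  roughly epoch 20 — mirroring the training dynamics the method reports,
  where reconstruction climbs steadily toward 100% and validity dips before
  recovering.
* Probabilities inside logs are clamped at `1e-12`; a probe gradient with
  norm below `1e-12` is declared flat and yields a zero perturbation; exact
  ties in selection break toward the lowest index; a single-atom molecule
  skips the attention stage with a zero context vector.
* Problem sizes in the shipped tests and acceptance study: 200-molecule
  fixtures, 5 replicate seeds, 60–100 epochs, hidden width 16–32. These are
  the package's desk-scale choices; the generator itself scales to larger
  libraries.

## Known limitations

* One substitution per anchor per run: the selection rule produces a single
  `(i*, k*)`; iterative multi-step optimization is out of scope, as are
  bond edits, ring edits and fragment replacements — the decoder relabels a
  fixed skeleton and never changes connectivity.
* The forward/reverse orientation of the perturbation is a first-order
  heuristic on the predictor; for a molecule at a local optimum of the
  predictor the orientation is arbitrary (and the perturbation flat).
* Held-out generalization across a cliff split is measured on the cliff
  highs only; at fixture scale their activity spread (scaffold base ± assay
  noise) is narrow, so the r² of *any* predictor there is small and the
  comparison between training variants is correspondingly noisy. The
  discovery-rate comparison against the matched-budget random baseline is
  the sharper instrument at this scale.
* Cliff mining is exact but quadratic per candidate bucket; the prefilter
  (atom count and masked skeleton) keeps desk-scale libraries fast, but a
  million-molecule deck would need a real MMP index.
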