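---
title: "Methods: the D-MPNN model, its losses, and the choices behind them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the D-MPNN model, its losses, and the choices behind them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
directed message passing neural network (D-MPNN) for molecular and
reaction property prediction, the loss-function menu, the training
recipe, the uncertainty toolchain, and — importantly — the places where
the design was genuinely open and what was decided there. Nothing below
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. Featurization

A molecule enters as a SMILES string and becomes a directed multigraph
over its heavy atoms; hydrogens appear only as an atom-level count
feature. Atom feature vectors are ordered one-hot blocks — element,
degree (number of heavy-atom bonds), formal charge, chirality tag,
total hydrogen count, hybridization — followed by an aromaticity bit and
the atomic mass divided by 100 for scaling. Bond vectors carry a
null-bond bit (used only by reaction graphs), a bond-type one-hot
(single/double/triple/aromatic), conjugation and ring bits, and a
cis/trans stereo one-hot.

The one-hot vocabularies are a deliberate, documented choice
(`feature_config()`): elements B, C, N, O, F, Si, P, S, Cl, Br, I;
degrees 0–5; charges −2…+2; H counts 0–4; hybridizations sp/sp²/sp³.
Every block ends in an "other" slot, so out-of-vocabulary values encode
to a valid vector rather than raising — an oddball element costs
information, never a crash. With the defaults the atom width is 41 and
the bond width 12; a directed edge's feature vector is the concatenation
of its source atom's features and the bond features (width 53), so the
two directions of a bond differ only in the chosen first atom.

The package carries its own small SMILES front end (organic subset,
bracket atoms with charges/H-counts/isotopes/atom-maps, ring closures,
branches, aromatic lowercase atoms, `/`–`\` double-bond stereo and
`@`/`@@` tags). Perception is heuristic and documented rather than a
full cheminformatics stack: implicit hydrogens from standard valences
adjusted by charge; hybridization from the multiset of incident bond
orders; ring bonds as non-bridges (Tarjan low-link); conjugation as "a
single bond between two π atoms, or a multiple bond adjacent to another
π atom". Chirality one-hots use the parser-native `@`/`@@` tags as
written in the SMILES, a dialect choice: no attempt is made to convert
to R/S labels. These rules are exercised directly by the tests and
cross-checked for atom/bond counts against an independent toolkit; they
are not intended to reproduce every perception corner case of a full
toolkit, which is a known limitation for exotic chemistry (fused
heteroaromatics, hypervalent stereo centers).

### Reactions: the condensed graph of reaction

An atom-mapped reaction `reactants >> products` becomes a single
pseudomolecule whose atoms and bonds are the unions of the two sides,
keyed by map number. Feature combination is pluggable; the default
`reac_diff` mode concatenates the reactant-side features with the
product-minus-reactant difference. Two consequences drive this default:
an identity reaction has an all-zero difference block (a testable
contract), and bond formation/breaking appears as a signed difference on
the null-bond bit. Bonds present on only one side take the null-bond
encoding on the missing side; atoms present on one side impute the other
side's features from the present side ("balanced imputation"), again so
that no-change regions contribute exactly zero difference. Unmapped
atoms raise by default — silent mis-mapping corrupts training — with an
opt-in lenient mode that pairs leftovers by position.

## 2. The encoder

Hidden edge states start as h⁰ = τ(W_i eᵈ) and are updated by summing
the states of edges entering the source atom, excluding the edge's own
reverse twin (the defining trick of the D-MPNN; it stops messages from
echoing straight back). Two conventions needed fixing:

* **Update form.** The skip connection enters as
  h^{t+1} = τ(h⁰ + W_h Σ messages), i.e. the *activated* initial state
  is re-added at every step. This is the reference D-MPNN form.
* **Depth counting.** `depth = T` counts the initial state as step one,
  so T − 1 update iterations run. With `depth = 3` a message travels two
  bonds beyond its origin edge.

Atomic embeddings concatenate the raw atom features with the summed
incoming final edge states and pass through W_o; molecular embeddings
aggregate atoms by mean (default), sum, or sum divided by a user scaler
(`norm_scaler`, default 100 — the option's named constant; no canonical
default exists, so choose it per dataset if used). The readout FFN
(default two linear layers of width 300) shares the encoder's activation
and has biases on (the message-passing layers default to bias-free).
Dropout, when enabled, applies after every activation in both encoder
and FFN, is rescaled inverted-style, and is disabled at inference unless
Monte-Carlo dropout uncertainty is requested.

Multimolecule rows (e.g. solute + solvent) run one encoder per column —
or a single shared encoder with `mpn_shared` — and concatenate the
embeddings in column order before the FFN. This is deliberately *not*
permutation invariant across columns: the columns have roles. A reaction
column and a molecule column can be mixed freely since each column owns
its encoder (the reaction-plus-solvent layout).

Atom- and bond-level targets skip aggregation: each property gets its
own FFN over atomic embeddings (bond embeddings are the symmetrized sum
of a bond's two directed states — the unordered choice, since a bond
property must not depend on edge direction). The optional constraint
head computes per-atom attention weights from a learned score via a
within-molecule softmax and redistributes the residual c − Σ raw
proportionally, so the constrained predictions sum to c *exactly* (to
floating point); exactness of the sum is the contract, the weighting is
the pluggable part.

The whole forward pass and its reverse-mode gradients are hand-written
over dense/sparse matrices. Correctness rests on two independent checks
in the test suite: equivalence with a naive loop-based reference
implementation (to 1e-6 over random weights and molecules), and central
finite differences on every learnable tensor (relative error below 1e-4
at double precision).

## 3. Losses

Regression: MSE (targets standardized per task to zero mean/unit
variance on the training split; predictions unstandardized — the
round-trip is tested to 1e-10); bounded MSE for inequality-censored
targets like `">5.0"`, where a satisfied inequality contributes zero
loss, and a plain squared error is used for `=` targets (whether
satisfied equalities should also be clipped is undefined for an
equality, so they are not); Gaussian NLL for mean-variance (MVE) heads
with a softplus-positive variance; and evidential regression, a
normal-inverse-gamma NLL plus an evidence-weighted |error| regularizer
with weight λ (default 0.2, exposed — small enough not to distort the
mean fit, large enough to control evidence growth). Aleatoric and
epistemic variances come from the head as β/(α−1) and β/(ν(α−1)).
Atom/bond-level targets train in raw units: an affine standardization
would break the exactness of molecular sum constraints.

Classification: BCE (binary) and per-task softmax cross-entropy
(multiclass); a differentiable Matthews-correlation surrogate, 1 − MCC
of the *expected* confusion counts (TP = Σ p·y etc.) — implemented for
binary tasks; multiclass MCC is available only as a hard evaluation
metric (Gorodkin's R_K), a documented narrowing since no differentiable
multiclass form is canonical; and Dirichlet evidential classification
(softplus evidence, the mean-square form plus a KL regularizer toward
the uniform Dirichlet).

Spectra: intensities over fixed bins, with per-bin masks for exclusion
regions (instrument gaps, solvent windows) supplied as NA cells. The
model head is softplus-positive and normalized to sum one over *valid*
bins — chosen so that masking and normalization commute. Spectral
information divergence (SID) is the symmetric divergence
Σ p·ln(p/q) + q·ln(q/p) with both spectra floored at a threshold
(default 1e-8, configurable) after normalization; the Wasserstein loss
is the closed-form L1 distance between cumulative sums, in bin units.
Both are invariant to common positive rescaling of the target, and
masked bins provably receive zero gradient (asserted in tests). The
Wasserstein implementation is checked against an independent
northwest-corner transport oracle.

## 4. Training

Adam (β 0.9/0.999), batch size 50, 30 epochs by default. The learning
rate rises linearly from 1e-4 to 1e-3 across the warmup (two epochs,
measured in optimizer steps) and then decays exponentially,
parameterized to land on 1e-4 *exactly at the final step* — the
endpoints are the specification; the step-wise parameterization is the
package's choice. For runs too short to fit the default warmup the
warmup is clamped to half the run rather than erroring. Small datasets
genuinely need far more epochs than 30; the CLI prints a note to that
effect below 1000 rows.

Early stopping tracks the validation metric (RMSE for regression, AUROC
for binary, cross-entropy for multiclass, SID for spectra) with a
patience in epochs and restores the best checkpoint. Ensembles train
`ensemble_size` members that share the data split and differ only in
the weight/shuffle seed (member k uses seed + k − 1); ensemble
prediction is the member mean. Splits are random by default with a
scaffold option: Bemis–Murcko scaffolds are computed natively (prune
degree-1 atoms to fixed point, canonicalize the remainder by
Morgan-style label refinement) and whole scaffold groups are assigned
greedily to the emptiest partition, so molecules sharing a scaffold can
never straddle partitions. All randomness flows through seeds that are
function arguments; a fixed seed reproduces a fit bit for bit on one
device (multithreaded BLAS reductions are the documented caveat).

Transfer learning warm-starts from a fitted model or JSON checkpoint
(shape-checked against the new featurization; mismatches are explicit
errors). Freezing always includes the encoder weights and can extend to
the first k FFN layers; frozen tensors are simply excluded from the
Adam update, which makes the bit-identity contract trivial to audit.
Checkpoints are single JSON files (weights serialized as 17-significant-
digit strings, which round-trip doubles exactly) with the full spec,
scalers and featurization vocabulary, version-stamped.

Hyperparameter search is native random search over a user dictionary,
with an append-safe JSON-lines trial log so parallel workers can share
one log; targeted samplers (e.g. a Tree-structured Parzen Estimator
from an external optimizer) plug in through the `sampler` argument, and
the reported best is monotone in the number of trials.

## 5. Uncertainty

Estimation: ensemble variance (for ensembles of MVE heads, the law of
total variance — mean of member variances plus variance of member means
— an explicit choice where several combinations are defensible);
Monte-Carlo dropout across K passes (default 30); the MVE and
evidential heads directly (evidential total = aleatoric + epistemic by
default, components exposed); predicted probabilities for classifiers;
and a leave-one-out "round-robin" per-bin ensemble variance for
spectra.

Regression calibration: z-scaling multiplies variances by the mean
squared standardized residual (idempotent by construction); t-scaling
fits the same scalar by Student-t maximum likelihood with n − 1 degrees
of freedom, more robust for small calibration sets; CRUDE stores the
empirical distribution of standardized errors (intervals use its
linearly interpolated quantiles; the variance-like report uses its
second moment); MVE weighting reweights ensemble members' variance
estimates by held-out NLL over the simplex. Classification calibration:
Platt scaling as a logistic fit on the logit of the score — the
package fits slope and intercept, monotone whenever the slope is
positive, so ranking metrics are untouched — and isotonic regression
via `stats::isoreg`. Calibration never changes predicted means, and
fitting on fewer than 10 points is refused.

Evaluation: Gaussian NLL; Spearman correlation between uncertainty and
|error| (constant uncertainties are signaled as undefined rather than
returning a spurious number); ENCE over 10 equal-count bins (default;
no canonical bin count exists); and miscalibration area as the mean gap
between empirical and nominal central-interval coverage over a 1%–99%
grid.

## 6. The fixture generator, and what passing tests mean

`make_molecule_set()` samples a combinatorial grammar — random carbon
trees up to 10 heavy atoms with optional hydroxyl/ether oxygens and an
occasional double bond, plus benzenes with up to three short
substituents — capped at 12 heavy atoms so the full suite runs in
minutes on one CPU. Outputs are pairwise non-isomorphic (checked by
canonical hash) and byte-identical under a fixed seed. Targets have
stated closed forms: heavy-atom count (+ Gaussian noise, sd 0.1 by
default — small relative to the unit spacing of the true counts),
ring indicator, a three-way composition class, Gaussian-mixture spectra
whose band positions are functions of composition, per-atom degrees
(whose molecular sum, twice the bond count, doubles as an exact
constraint), and a heteroscedastic variant whose noise sd grows
linearly with molecule size (5% per heavy atom) for uncertainty tests —
heteroscedastic sets draw molecules with replacement from a unique
pool, modelling repeated measurements. Reaction fixtures are mapped
alkane identities, cleavages and bond-order changes with the changed-
bond count as target, plus a fully mapped Diels–Alder reaction whose
CGR (6 atoms, 6-bond union, 2 product-only bonds) is hand-enumerable.

These fixtures emulate the *computational* structure of real tasks —
graph-size signals, class structure, smooth spectra, size-dependent
noise — and none of their chemistry: no feasibility, no spectral
physics, no activity cliffs, and molecular diversity far below any real
screening library. Passing the learnability gates (beating the
mean-predictor baseline, RMSE below half an atom on counts, SID below
the uniform baseline) therefore demonstrates that the architecture,
gradients and training loop work end to end; it does not certify
predictive performance on real chemistry.

Problem sizes used by the shipped tests and acceptance script — 300
molecules for the default-size learnability run, 50 molecules × 10
renderings for order invariance, 20 molecules × 20 draws for the
oracle, n = 5000/10000 for the calibration simulations, 2000 rows for
the heteroscedastic MVE recovery — were chosen as the smallest sizes at
which the corresponding statistics are stable, and are stated here as
the package's reference configuration.

## 7. Numerical details and edge cases

Xavier-uniform initialization; ReLU kinks make finite-difference checks
slightly noisy, hence the 1e-4 relative tolerance at random (non-kink)
points. Softmax and softplus computations are max-shifted/clamped
against overflow; SID floors both spectra; degenerate inputs have
defined behavior: empty molecules refuse to aggregate, all-masked
spectra error, single-class calibration sets error, NaN losses abort
with a diagnostic pointing at the learning rate and targets. A
molecule with a single atom has no edges: its initial edge-state matrix
is empty, the incoming sum is the zero vector, and the atomic embedding
reduces to τ(W_o cat(x_v, 0)) — all paths are covered by tests.

## 8. Known limitations

Perception is heuristic (Section 1); no 3D information, conformers or
tautomer standardization; no aromatic *perception* from Kekulé input
(aromatic SMILES are honored as written); the soft-MCC loss is binary
only; TPE-style targeted hyperparameter sampling is an external hook,
not built in; and training is single-device (no GPU path), which bounds
practical hidden sizes well below what a tensor framework would allow —
adequate for the fixture scale and for small laboratory datasets,
not for million-compound screens.
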