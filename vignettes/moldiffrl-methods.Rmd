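---
title: "Methods: graph diffusion with Pareto-based multi-objective RL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph diffusion with Pareto-based multi-objective RL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moldiffrl)
```

This vignette describes the models implemented in `moldiffrl`, the
assumptions behind them, the tunable parameters, and the numerical and
design choices made where the design was genuinely open. It states no
empirical result that the test-suite or `scripts/acceptance.R` does not
itself compute.

## The molecular representation

A molecule is a tuple of `n` heavy atoms with 3D Cartesian coordinates in
Ångström, atom types over the six-element alphabet {C, N, O, F, S, Cl}, and
an `n x n x 8` edge-feature tensor: bond-type one-hot
(single/double/triple/aromatic), interatomic distance, mean bond-angle
cosine, conjugation flag and ring-membership flag. Hydrogens are implicit —
each heavy atom carries enough H to fill its valence — so validity is
checked on heavy-atom bond orders only: an atom is over-valent when its
(per-atom rounded) bond-order total exceeds `v_max` (C 4, N 3, O 2, F 1,
Cl 1; S defaults to 2 with a configurable override to 6, since divalent
sulfur covers the thioethers the fixture chemistry produces while
hypervalent S exists in real corpora).

Three interpretation choices deserve note:

* **Non-bonded pairs.** The distance channel is filled for *every* atom
  pair, bonded or not, because the bond-consistency loss needs `d_ij`
  everywhere; all other channels stay zero off the bond list.
* **Bond-angle cosine.** "Angle relative to neighbouring bonds" is ambiguous
  for atoms with more than two neighbours; we use the mean cosine over all
  adjacent bond pairs at both endpoints and flag this as an interpretation.
* **Aromaticity.** Parsed SMILES arrive kekulized from OpenBabel; a 5- or
  6-ring is re-perceived as aromatic when every ring atom either carries a
  double bond or is an N/O/S heteroatom. This simplified rule covers the
  benzene/pyridine/thiophene/furan-type rings in scope; aromatic bonds count
  1.5 toward valence with per-atom rounding.

Coordinates are centred at zero mean on ingestion, which makes translation
invariance of everything downstream trivial. Stereochemistry is out of
scope: canonical SMILES are emitted without chiral or cis/trans markers.

## Diffusion

The forward process corrupts coordinates with the closed-form Gaussian
`x_t = √ᾱ_t x_0 + √(1−ᾱ_t) ε` over `T = 1000` steps. The cumulative
schedule is squared-cosine (offset 0.008) with the implied per-step
variances clipped to `[1e-4, 0.02]`; the clipping reconciles the cosine
shape with the stated variance range, and at `T = 1000` the endpoints after
clipping are exactly `1e-4` and `0.02`. Categorical atom state is corrupted
by uniform resampling with probability `1 − ᾱ_t` — the Gaussian form is
only defined for coordinates, and uniform resampling is the simplest
discrete process consistent with gradual structural corruption.

Training minimizes `L_denoise + 0.1·L_bond + 0.5·L_valence`, where the
denoising term is the *mean* (not sum) squared error between true and
predicted noise (a documented constant — the mean keeps the loss scale
independent of molecule size), the bond term is the summed binary
cross-entropy between predicted bond probabilities and the indicator
`d_ij < 1.8 Å` (probabilities clamped at `1e-7`), and the valence term is
the squared hinge on each atom's predicted-bond row sum over `v_max`. The
printed form of the valence loss duplicates its summation symbols in the
source material; it is read as the row-sum hinge, and the closed-form unit
tests (`ln 2` for an uncommitted pair, `(5−4)² = 1` per over-valent carbon
row) pin that reading.

Sampling is deterministic DDIM (`η = 0`): at each kept step,
`x̂_0 = (x_t − √(1−ᾱ_t) ε̂)/√ᾱ_t`, then
`x_{t−1} = √ᾱ_{t−1} x̂_0 + √(1−ᾱ_{t−1}) ε̂`. The `α` in the printed update
is read as the cumulative `ᾱ` (standard DDIM). The sub-schedule is a
uniform stride from `T` to 0 (default 100 kept steps); with a denoiser that
predicts zero noise the trajectory reduces to
`x_{t−1} = √(ᾱ_{t−1}/ᾱ_t) x_t`, which the tests verify against hand
recursion, along with agreement between full and strided schedules at
shared timesteps. The final step decodes atom types by logit argmax and
bonds by thresholding `b̂_ij ≥ 0.5`.

## The equivariant denoiser

The denoiser is a message-passing network whose node features are built
exclusively from rotation-invariant inputs — atom one-hots, a 64-dim
sinusoidal timestep embedding, and distance-based edge weights
`exp(−d²/2s²)` with length scale `s = 2 Å` — and whose coordinate head
outputs `ε_i = Σ_j G_ij (x_i − x_j)` with invariant pair weights `G`.
Equivariance under rotation, invariance under translation (inputs are
centred) and permutation consistency therefore hold by construction and are
tested at `1e-5` over random molecules and rotations. Atom logits and the
symmetric bond-probability head (`σ` of an inner-product score plus a
learned affine function of `τ_bond − d_ij`) are invariant. The reference
configuration is 12 layers at hidden size 256 with conditioning at layers
{3, 6, 9, 12}; tests and smoke training use 2–3 layers at width 16–32 —
same architecture, smaller instance — so every property test finishes on
one CPU in seconds.

All trainable components run on a small in-package reverse-mode autodiff
tape over dense matrices (`R/autodiff.R`), checked against central finite
differences. Dense `n x n` algebra is the right regime for molecules of a
few dozen atoms.

## Property conditioning

Continuous targets (QED, SA, logP, MW) are z-scored against
training-corpus statistics before sinusoidal encoding — the encoding is
scale-sensitive, so standardization keeps all properties in a comparable
band; the statistics are stored with the checkpoint. Discrete targets use
learned embedding tables over their vocabularies (ring count 0–6, aromatic
rings 0–4, HBD 0–5, HBA 0–10; out-of-vocabulary values are clamped with a
warning). Each 64-dim encoding is projected to the 256-dim model space and
tagged with a learned per-property *type embedding* instead of a positional
encoding — the source design is silent on token identity, and type
embeddings make the 4-layer, 8-head self-attention encoder insensitive to
the order in which targets are supplied (a tested invariant). A learned
null token expresses unconditioned generation through the same forward
pass. Cross-attention at the conditioned layers uses
`softmax(QKᵀ/√d_k)V` with queries from node features and keys/values from
the property context, followed by the sigmoid-gated convex fusion
`h′ = g ⊙ h + (1−g) ⊙ c`, `g = σ(W_g h)`. Zeroing `W_V` provably removes
all influence of the context values, which the tests use to confirm
conditioning flows only through the value pathway. Target achievement is
reported at ±5% relative tolerance.

## Multi-objective RL

Each generated batch is scored on the maximization-oriented objective
vector `(QED, −SA, Novelty)`, where per-molecule novelty is `1 − max
Tanimoto` over 2048-bit radius-2 circular fingerprints of the training
corpus (the batch-level novelty *metric* is exact canonical-SMILES set
membership; the two conventions coexist deliberately and are documented
side by side). NSGA-II non-dominated sorting assigns ranks; the reward is
`R_rank = 1 − (r−1)/(N−1)` — the alternative printed form `1 − r/|B|` is
noted but not used, as the implemented form yields the natural [0, 1]
endpoints — plus, in curriculum phase 3, the crowding-distance bonus
`0.1 · CD/max CD`. Classic NSGA-II gives boundary points infinite crowding
distance; because the bonus is normalized, boundaries instead get twice the
maximum finite interior distance (fronts of size ≤ 2 get uniform distance
1), keeping rewards inside `[0, 1.1]`. Invalid molecules receive reward 0
in every phase. A singleton batch gets reward 1.

The policy-gradient machinery needs a log-probability for what is otherwise
a deterministic DDIM action. The largest gap in the source design is that
it never defines one; here the denoiser is exposed as a Gaussian policy
over the predicted noise with fixed σ = 1 at the sampled DDIM steps, which
makes the PPO ratio well defined. A direct consequence: the policy entropy
is a constant, so the entropy bonus (coefficient 0.01) is reported but
contributes no gradient. Episodes are one molecule rollout with the Pareto
reward at the terminal step and zeros before it; advantages come from GAE
(γ = 0.99, λ = 0.95, terminal value 0) with per-minibatch advantage
normalization (documented choice), and K = 4 PPO epochs run per update with
the clipped surrogate (ε = 0.2). Replay-buffer samples enter only the
value loss, weighted by importance ratios clipped to [0.5, 2] and treated
as constant multipliers — the tests verify by parameter audit that buffer
samples produce exactly zero policy gradient. Buffer priorities are
`(1/rank)·novelty` (floored at 1e-8 to keep them positive), sampling is
without replacement with probabilities ∝ priority^0.6, and eviction removes
the lowest-priority entries with ties broken oldest-first.

Batch composition targets 70% new / 20% buffer / 10% training data. At
batch 128 the shares are rounded to 90/26/12: the new and buffer shares are
rounded to the nearest integer and the training share absorbs the residual,
which reproduces the published example (plain largest-remainder would give
the extra seat to the training share instead). Shortfalls in the buffer or
training pools are backfilled with new samples and logged.

The curriculum is phase 1 (epochs 1–20, QED only, no ranking), phase 2
(21–50, adds SA and novelty with Pareto ranking), phase 3 (51+, adds the
diversity bonus), with both learning rates (5e-4 diffusion, 1e-4 RL) halved
at each transition. `train_epoch` asserts finite losses and logs phase,
learning rates, batch composition, reward statistics, front size and buffer
occupancy as JSON-lines.

## Metrics

Pareto efficiency is `100 · |rank-1 front| / N` using the same sorter as
the reward path (a tested consistency). Hypervolume against a reference
point (default the origin, matching normalized objectives whose worst case
is 0) is computed exactly for up to three objectives by a slab sweep over
the third coordinate with a 2D staircase sweep inside, verified against
closed-form staircases and a Monte-Carlo oracle; more objectives fall back
to Monte-Carlo. The Fréchet distance
`‖μ_a−μ_b‖² + Tr(Σ_a+Σ_b−2(Σ_aΣ_b)^{1/2})` uses a symmetric eigenvalue
square root; it is "FCD-style" — generic over descriptor sets — because the
learned-network descriptors of the original metric are a trained external
artifact, out of scope here. Desirability is the geometric mean of
objectives min–max normalized against configured bounds (QED native, SA
mapped from [1, 10] and inverted, novelty native); a baseline-relative
normalization mode is not reproducible without the external baseline
system and is therefore not a default.

## The fixture generators and what they do (not) show

`gen_toy_molecules` emulates a drug-like corpus at desk scale: 5–15 heavy
atoms from valence-respecting templates (zig-zag chains with ether/amine
heteroatoms, aromatic six-rings with substituents, branched chains),
idealized geometry (1.54 Å C–C, 1.40 Å aromatic, 109.5°/120° angles) and
seeded jitter ≤ 0.05 Å. Template mixing induces property spread. It does
*not* reproduce real-corpus property marginals, molecular sizes (real
drug-like means are ~300 Da; the fixtures are far smaller, so QED-threshold
rates stay near zero by design), conformational flexibility, or charged and
hypervalent chemistry. Tests passing on fixtures therefore demonstrate
mechanistic correctness of every component, not benchmark-level generative
quality, which would require corpus-scale training far beyond one CPU.

`gen_objective_cloud` builds clouds with an exactly known frontier: the
frontier points lie on the simplex `x+y+z = c` (equal sums make them
mutually non-dominating) and every other point is a frontier point scaled
by a factor strictly inside (0, 1), hence strictly dominated. A 10,000-point
cloud with 421 frontier points measures Pareto efficiency 4.21% through the
real sorter; the construction is verified by brute force at 500 points.

## Problem sizes, seeds and known limitations

Smoke training uses a 2-layer width-16 denoiser, a 60-step schedule with 6
DDIM steps, batch 10, and a 12-molecule fixture corpus — sizes chosen so
the full test-suite (including a 200-step diffusion run and six RL epochs)
completes in a few minutes on one CPU. One integer seed controls
initialization, noise draws and data order; sub-seeds are derived
arithmetically, and all generators restore the caller's RNG state.

Observed limitation, measured rather than assumed: over a 5-epoch seeded
run the epoch-mean reward fluctuates with no visible trend — at these batch
sizes rollout sampling noise dominates any learning signal, so the tests
assert reward bounds and bookkeeping rather than a monotone reward trend.
The 200-step diffusion loss, by contrast, falls by more than an order of
magnitude with strictly decreasing 50-step block means, and that *is*
asserted. Other known limitations: no stereochemistry or tautomer handling,
simplified aromaticity perception, a surrogate QED/SA (the exact original
scoring functions depend on external fragment databases; the pluggable
backend contract is the boundary), and no latent-space diffusion or
classifier-free guidance.
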