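---
title: "Resource competition and gene expression noise: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource competition and gene expression noise: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcnoise)
```

## The system

`rcnoise` studies a deliberately minimal circuit: two identical,
independently regulated reporter genes (GFP and RFP) expressed in the same
cell through transcription, translation, and first-order degradation of
mRNAs and proteins. What makes the circuit interesting is that both genes
draw on the *same* finite pools of transcriptional (RNAP) and translational
(ribosome) machinery. When one gene momentarily grabs more ribosomes, fewer
remain for the other, so resource sharing installs hidden mutual-inhibition
links between otherwise unconnected genes — and these links reshape the
stochastic fluctuations of both reporters, not just their means.

Four resource modes are implemented as rate-law variants of the same
eight-reaction birth/death network:

* **unlimited** — transcription `k_m g_i`, translation `k_p m_i`: the
  idealised textbook model;
* **competitive** — saturating shared capacity: transcription
  `k_m g_i / (1 + (g_1 + g_2)/J_g)`, translation
  `k_p m_i / (1 + (m_1 + m_2)/J_p)`;
* **orthogonal** — dedicated pools per gene: the self-saturation remains
  (`k_p m_i / (1 + m_i/J_p)`), the cross-gene term is gone;
* **frozen_cross** — competitive, but the *opposing* mRNA inside each
  translation propensity is pinned to a constant (normally its stationary
  mean). This surgically removes the fluctuation channel between the genes
  while leaving the deterministic operating point untouched, and is the
  device used to isolate resource-competitive noise.

The saturating (Hill-type) sharing form is the simplest family satisfying
the constraints the analysis needs: infinite capacity recovers the
unlimited laws; finite capacity creates mutual inhibition; orthogonal pools
keep the constraint but cut the cross-links. Gene doses are deterministic
constants, so transcriptional sharing moves means only and all stochastic
cross-coupling enters through translation; consequently a protein's noise
has exactly three independent upstream sources (its own birth/death, its
own mRNA, the opposing mRNA).

## The noise decomposition

For the GFP protein the stationary squared coefficient of variation
decomposes exactly (within the linear noise approximation) as

$$
\eta_{\text{total}}^2
 = \underbrace{\frac{1}{\langle P_1\rangle}}_{\eta_p^2}
 + \underbrace{\frac{\sigma_{m_1}^2}{\langle m_1\rangle^2} H_{21}^2
   \frac{1/\tau_2}{1/\tau_1 + 1/\tau_2}}_{\eta_m^2}
 + \underbrace{\frac{\sigma_{m_2}^2}{\langle m_2\rangle^2} H_{23}^2
   \frac{1/\tau_2}{1/\tau_3 + 1/\tau_2}}_{\eta_{RC}^2},
$$

where `H2j = -∂ln f₁/∂ln m_j` are the static susceptibilities of the GFP
translation propensity, the lifetime ratios are the usual time-averaging
factors, and the mRNA variances come from the LNA (Poisson here). For the
shared-capacity law the susceptibilities are
`H21 = -(J_p + m₂*)/(J_p + m₁* + m₂*)` and
`H23 = m₂*/(J_p + m₁* + m₂*)`; as `J_p → ∞` they reach the
unlimited-resource values `(-1, 0)`. The sign convention is fixed by that
limit; only squares enter the decomposition. `decompose_noise()` returns
all terms, and the package's tests assert the closure
`η_p² + η_m² + η_RC² = CV²(P1)` against an independent Lyapunov solution to
1e-8 in all four modes (exact because the two mRNAs are independent
upstream sources).

The decomposition exposes the double-edged role of sharing: the resource
constraint *reduces* the own-mRNA term (|H21| < 1), while the cross term
η_RC² is a *new* noise source that vanishes only when sharing is removed.
Along a `J_p` sweep with fixed rate constants (`sweep_jp()`), η_RC² falls
monotonically, η_m² rises toward its unlimited value, and their sum passes
through an interior minimum.

## Default operating points

All rates are in an arbitrary time unit with the mRNA lifetime as the
scale: `d_m = 1`, `d_p = 0.1` (proteins live ten times longer), `g = 1` per
module. The base calibration targets mRNA mean 10 and protein mean 100 per
module with `J_p = 10` mRNA copies and `J_g = 20` dose units — strong but
not extreme sharing at desk-scale copy numbers; `match_means()` rescales
`k_m`, `k_p` per mode so every variant sits at the same means, which is
what makes noise comparisons across modes meaningful.

Two further presets matter:

* **strong competition** (`strong_competition_network()`): `J_p = 2`
  against mRNA means of 10 and high translational demand (`k_p = 100`,
  protein mean ≈ 909). This is the regime where the resource-competitive
  share of GFP noise is maximal (the share climbs with `k_p` and exceeds
  30%) and where the linear-noise theory predicts a reporter
  anticorrelation of about −0.8. Controller experiments default to this
  operating point, because a controller can only act on the propagated
  noise share, which is negligible at mild competition.
* **reduced regime** (`cme_regime_network()`): mRNA mean 3, protein mean 6,
  `d_p = 1`, `J_p = 3`. The truncated master equation is solved exactly
  here; caps of five times the mean (plus a small margin) keep the joint
  state space near 3e5 states with boundary mass below 1e-6. Protein means
  of 15–30 would be more comfortable visually but push the truncated space
  past a million states for no methodological gain; the full-scale regime
  is covered by the SSA and the LNA instead.

## Stochastic simulation and statistics

`simulate_ssa()` implements the exact Gillespie direct method in plain R
(copy numbers are tens to hundreds, so exactness is cheap at roughly 1e5
events per second). A trajectory is a step function, so all stationary
estimators in `stationary_statistics()` are *time*-weighted — means,
variances, and the Pearson correlation of the reporter pair — with Monte
Carlo standard errors from twenty non-overlapping batch means. Default
horizons are a burn-in of 50 protein lifetimes starting from the rounded
deterministic fixed point and a recording span of 2000 protein lifetimes;
both are arguments. Every simulation takes an explicit integer seed and is
reproducible by seed; ensembles (`ssa_ensemble()`) use consecutive seeds.

## Master equation

`build_generator()` assembles the sparse column-generator of the truncated
chemical master equation; reactions that would leave the truncation are
reflected (dropped), which preserves a proper stationary distribution, and
the post-hoc boundary mass is reported as the truncation diagnostic.
`stationary_distribution()` uses a direct sparse solve below 2e4 states and
uniformization power iterations (started from a product-Poisson guess at
the deterministic means) above, converging the residual `max|Qp|` below
1e-10. Increasing the caps by 50% moves the reported moments by well under
0.1%. Marginals and pairwise joints are exact sums; `fwhm()` interpolates
half-maximum crossings linearly between integer copy numbers and flags
multimodal inputs.

## Controllers

Three negative-feedback controller types are compared in four placements
(`M`/`P`: mRNA- or protein-mediated sensing; `X`/`L`: transcription or
translation as the inhibited step). All act through the same
non-cooperative repression factor `1/(1 + S_c E_i/K_e)` on the targeted
propensity of module *i*; they differ only in the effector `E_i`:

* **local** — `E_i = X_i`: each module represses itself;
* **global** — `E_i = X_1 + X_2`: one shared loop represses both modules;
* **NCR** (negatively competitive regulation) — each module expresses a
  sensor RNA `s_i` (production `α_s X_i`, degradation `d_s s_i`) and the
  sensors compete for a fixed pool of inhibitory CRISPR machinery; the
  quasi-steady-state self-inhibiting complex
  `c_i = D (s_i/K_b)/(1 + s_1/K_b + s_2/K_b)` is the effector.

The NCR partition is the interesting one: a rise in the *opposing* module
pulls machinery away from a module's own complex and releases its
repression, which anti-compensates resource stealing — the controller was
designed against resource competition, and this is how that design reads
in rate-law form. The explicit sensor species matters too: its birth/death
shot noise is injected into the loop, which is why translation-inhibiting
NCR placements amplify noise where there is little competitive noise to
cancel (low RFP dose) yet win where there is much (high RFP dose). The
sensor coupling `α_s` defaults to auto-scaling such that the module-1
sensor mean sits at the binding scale `K_b` — the half-occupancy point
where the machinery partition is most sensitive — so mRNA- and
protein-mediated sensors operate at comparable copy numbers. Defaults
`K_e = K_b = 10`, pool `D = 50`, strength grid 0–20.

Two conventions required a decision, both resolved in favour of fair
comparison at matched operating points:

* **Noise fold changes are computed at matched means.** A repression
  factor shrinks the protein mean, and `1/⟨P⟩` noise would then dominate
  any comparison: every controller would appear to amplify noise for the
  trivial reason that it represses expression. `normalized_noise()`
  therefore rescales the controlled network's rate constants
  (`rescale_to_means()`, exact in one pass because the repression factors
  depend only on the state) onto the uncontrolled fixed point before
  comparing coefficients of variation. `deterministic_dose_response()`
  deliberately does *not* rescale — the repression of the means is part of
  what that curve shows.
* **The sweep axis is the base-case RFP mean** at each gene dose, so all
  controllers at a dose are compared against the same reference.

The average noise reduction coefficient (`noise_reduction_coefficient()`)
is the grid mean of `1 − fold change of total system noise` (Pythagorean
sum of both reporters' CVs) over all active-controller cells of a dose ×
strength grid, the `S_c = 0` row serving as reference only. Negative
values mean net amplification.

## What the generator emulates — and what it does not

The stochastic simulator doubles as the package's synthetic-data source:
it produces exactly the statistical structure the analysis assumes —
Poissonian mRNA statistics, protein bursts filtered by lifetime ratios,
and translation propensities coupled through a finite shared capacity
(hence anticorrelated reporters). Real measurements contain in addition
extrinsic noise in the machinery pools themselves, transcriptional
bursting from promoter state switching, growth-rate feedback, cell-cycle
dilution, and fluorophore maturation delays — all deliberately outside
this model family. Passing tests therefore validate the method's internal
consistency and its predictions *within* this model class, not the claim
that a given in vivo circuit is described by it.

## Numerical choices

* Mean-field fixed points: closed form for base networks; controlled
  networks relax along the ODE flow (`deSolve::lsoda`) from the
  uncontrolled fixed point and finish with damped Newton to residual
  1e-10.
* Jacobians: analytic for base networks, central differences for
  controlled ones; Lyapunov equations are solved by Kronecker
  vectorisation (the largest system has six species) with residuals
  checked below 1e-10.
* Stability is verified (all Jacobian eigenvalues with negative real
  part) before any LNA quantity is reported; unstable cells in controller
  grids are flagged, not fatal.
* Problem sizes in the test-suite simulations (horizons of 2e3–4e4 time
  units, 25-point sweep grids, 4×4 controller grids) are chosen so the
  whole suite completes in a few minutes on one CPU; the estimators' Monte
  Carlo errors at those sizes are what the tolerances in the tests encode.

## Known limitations

* The LNA is a small-fluctuation expansion: at the reduced-copy regime its
  protein variance deviates from the exact master equation by a few
  percent (asserted < 10% in the tests), and mean-field means carry an
  O(1/N) bias under nonlinear sharing.
* The quasi-steady-state complex partition in the NCR controller assumes
  fast binding relative to sensor turnover; the SSA spot-checks in the
  test-suite bound the resulting discrepancy at the default parameters but
  a slow-binding NCR would need explicit complex species.
* Controller conclusions are parameter-regime statements (they default to
  the strong-competition preset); at mild competition the propagated noise
  share is small and all controllers are nearly inert on GFP noise.
* In this model family, protein-mediated placements are *not* uniformly
  worse than mRNA-mediated ones: proteins here are high-copy, low-CV
  moieties, so protein-sensing loops can be quite effective. Claims about
  the moiety ranking depend on the relative copy numbers and lifetimes of
  the two moieties and should not be read as universal.
* No extrinsic noise, bursting, growth feedback, delays, or spatial
  effects; no SBML interchange.
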