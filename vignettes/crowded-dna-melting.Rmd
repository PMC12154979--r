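---
title: "Modelling DNA melting in crowded solution with pbdmelt"
author: "pbdmelt maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA melting in crowded solution with pbdmelt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbdmelt)
```

## The model

pbdmelt computes thermal denaturation of double-stranded DNA with the
Peyrard–Bishop–Dauxois (PBD) lattice model. Each base pair $n$ carries one
stretching coordinate $y_n$ (Å), the transverse separation of the two
bases from their bound equilibrium. The configurational energy of an
$N$-pair duplex is

$$
E(y_1,\dots,y_N) \;=\; \sum_{n=1}^{N} D_n\!\left(e^{-a_n y_n}-1\right)^2
\;+\; \sum_{n=2}^{N} \frac{\kappa}{2}\,(y_n-y_{n-1})^2
\left[1+\rho\, e^{-b (y_n+y_{n-1})}\right].
$$

The Morse term models the hydrogen bond: depth $D_n$ and inverse width
$a_n$ depend only on the pair class (AT or GC). The stacking term couples
neighbours; its anharmonic factor stiffens the coupling by $(1+\rho)$
while both pairs are closed and relaxes to the bare spring $\kappa$ once
either opens, which is the mechanism that sharpens the melting transition
into a cooperative, entropy-driven event. The momentum sector is Gaussian
and integrates analytically; it adds exactly $k_B/2$ per base pair to the
specific heat and never moves the melting peak.

### Crowders

Inert macromolecular crowders (PEG-like) are not simulated explicitly.
A crowder parked at site $i$ restricts that pair's transverse fluctuation,
which the model represents as a local deepening of the Morse well,
$D_i = \alpha\, D_0$ with $\alpha > 1$. A `crowder_config` is a list of
(site, $\alpha$) assignments; several crowders may share a site, in which
case their factors combine multiplicatively by default
(`multiplicity_rule = "product"`). The product rule is a modelling choice:
doubly occupied sites should stabilise more than singly occupied ones, and
multiplicative depth scaling realises that ordering; a `"single"` collapse
rule is available for sensitivity checks. Through the nonlinear stacking
the local deepening also stiffens neighbouring sites, so a crowder's reach
extends slightly beyond its own base pair.

Counting placements of $k$ identical crowders on $N$ sites:
$\binom{N}{k}$ distinct-site placements (56 for three crowders on an
8-mer) or $\binom{N+k-1}{k}$ if sharing is allowed (120 for the same
case). `enumerate_crowder_configs()` exposes both, deterministically
ordered.

## Default parameters

| parameter | value | units | meaning |
|---|---|---|---|
| `D_AT`, `D_GC` | 0.0395, 0.059 | eV | Morse depth (2 vs 3 H-bonds) |
| `a_AT`, `a_GC` | 4.2, 6.3 | 1/Å | inverse well width |
| `kappa` | 0.03 | eV/Å² | stacking stiffness |
| `rho`, `b` | 2.0, 0.35 | –, 1/Å | stacking anharmonicity |
| `m` | 300 | amu | reduced pair mass |
| `y_min`, `y_max` | −5, 200 | Å | integration cutoffs |
| `n_grid` | 900 | – | Gauss–Legendre nodes |
| `y0` | 2.0 | Å | open/closed threshold |

The GC:AT depth ratio is 0.059/0.0395 ≈ 1.49, at the top of the 1.25–1.5
range usually quoted for the relative bond strengths. The threshold
$y_0 = 2$ Å sits inside the 1.5–2.2 Å band used across the melting
literature and coincides with where the mean separation
$\langle y\rangle(T)$ rises steeply through the transition; it is exposed
as a parameter. All parameters can be overridden from YAML/JSON via
`read_params()`, and every output file echoes the full set plus a config
hash so runs are reproducible from their own metadata.

## Numerics

**Partition function.** The configurational partition function on the
truncated domain $[y_{\min}, y_{\max}]$ is evaluated by transfer-integral
contraction: single-interval Gauss–Legendre nodes $y_i$ with weights
$w_i$, per-site factors $d_n(i) = w_i e^{-\beta V_n(y_i)}$, and the
stacking kernel $G_{ij} = e^{-\beta V_s(y_i, y_j)}$. Summing
$d_1 G d_2 G \cdots d_N$ left-to-right reproduces the full
tensor-product quadrature of $e^{-\beta E}$ exactly (verified against
explicit tensor sums to ~1e−16 relative for $N \le 3$), at cost
$O(N n^2)$ instead of $O(n^N)$. Each contraction step rescales by its
maximum and accumulates the log, so no overflow or underflow occurs
anywhere on a 100–540 K scan even for 300-bp chains. The kernel depends
on temperature but not on the sequence or the crowders, so placement
scans reuse one kernel per temperature — this is what makes the
exhaustive 56-placement scan cheap.

**Marginals and opening probabilities.** A forward/backward pass yields
every site's marginal mass on the grid in one sweep. The opening
probability $P_i(T) = Z_c(y_i \ge y_0)/Z_c$ is a masked column sum; the
open and closed restricted partition functions add to the full one
exactly because they partition the same grid. The open fraction is
$\phi = 1 - \theta$ with $\theta$ the mean intact probability over sites,
computed from the same threshold so $\phi \equiv \mathrm{mean}_i P_i$ to
machine precision. (An alternative bound-state-projector reading of the
intact fraction exists in the literature; the threshold estimator was
chosen so that $\phi$, the opening map and $\langle y\rangle$ are
mutually consistent by construction.)

**Thermodynamics.** The free energy per base pair is
$f(T) = -\tfrac{1}{2} k_B T \ln(2\pi m k_B T) - \tfrac{k_B T}{N}\ln Z_c$,
in reduced units (eV, Å, amu, K): unit constants inside the logarithm
contribute only terms linear in $T$ and $T\ln T$, invisible to
$C_v = -T\,\partial^2 f/\partial T^2$. $C_v$ uses a central second
difference with a 0.1 K stencil on exactly computed $f$; the melting
temperature is the $C_v$ peak, refined by a three-point parabolic fit,
with discrete ties broken toward lower temperature and an explicit error
if the peak touches the scan boundary. Scans are two-stage: 1 K coarse
bracketing, then 0.1 K refinement in a window around the peak.

**Known quadrature limitation.** The Morse wells are narrow (≈0.1–0.3 Å
of thermally relevant width) on a 205 Å interval, so single-interval
Gauss–Legendre at the default 900 nodes is *not* fully converged: the
acceptance suite measures that halving the node count moves an 8-mer's
melting temperature by a few kelvin, and further refinement continues to
lower it slightly. The default stays at 900 nodes because that
grid *defines* the reference computation this package reproduces;
composite panels concentrated near the well would converge faster and are
a natural extension. All cross-method validations (tensor quadrature, MC)
are run on a shared grid, so they test the contraction, not the
quadrature's convergence.

## Temperature scale of the defaults

With the printed default parameter set the 8-bp duplex GGGAGAAG melts
near 224 K uncrowded, near 262 K on average over the 56 three-crowder
placements at $\alpha = 1.5$ — roughly 40–80 K below the experimental
melting range of such oligomers. This is a property of the parameter set
on this integration domain, confirmed here by three mutually independent
routes (exact tensor quadrature, an external adaptive integrator, and
Metropolis MC), and no numerical convention we varied — node count,
finite-difference step, peak refinement, or a tighter upper cutoff —
comes close to bridging it. Users who need absolute agreement with a
specific experiment should calibrate $D$, $\kappa$ or the cutoffs to that
experiment; all *relative* statements the package is built to probe —
crowders stabilise, stabilisation grows with $\alpha$ and with occupancy,
placement matters, terminal-GC chains beat interior-AT chains, long
crowded chains melt in multiple stages — are robust to this overall
scale.

## The Monte Carlo oracle

`metropolis_sample()` is an independent check of the transfer-integral
machinery: single-site Metropolis sampling of $e^{-\beta E}$ on the same
truncated domain (out-of-domain proposals are rejected, which preserves
detailed balance with respect to the truncated measure the quadrature
integrates). Because collective unzipping is a rare event for local
moves, the proposal mixture includes uniform single-site redraws and a
rigid whole-chain translation; the translation changes both the Morse
terms and the anharmonic stacking factor, and its acceptance test uses
the full chain energy. Step sizes adapt only during the discarded 20%
burn-in; standard errors come from ≥20-block averaging. The acceptance
suite requires agreement with the transfer integral within 3 standard
errors for a 4-mer at temperatures below, just above, and well above its
transition. Near-coexistence temperatures, where both basins carry
comparable weight and dwell times are long, are the hardest regime; the
full-domain translation keeps basin exchange frequent enough for the
chain sizes tested here ($N \le 8$).

## Synthetic long-chain scenarios

The 50-, 100- and 300-bp scenarios place five crowders of graded strength
$\alpha = 5, 6, 7, 8, 9$ at fixed positions — (33, 36, 27, 15, 43),
(83, 86, 77, 15, 93) and (283, 286, 177, 115, 293) — giving crowded-site
fractions of 10%, 5% and ≈1.7%. The base-pair sequences underneath are
*synthetic*: seeded 50% GC random heteropolymers from
`generate_random_duplex()` (seed 2025, chosen once), because no published
sequence exists for these scenarios; the fixture files say so. With this
setup the specific heat develops two melting stages: the bulk of the
chain (first peak, ≈330–350 K) and, far above it, the dissociation of the
strongly crowded sites themselves (≈510–530 K for $\alpha = 5$–9 on the
default depths) — which is why the long-chain scans extend to 540 K. At
mid-transition a contiguous interior denaturation bubble of tens of base
pairs coexists with still-closed crowded sites. These are the features
the acceptance suite asserts; peak *heights* and exact positions depend
on the random sequence realisation and should not be read as predictions
for any specific natural sequence. The generator draws an exact GC count
without replacement, so the composition is deterministic and only the
arrangement varies with the seed — real genomic sequence features
(correlations, repeats, CpG structure) are deliberately absent, so
passing tests validate the crowding physics, not sequence realism.

## What a typical session looks like

```{r example, eval = FALSE}
chainA <- parse_duplex("GGGAGAAG")
profile <- melting_scan(chainA, crowder_config(c(2, 7, 8), alpha = 1.5))
profile$tm            # Cv-peak melting temperature
plot_melting(profile) # phi(T) with Tm marked

configs <- enumerate_crowder_configs(8, 3, alpha = 1.5)
scan <- scan_crowder_configs(chainA, configs, t_range = c(250, 350))
attr(scan, "mean_tm")
```

A command-line front end with `melt`, `scan-crowders`, `openmap`, `mc`
and `fixtures` subcommands ships in `inst/cli/pbdmelt.R`.

## Limitations

* Crowders are static depth modifiers: no diffusion, residence times, or
  excluded-volume geometry.
* No strand-dissociation equilibrium: for oligomers the model describes
  base-pair opening statistics, not the bimolecular duplex–coil
  equilibrium, so absolute oligomer melting temperatures are systematically
  model-bound (see the temperature-scale note above).
* One stacking parameter set for all steps; sequence enters only through
  the Morse term.
* Single-interval quadrature at the reference node count is a few kelvin
  away from full convergence (measured, documented above).
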