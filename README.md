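# pbdmelt — DNA melting in crowded solution

The interior of a cell is packed with macromolecules, and that crowding
changes how double-stranded DNA breathes and denatures. `pbdmelt` models
this with the Peyrard–Bishop–Dauxois (PBD) lattice Hamiltonian: each base
pair carries one stretching coordinate `y_n`, bound by a Morse potential

    V_M(y) = D (e^{-a y} - 1)^2

(depth `D` per pair class, AT or GC) and coupled to its neighbours by the
anharmonic stacking interaction

    V_s(y_n, y_{n-1}) = (κ/2)(y_n - y_{n-1})^2 [1 + ρ e^{-b(y_n + y_{n-1})}],

whose extra stiffness in the closed state makes melting sharp and
cooperative. An inert crowder parked at site *i* restricts that pair's
fluctuations, modelled as a local deepening of its Morse well,
`D_i = α·D0` with `α > 1`. The package answers questions like: how much
does a given crowder arrangement raise the melting temperature, which
base pairs open first, and how do sparse strong crowders reshape the
melting of long chains?

What it computes, all from the configurational partition function
evaluated by transfer-integral contraction on a Gauss–Legendre grid:

* free energy `f(T)`, specific heat `C_v(T)` and the melting temperature
  `Tm` (the `C_v` peak, parabolically refined) — `melting_scan()`;
* exhaustive `Tm` tables over every placement of *k* identical crowders —
  `enumerate_crowder_configs()` + `scan_crowder_configs()`;
* the fraction of open base pairs `φ(T)` (the UV-melting observable),
  per-site opening probabilities `P_i(T)` and mean separations
  `⟨y_i⟩(T)` — `fraction_open()`, `opening_map()`,
  `average_separation()`;
* an independent Metropolis Monte Carlo sampler of the same Hamiltonian
  for validation — `metropolis_sample()`;
* seeded synthetic long-chain scenarios (50/100/300 bp, five crowders of
  strength α = 5–9 at fixed sites) — `long_chain_scenario()`,
  `write_scenario_fixtures()`.

## A worked example

Three crowders (α = 1.5) on the 8-bp duplex `GGGAGAAG` ("G" = GC pair,
"A" = AT pair), placed at sites 2, 7 and 8:

```r
library(pbdmelt)
chainA  <- parse_duplex("GGGAGAAG")
profile <- melting_scan(chainA, crowder_config(c(2, 7, 8), alpha = 1.5),
                        t_range = c(200, 350))
profile
#> Melting profile of 'GGGAGAAG' (8 bp, 2:1.5,7:1.5,8:1.5)
#>   scan 200-350 K; Tm = 261.95 K (Cv peak)
#>   phi = 0.5 near 268 K
```

The crowder-free duplex melts at 224.0 K, so this arrangement stabilises
the duplex by ~38 K. Scanning every one of the 56 possible placements:

```r
configs <- enumerate_crowder_configs(8, 3, alpha = 1.5)
scan    <- scan_crowder_configs(chainA, configs, t_range = c(250, 350))
attr(scan, "mean_tm")
#> [1] 261.6545
range(scan$tm)
#> [1] 251.5124 268.6172
```

Every placement melts above the free duplex, end-loaded placements
(sites 1–3) stabilise most, and the 17 K spread shows how strongly
position matters. The `Tm` values here sit on an absolute scale ~40–80 K
below the experimental melting range of such oligomers — a documented
property of the standard parameter set on this integration domain (see
the vignette's "Temperature scale" section); all comparative statements
are robust to it.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/pbdmelt.R melt --seq GGGAGAAG --crowders 2:1.5,7:1.5,8:1.5 --out out/
Rscript inst/cli/pbdmelt.R scan-crowders --seq GGGAGAAG --k 3 --t-min 250 --t-max 350 --out out/
Rscript inst/cli/pbdmelt.R fixtures --out fixtures/
```

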