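---
title: "Modelling batch levan fermentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling batch levan fermentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levansim)
```

# The system

Levan is a fructose homopolysaccharide that *Bacillus subtilis* builds
*outside* the cell: the secreted enzyme levansucrase (SacB) attacks
sucrose and partitions it between **hydrolysis** (sucrose → glucose +
fructose) and **transfructosylation** (sucrose + growing chain → levan +
glucose, with free fructose acting as an additional acceptor). After the
sugar is exhausted the same enzyme degrades part of the accumulated
polymer back to fructose. Because the enzyme is growth-associated, the
whole process is a tug-of-war between biomass formation (which consumes
sucrose but produces the catalyst) and polymer synthesis (which needs
both sucrose and catalyst). The initial sucrose concentration sets where
this balance lands, which is why batches started at 100 g/L and 250 g/L
behave qualitatively differently.

`levansim` implements the full modelling chain for this system:

1. a seven-state kinetic ODE model of the batch reactor,
2. least-squares calibration against measured time courses with NRMSE
   validation and a ±50% sensitivity scan,
3. production summary metrics (maximum titre, rate, substrate-use
   efficiency),
4. a snapshot coupling of the kinetic model into a constraint-based
   stoichiometric model, solved by minimal-total-flux (parsimonious) FBA
   with flux-sum turnover analysis, and
5. three in-silico enhancement scenarios (enzyme-yield modulation,
   amino-acid supplementation, reaction knockdown).

# The kinetic model

States (internal units mM; biomass gDW/L; enzyme mg/L): biomass $X$,
levansucrase $E$, cumulative growth-consumed sucrose, glucose, fructose,
reactor sucrose $S$, and levan $L$ counted in fructosyl-monomer
equivalents (162.14 g/mol). The rates:

$$\mu = \mu_{max}\frac{S}{K_s + S}, \qquad
  v_1 = \frac{\mu X}{Y_{X/S}}, \qquad
  v_2 = \alpha\,\mu X$$

$$v_3 = \frac{v_{max,hyd}\,S}{K_{M,hyd}+S}, \qquad
  v_4 = \frac{v_{max,t1}\frac{S}{K_{M,t1}} + v_{max,t2}\frac{F\,S}{K_{M,t2}}}
             {1 + \frac{S}{K_{M,t1}} + \frac{F\,S}{K_{M,t2}}}, \qquad
  v_5 = H(t - t_{on})\,\frac{v_{max,deg}\,0.67L}{K_{M,deg}+0.67L}$$

$v_3$–$v_5$ are specific activities (mmol per mg enzyme per hour) and
act through the enzyme pool $E_{pool}=\alpha X$; growth is Monod with a
first-order death term; levansucrase is growth-associated with yield
$\alpha$ (mg/gDW). Levan degradation is gated by a Heaviside step at
$t_{on}$ and saturates on the *degradable* 67% of the polymer — the
remaining third is treated as structurally resistant, which is why
degradation slows but never formally stops at the 33% floor.

Two notational points in the published formulation required a decision:

* **Enzyme pool on hydrolysis.** The printed glucose/fructose/sucrose
  balances carry the $\alpha X$ factor on $v_4$ and $v_5$ but not on
  $v_3$, although $v_3$ has per-mg units. The default applies the pool
  uniformly to all three enzymatic rates; `equations = "as_printed"`
  reproduces the literal text for comparison.
* **Fructose non-conservation.** The printed fructose balance subtracts
  the *whole* transfructosylation rate, i.e. each levan unit formed also
  consumes one free fructose regardless of which term drives it. We
  implement this balance as printed. It has a structural consequence
  worth knowing: since only hydrolysis and degradation produce free
  fructose, non-negative fructose forces
  $\int v_4 \le \int v_3 + F$, so the molar levan yield can never exceed
  roughly half of the enzymatically consumed sucrose. Simulated maxima
  at high sucrose therefore sit near 50 g/L rather than the ~100 g/L a
  measured batch can reach; the model reproduces timing, shapes and
  ordering of conditions, not absolute high-sucrose titres.

## Parameters and presets

Three regime presets are shipped (`levan_presets()`), keyed to the
initial sucrose concentration via `select_regime()`:

| parameter | low (≤100 g/L) | transition (200) | high (≥250) | unit |
|---|---|---|---|---|
| $\mu_{max}$ | 0.2454 | 0.2454 | 0.1 | 1/h |
| $\alpha$ | 18.19 | 45 | 45 | mg/gDW |
| $v_{max,trans}$ | 6.42 | 6.42 | 6.42 | mmol/(mg h) |
| $Y_{X/S}$ | 0.020 | 0.015 | 0.012 | gDW/mmol |
| $t_{on}$ | 18 | 24 | 36 | h |

The first three rows are fitted values reported for this strain; the
transfructosylation maximum is shared across regimes (enzyme-activity
constants are held constant between conditions, only growth-side
parameters move). The remaining constants — $K_s$ = 5 mM, $k_d$ =
0.008/h, $v_{max,hyd}$ = 1.0 mmol/(mg h), $K_{M,hyd}$ = 30 mM,
$K_{M,t1}$ = 7000 mM, $K_{M,t2}$ = 5·10⁴ mM², $v_{max,deg}$ = 0.03
mmol/(mg h), $K_{M,deg}$ = 100 mM — are **not published** for this
system. They were chosen once, by forward simulation, so that the
presets reproduce the documented qualitative regime: hydrolysis-dominant
early conversion at low sucrose, fructose-mediated shift toward
transfructosylation as the batch progresses and as $\alpha$ rises,
sucrose depletion near 16–18 h at 100 g/L versus ~36 h at 250 g/L,
biomass maxima of order 1–3 gDW/L, and levan decline with fructose rise
after depletion. They are placeholders on the Table-scale, not fitted
constants, and downstream users calibrating against real data should
treat them as starting values. The onset times equal the observed times
of maximal levan per condition, which is where degradation becomes
visible in the data.

Between 100 and 250 g/L, `select_regime()` returns the fitted
transition set at exactly 200 g/L and linearly interpolates each
parameter otherwise; supplying a condition-specific fitted set always
takes precedence.

`X0` defaults to 0.05 gDW/L: the 2% (v/v) inoculum at OD₆₀₀ ≈ 0.6 is
not mapped to a dry weight in the source, so a small conventional
inoculum was fixed; it is configurable.

# Numerical choices

* **Integrator.** `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`.
  The Heaviside switch is handled exactly by splitting the integration
  at $t_{on}$, so the discontinuity never falls inside an adaptive step;
  an independent fixed-step RK4 oracle agrees to ~10⁻⁶ relative.
* **Negative undershoot.** Adaptive steps may transiently undershoot
  zero; rates are evaluated on clamped states and reported states are
  clipped at zero, with a warning when the undershoot exceeds 10⁻⁶ mM.
  Large undershoots are a property of the printed fructose balance under
  extreme parameters (e.g. halved hydrolysis capacity in the sensitivity
  scan), not a solver fault.
* **Calibration.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`)
  on log-transformed parameters (all strictly positive), objective =
  SSE over all species in measurement units, seeded multi-start
  (default 10 starts, log-normal jitter σ = 0.3). The default free set
  is {μ_max, K_s, k_d, Y_X/S, α, t_on} with the enzyme-activity
  constants held fixed, mirroring the per-condition estimation strategy;
  which parameters were free per condition is only partially documented,
  so this set is an interpretation and fully configurable.
* **NRMSE.** `100·RMSE/(max(obs) − min(obs))` per species; the
  normaliser is not defined in the source, so range-normalisation is
  the default with mean- and max-normalised variants selectable. The
  condition-level value is the unweighted mean over the five measured
  species.
* **Linear programming.** The minimal-total-flux problem (reversible
  reactions split into irreversible pairs, minimise total flux subject
  to $S\,v = 0$ and bounds) is solved by a package-internal dense
  two-phase primal simplex with Bland's anti-cycling rule. FBA
  instances here are small (tens of variables) but routinely degenerate
  (homogeneous right-hand sides, fluxes pinned at zero), which is
  exactly where naive pivoting rules cycle; Bland's rule guarantees
  termination. A brute-force vertex-enumeration oracle in the test
  suite checks optimality on the packaged network.
* **Degenerate optima.** Individual fluxes at the minimal-total-flux
  optimum need not be unique; reported flux-sums come from the returned
  vertex. On the packaged network the optimum is unique.

# The snapshot coupling

At a snapshot time (default 9 h, mid-exponential), three equalities link
the kinetic model to the stoichiometric one: biomass flux = Monod rate
$\mu$, sucrose uptake = $\mu/Y_{X/S}$, and levansucrase synthesis flux =
$\alpha\mu/MW$. Two conventions had to be fixed:

* The published linker is written as the specific biomass change
  $(1/X)\,dX/dt$, which equals $\mu - k_d$; we pass the Monod $\mu$
  itself, consistent with the uptake expression $v_1 = \mu X/Y_{X/S}$.
  The difference is $k_d$ = 0.008/h, well below the solver's working
  precision of interest.
* The enzyme-yield equality needs mg→mmol conversion; no molecular
  weight is published for the conversion, so a SacB-class 53,000
  mg/mmol is the default (`levansucrase_MW`, configurable).

Constraints are applied as fixed bounds (lb = ub), with a `relax`
option for feasibility diagnosis; on infeasibility each constraint is
probed alone and the binding one is named.

# The packaged stoichiometric network

Tests and default analyses run on a 13-reaction mass-balanced network
built in code (`generate_toy_gem()`), not on the published genome-scale
model (which is an optional, external input consumed through the same
SBML interface). The network deliberately mirrors the decision points
the scenarios need: a glucose-6-phosphate node branching into
glycolysis (PGI analogue) versus the oxidative pentose phosphate route
(G6PDH analogue, returning through a non-oxidative lump), respiration
plus an ATP-maintenance sink so energy always balances, an amino-acid
precursor with a closed supplement exchange, a biomass drain, and the
levansucrase-synthesis pseudo-reaction. PGI is reversible so the
irreversible-splitting code path is always exercised. The levansucrase
amino-acid/ATP cost is a uniform placeholder (2 aa + 1 ATP per mmol
protein) because the true residue-level stoichiometry of the secreted
protein is not published; `augment_levansucrase()` takes any
composition table. The network keeps an internal precursor-synthesis
route so the coupled baseline is feasible with the supplement exchange
closed; the designed precursor dependency is asserted by closing both
routes, which drives the maximal enzyme flux to zero. The fixture is
hash-pinned in the tests so scenario results stay stable.

# Scenarios

* **α sweep** (`run_alpha_perturbation()`): re-simulates the batch at
  enzyme yields {22.5, 45, 184.1} mg/gDW. Raising α suppresses maximal
  biomass, raises levan, and shifts the balance toward
  transfructosylation. The summary H/T statistic is the
  conversion-weighted time average $\int v_3 E\,dt / \int v_4 E\,dt$
  (cumulative hydrolysis over cumulative transfructosylation): the
  plain time average of the instantaneous ratio is dominated by the
  tail after sucrose exhaustion, where both rates vanish but their
  ratio stays finite, and carries no conversion meaning there. The
  instantaneous masked series remains available via `ht_ratio()`.
* **Supplementation** (`run_supplementation()`): maximise levansucrase
  synthesis with the growth equality relaxed to a floor (default 50% of
  the coupled μ — a floor is necessary because the unconstrained
  optimum is zero growth; the fraction is a package choice, the source
  does not state its implementation). Opening the precursor exchange
  raises the maximised enzyme flux; on the packaged network the fold
  change is ~1.4–1.5, qualitatively matching the published 1.342-fold
  threonine result whose exact value depends on the unpublished protein
  stoichiometry.
* **Knockdown** (`run_knockdown()`): cap a reaction (PGI analogue to
  0.006 mmol/(gDW h) in the headline experiment) and re-solve;
  per-reaction deltas are flagged increased/decreased/unchanged at the
  1e-6 activity threshold. On the packaged network flux redirects
  through the G6PDH branch, raising reducing-equivalent turnover.

# What the synthetic data do and do not show

`generate_timecourses()` samples regime-specific simulations on the
experimental grid (6–120 h) and applies mean-preserving multiplicative
lognormal noise (default CV 3%, the scale of the replicate standard
deviations in the production summary table; additive Gaussian
selectable) with a detection floor. It emulates sampling schedule,
magnitudes, and noise scale — not HPLC artefacts (retention drift,
co-elution), replicate-level covariance, or the absolute high-sucrose
levan titres excluded by the printed fructose balance (see above).
Passing calibration tests on these data therefore demonstrates that the
estimator recovers parameters of the model that generated the data at
realistic noise; it does not validate the model against real
measurements, and the reported experimental NRMSE values cannot be
recomputed here because the underlying time-course measurements are not
published in tabular form.

Problem sizes used by the test-suite and the acceptance script — 20
recovery replicates per regime at one condition each, 0.05 h
integration grids for conservation checks, the 13-reaction network for
all LP work — were chosen as the smallest sizes at which every check is
sharp (recovery medians sit near 1%, an order below their thresholds).

# Known limitations

* Batch operation only; no fed-batch or continuous feeding terms, no
  temperature or pH dependence, no intracellular glucose/fructose
  uptake (the printed model grows on sucrose alone).
* The coupling is snapshot-based, as in the source framework — there is
  no dynamic FBA time-stepping loop.
* The high-sucrose levan ceiling discussed above.
* No identifiability machinery beyond the ±50% perturbation scan.
* Levan quality (chain length, branching) and downstream recovery are
  out of scope.
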