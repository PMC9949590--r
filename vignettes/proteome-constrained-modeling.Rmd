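---
title: "Proteome-constrained metabolic modeling with pcfba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-constrained metabolic modeling with pcfba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcfba)
```

## The model

A proteome-constrained metabolic model extends an ordinary stoichiometric
(flux-balance) model with an explicit protein economy. On top of the usual
steady-state mass balances $S\,v = 0$ and flux bounds, the model carries

* one abundance variable $c_p$ (mmol gDW$^{-1}$) per protein, with a
  synthesis–dilution balance $s_p - \mu\,c_p = 0$ at growth rate $\mu$;
* a capacity coupling per catalyzed reaction direction,
  $v_r \le \sum_k 3600\,k_{cat,k}\,a_{k,r}$, where the allocations
  $a_{k,r}$ of a complex $k$ across its reactions sum into the subunit
  abundances ($\sum_{k,r} n_{p,k}\,a_{k,r} \le c_p$) — a shared enzyme can
  therefore be split freely over its reactions;
* a lumped translation machinery: synthesis drains amino acids
  ($L_p$ per protein) and ATP ($\approx 4.3$ per peptide bond), and total
  elongation is capped by the ribosome pseudo-protein,
  $\sum_p L_p\,s_p \le k_{el}\cdot 3600\cdot c_{ribo}$;
* the *unspecified protein* (UP), an artificial near-average-composition
  protein standing in for all metabolically inactive proteome, with a
  minimal mass fraction (0.22 g (g protein)$^{-1}$ by default);
* the proteome closure $\sum_p m_p\,c_p = P$ (total protein per dry
  weight, default 0.45 g gDW$^{-1}$), compartment proteome caps
  $\sum_{p \in X} m_p c_p \le \phi_X P$, and membrane-area caps for
  transporter classes;
* maintenance energetics: the growth-associated maintenance (GAM, mmol
  ATP per gDW of biomass, added to the biomass reaction) and the
  non-growth-associated maintenance (NGAM, a fixed hydrolysis flux).

At fixed $\mu$ every constraint is linear — $\mu$ enters only through the
dilution terms and the biomass flux bound — so feasibility is a single LP
and is monotone in $\mu$. `maximize_growth()` exploits this: it doubles an
upper seed until infeasible and bisects to `bisection_tolerance_mu`
(default $10^{-4}$ h$^{-1}$, matched to two-significant-digit growth-rate
reporting). Glucose limitation in a chemostat is emulated by scaling the
glucose transporter's effective turnover,
$k^*_{cat} = f_{sat}\times k_{cat}$; the growth maximum at a given
saturation *is* the dilution rate of that point.

## Inner objective (tie-break)

The growth maximum rarely pins a unique flux/proteome state, so
`solve_at_mu()` applies a lexicographic inner objective. The default
policy is **minimal functional proteome first, minimal
limiting-substrate uptake second**:

1. minimize $\sum_{p \ne UP} m_p c_p$ — the model then reports *minimal
   required* proteome fractions, with all slack proteome attributed to
   UP;
2. among proteome-minimal states, minimize uptake of the medium's
   declared limiting substrate.

The reverse order (`tie_break = "min_uptake_then_min_protein"`) is also
available and is the default inside `chemostat_sweep()` and
`fit_gam_to_fluxes()`: a glucose-limited steady state is defined by
substrate scarcity, so uptake minimization is the physiological reading
there. The order matters at glucose excess: because the proteome closure
means ballast protein is synthesized either way, minimizing uptake first
would always expand respiration to the mitochondrial capacity cap merely
to save substrate, and the mitochondrial constraint would appear
saturated at the growth maximum. With protein-first, batch growth is
fermentative (overflow metabolism), respiration stays at its useful
minimum, and only the cytosolic-capacity constraints remain limiting at
glucose excess — the behavior the framework is designed to reproduce.

A related subtlety is the difference between a *saturated* and a
*growth-limiting* constraint. A capacity can sit at its bound in the
reported solution without restricting the growth maximum.
`constraint_utilization()` reports attained/bound ratios (a constraint
with expression 1 is "active"); `limiting_constraints()` instead relaxes
each capacity by a few percent and tests whether a slightly larger growth
rate becomes feasible — the Fig.-1D-style regime classification in
`regime_label()` is built on the latter. After a bisection the certified
$\mu$ sits up to one tolerance below the true maximum, so activity
detection there uses a threshold scaled to
$\sim 8\,\mathrm{tol}_\mu/\mu$ rather than the raw $10^{-6}$ used at an
exactly specified $\mu$.

One more numerical tie-break: the UP's residues-per-mass ratio (396 aa at
44 kDa) is set marginally *below* that of the real proteins. The closure
equality forces ballast proteome to exist; if any real protein were
cheaper to synthesize per gram, the uptake-minimizing phase would park
the ballast there and inflate an arbitrary enzyme. With UP cheapest, both
phases agree that slack proteome is UP.

## The unspecified protein as the cytosolic capacity proxy

When UP sits at its floor, the closure turns into a hard cap on the total
functional proteome: investment in any protein comes at the expense of
another, across compartments. This minimal-UP constraint is therefore the
operative proxy for "cytosolic proteome capacity" at glucose excess, and
`regime_label()` counts it (together with the translation capacity and an
explicit cytosolic compartment cap, if binding) in the *cytosolic*
bucket. The explicit cytosolic compartment cap in the bundled profiles is
set generously (0.80 of protein) as a guard, so the UP floor is what
binds first at batch — mirroring the role the minimal-UP level plays in
fitting anaerobic maximal growth rates.

## The solver

The LP backend is a dense two-phase primal simplex compiled via Rcpp
(`solve_lp()`), with Dantzig pricing switching to Bland's rule after a
pivot budget to guarantee termination on the highly degenerate LPs that
flux models produce. For the bundled model sizes (a few hundred variables
and rows) it solves in single-digit milliseconds; its solutions are
checked in the test suite against an independent dense solver on random
LPs. `precision_refine` re-solves the final LP with tightened pivot
tolerances; exact rational re-solving is exposed only as this hook.

## The bundled toy network

`make_toy_yeast()` generates a miniature compartmentalized yeast-like
network (cytosol, mitochondrion, two membranes; 61 reactions, 36
proteins) whose lumped stoichiometries are integer-valued so closed-form
oracles exist:

* glycolysis: glucose $\to$ 2 DHAP $\to$ 2 pyruvate + 2 ATP + 2 NADH
  (the DHAP branch feeds the glycerol shunt);
* fermentation (pyruvate decarboxylase + alcohol dehydrogenase),
  aldehyde dehydrogenase, acetyl-CoA synthetase (ATP $\to$ AMP),
  adenylate kinase;
* pyruvate dehydrogenase, a lumped TCA step (acetyl-CoA $\to$ 2 CO$_2$ +
  3 NADH + FADH$_2$), an NADP-dependent variant, and oxidative
  phosphorylation at a configurable P/O ratio (default 1, FADH$_2$ at
  half);
* the three NAD(H) shuttles with an explicit mitochondrial proton
  species: the acetaldehyde–ethanol shuttle (mitochondrial alcohol
  dehydrogenase; export-only, its physiological direction), the
  malate–oxaloacetate shuttle whose oxaloacetate/H$^+$ symport imports
  one proton per cycle, and the glycerol-3-phosphate shuttle. The
  mitochondrial ATPase exports one proton per ATP hydrolyzed, so the
  malate route costs exactly 1 ATP per NADH and the ethanol route 0; a
  configurable proton leak of $h$ per ethanol-shuttle cycle raises its
  cost to exactly $h$;
* the carnitine shuttle plus CoA-transferase plus succinyl-CoA ligase:
  cytosolic acetyl-CoA can generate mitochondrial ATP at a cost of two
  cytosolic ATP equivalents each (the acetyl-CoA synthetase's ATP-to-AMP
  step);
* a lumped mitochondrial amino-acid synthesis consuming pyruvate, ATP
  and mitochondrial NADPH while releasing 0.5 NADH per amino acid into
  the mitochondrion — the biosynthetic redox burden that drives the
  anaerobic energetics; NADPH comes from the malic enzyme or, at a
  premium, from an ATP-dependent mitochondrial NADH kinase (the fallback
  that keeps the malic-enzyme deletion viable anaerobically);
* a biomass reaction (amino acids, carbohydrate and lipid precursors,
  GAM ATP) releasing a small cytosolic NADH surplus, aerobic and
  anaerobic lipid routes (the latter requiring three trace lipids, so
  anaerobic growth needs their supplementation), and exchanges.

Two glycerol routes resolve an ambiguity about the respiration-independent
shuttle: `GPD1` consumes *cytosolic* NADH (the always-available redox
valve) and `GPD2M` consumes *mitochondrial* NADH directly into the
glycerol-3-phosphate pool. The latter is why the mitochondrial alcohol
dehydrogenase deletion must be paired with the Gpd2 deletion in silico —
otherwise mitochondrial NADH escapes through it — while the Gpd1 valve
keeps the double mutant anaerobically feasible. Anaerobic glycerol
excretion then closes the cytosolic redox balance in closed form
(checked in the tests): per unit biomass the biomass surplus, plus per
amino acid one NADH from the withdrawn glycolytic pyruvate plus the
re-exported mitochondrial burden minus the NADPH-cycle drain, plus two
per anaerobically assembled lipid.

### Parameter choices (fixed once, toy scale)

The defaults in `toy_config()` define the bundled study conditions:
protein content 0.45 g gDW$^{-1}$ (mid-range of yeast measurements),
GAM 24 and NGAM 1 mmol gDW$^{-1}$ (h$^{-1}$), minimal UP 0.22 with the
anaerobic profile at 0.32 and GAM 40, membrane transporter area caps of
11.0/4.5 % (aerobic minimal), 13.0/5.5 % (aerobic rich) and 13.0/4.5 %
(anaerobic) for carbon/nitrogen transporters, default turnover 71
s$^{-1}$ with a 1 s$^{-1}$ floor, and an amino-acid mitochondrial NADH
burden of 0.5 mmol/mmol. Enzyme turnover numbers and the ribosome
elongation rate (3.5 aa s$^{-1}$) are deliberately *toy-scale* — slower
than physiological values — so that the proteome economy is already taut
at the small fluxes the lumped network carries. They were chosen once so
that the three growth-limiting regimes appear in order as glucose
availability rises (transporter area below $f_{sat}\approx 0.05$,
mitochondrial capacity through mid saturations, the cytosolic/UP budget
at glucose excess), with the critical dilution rate near 0.14 h$^{-1}$
and a batch maximum near 0.45 h$^{-1}$. The toy reproduces structure,
directions and exact stoichiometric ratios — not the absolute fluxes or
growth rates of a genome-scale model.

## Calibration procedures

* `fit_capacity_to_dcrit()` bisects a compartment-capacity scaling until
  the critical dilution rate (ethanol-excretion onset, threshold
  $10^{-3}$ mmol gDW$^{-1}$ h$^{-1}$, linearly interpolated; the
  estimator re-sweeps the onset bracket at finer saturation resolution)
  matches a target. This is the in-silico surrogate for over- and
  under-expressing the mitochondrial biogenesis program.
* `fit_gam_to_fluxes()` scores candidate GAM values by squared relative
  residuals of predicted vs observed exchange fluxes across dilution
  rates (chemostat mode, uptake-minimizing; observations below 0.01 in
  magnitude are compared on that floor to keep zero observations
  usable). The GAM is fitted on a grid — mirroring a discrete-choice
  calibration — with an optional continuous refinement.
* `fit_min_up()` bisects the minimal UP fraction until the predicted
  maximal growth rate matches a target; the maximum is non-increasing in
  the floor, which the routine asserts.
* `hap4_protocol()` chains them in the sequence used for
  respiration-deficient strains: capacity at the naive GAM, GAM against
  fluxes, capacity again at the fitted GAM, with the
  ethanol-per-glucose ratio at both GAM values reported as a diagnostic
  (it should be largely GAM-insensitive). Note that the one-pass
  sequence identifies the pair best when the flux data include
  sub-critical dilution rates, where the respiratory state does not
  touch the capacity cap and the maintenance parameter is identified
  independently of the still-mis-set capacity.

All three are deterministic given their inputs; the synthetic-data
generator (`make_synthetic_chemostat_data()`) applies multiplicative
lognormal noise of a stated coefficient of variation under a fixed seed,
and reproduces the model curve exactly at zero noise.

## What the toy does and does not show

Passing tests on the bundled network demonstrate that the construction,
solver, perturbation and calibration machinery behave correctly on a
model whose energetics are known in closed form, and that the qualitative
physiology — overflow metabolism, the regime sequence, the shuttle cost
asymmetry, the anaerobic amino-acid-burden story and its rescue by
supplementation — emerges from the constraint structure. They do not
validate absolute predictions for a real organism: that requires a
genome-scale reconstruction with curated turnover numbers and protein
properties, supplied through `read_gem()` (SBML L3+fbc subset or the
tabular dialect) and `read_protein_table()`.

## Worked example

```{r example}
toy <- make_toy_yeast()
pc <- toy_pc_model(toy, "aerobic_minimal")
med <- toy_medium(toy, "aerobic_minimal")

batch <- maximize_growth(pc, med)
batch
physiology(batch, toy$gem)

## the two shuttle energetics the network is built around
shuttle_cost(toy, "malate_oaa")
shuttle_cost(toy, "acetaldehyde_ethanol")
bypass_cost(toy)
```

```{r chemostat}
curve <- chemostat_sweep(pc, med, c(0.03, 0.08, 0.15, 0.4, 1.0))
curve
detect_dcrit(curve)
```

## Known limitations

* Translation is a lumped resource (no tRNA/mRNA species); protein
  import, folding and degradation are not modeled.
* Membrane caps use a single per-molecule area constant per transporter
  class; relative footprints are not identifiable from percentage caps
  alone.
* The UP occupies no compartment cap (only the closure and its own
  floor); whether the inactive proteome should count against a specific
  compartment is left to the user via the protein table.
* Flux distributions at the growth maximum are unique only up to the
  lexicographic policy; alternative optima may exist in degenerate
  directions.
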