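---
title: "Modeling canonical/non-canonical NF-kB crosstalk and BH3-mimetic response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling canonical/non-canonical NF-kB crosstalk and BH3-mimetic response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfcrosstalk)
```

## The biological question

Diffuse large B-cell lymphoma (DLBCL) cells in a lymph node are bathed in
CD40 ligand from T cells, which activates the *non-canonical* NF-kB pathway:
CD40 ligation stabilizes the kinase NIK, NIK drives processing of p100 to
p52, and RelB:p52 dimers enter the nucleus and induce the anti-apoptotic
protein BCLXL. Independently, chronic B-cell-receptor (BCR/BTK) signaling
drives *canonical* IKK activity, degrading the inhibitors IkB-alpha and
IkB-epsilon and freeing RelA:p50 and cRel:p50.

The two pathways are not independent. RelA activity induces p100, and p100
multimers act as a fourth inhibitor ("IkB-delta") that sequesters
cRel-containing dimers with higher affinity than RelA-containing ones.
NIK-dependent processing destroys the IkB-delta activity. A cell with high
basal canonical signaling therefore stores a large IkB-delta-bound cRel
reservoir; when CD40 arrives, NIK removes the reservoir's inhibitor and
*releases cRel*, which induces MCL1. A cell with low basal signaling keeps
cRel on IkB-alpha/-epsilon (which NIK cannot touch), so CD40 induces only
RelB/BCLXL. The same microenvironmental signal thus produces two different
anti-apoptotic escape routes - and two different drug-resistance phenotypes -
depending on the cell's basal state. This package implements that mechanism
as a testable kinetic model, together with the downstream viability logic
for BH3 mimetics and the quantification procedures used on the data side
(fingerprints, N:C ratios, TSS-window ChIP scores, robust outlier removal).

## The kinetic model

Sixteen species: free cytoplasmic and nuclear RelA:p50 (`A_cyt`, `A_nuc`)
and cRel:p50 (`C_cyt`, `C_nuc`); free IkB-alpha, IkB-epsilon and p100 (the
IkB-delta activity); the six inhibitor-dimer complexes; RelB sequestered by
p100 (`RelB_p100`); active nuclear RelB:p52 (`B_nuc`); and NIK. All mass
action, in minutes and arbitrary concentration units.

The inputs are:

* **Basal canonical activation** `b` in [0, 0.005] - the fraction of
  maximal IKK activity driven by constitutive BCR/BTK signaling. IKK
  degrades free and bound IkB-alpha/-epsilon at `d0 + d_ikk * b`, releasing
  the bound dimer. The endpoints of the range anchor the two cell states:
  `b = 0.0005` ("RIVA-like", low) and `b = 0.005` ("SUDHL8-like", high).
  The upstream BTK-to-NEMO cascade is deliberately collapsed into this one
  number; a BTK inhibitor scales it.
* **CD40 ligation** - stabilizes NIK by scaling its degradation rate with
  `1/(1 + t/600)`, `t` minutes since onset (so 1 at onset, 0.5 at 10 h,
  0.25 at 30 h). Time is read in minutes: 600 min places the half-maximal
  stabilization at 10 h, which makes NIK accumulation unfold on the 24-h
  co-culture horizon; seconds would compress it into biologically
  implausible minutes. NIK-dependent processing (`k_proc * NIK`) removes
  free p100, converts `Id_A`/`Id_C` complexes back to free dimer, and
  converts `RelB_p100` to `B_nuc`.
* **Inhibitor drugs** - occupancy factors `1/(1 + dose/Ki)` applied to NIK
  processing (NIK inhibitors such as Amgen16) or to `b` (BTK inhibitors
  such as ibrutinib). Factors compose multiplicatively.

RelA activity feeds back through a shared Hill term
`H(A_nuc) = A_nuc^h / (K_tx^h + A_nuc^h)` on the synthesis of all three
inhibitors (`k0 + g * H`). Processing products are not tracked beyond their
roles: processed p100 leaves the inhibitor pool, and p52 appears only
inside RelB:p52. IkB-beta is omitted (no mechanistic role here), and p50/p52
monomers are treated as non-limiting, so dimers are the model's units.

## Calibration: constraints, not rate measurements

No rate constant in this model is a measured quantity. The shipped
canonical set (`build_parameters()`, mirrored in
`inst/extdata/canonical_params.yaml`) was found by grid and manual search
(`scripts/calibrate.R`) against a qualitative constraint surface, which is
what the mechanism actually asserts:

* C1 - higher steady-state nuclear RelA at `b = 0.005` than `b = 0.0005`;
* C2 - 24-h CD40 raises nuclear RelB:p52 more than 2-fold at both basal
  levels;
* C3 - nuclear RelA stays within 20% under CD40;
* C4 - nuclear cRel rises at least 1.5-fold under CD40 only at high basal
  (below 1.1-fold at low basal);
* C5 - IkB-alpha plus IkB-epsilon hold at most 14% of the inhibitor-bound
  cRel pool at the high-basal steady state;
* C6 - the affinity orderings (IkB-delta prefers cRel, IkB-alpha prefers
  RelA);
* genotype selectivity - IkB-epsilon knock-out raises cRel activity much
  more than RelA, while halving IkB-alpha synthesis (a kB-site promoter
  mutant) changes neither selectively.

`validate_calibration()` reports all of these with margins. Four structural
features turned out to be required, not optional, and are worth recording:

1. **Feedback-dominated IkB-alpha synthesis** (`g_Ia >> k0_Ia`). When
   IkB-alpha synthesis is mostly constitutive, halving the promoter doubles
   free RelA and - through the shared Hill term - multiplies p100 synthesis
   several-fold, crushing cRel. With synthesis dominated by the RelA-driven
   term, the loop is self-correcting: the promoter mutant settles with only
   ~12% more nuclear RelA, because synthesis demand forces the Hill
   occupancy to double and the steep Hill makes that cheap.
2. **IkB-epsilon binds both cRel (dominant) and RelA.** The p100 doubling
   in the promoter mutant is structural (see above), so cRel must be
   buffered against it: the extra free RelA diverts IkB-epsilon capture
   flux away from cRel, offsetting the extra IkB-delta capture. Without the
   RelA arm, the mutant is spuriously cRel-suppressive.
3. **Strong IkB-delta capture with a small synthesis flux.** The IkB-delta
   bound pool is flux-limited: at low basal the p100 synthesis flux is tiny,
   so even a high association constant cannot build a cRel reservoir -
   which is exactly why CD40 has nothing to release there.
4. **A steep shared Hill** (`h = 6`, half-max between the two basal RelA
   levels), read as effective cooperativity of RelA-driven transcription
   plus the multimerization of p100 into IkB-delta. Shallower response
   curves cannot simultaneously produce the p100 contrast between basal
   states (C4/C5) and the promoter-mutant buffering.

The solver is `deSolve::ode` (lsoda) at rtol = atol = 1e-8, sampled on at
least 97 evenly spaced points; steady states come from 20,000-min
unstimulated relaxation with an explicit derivative-norm convergence check
(residual below 1e-10 times the largest concentration) and are verified by
re-simulation (drift under 1e-6 relative over 24 h). An independent
fixed-step RK4 oracle reproduces the adaptive solution to 1e-5 relative; in
closed test mode (synthesis and degradation zeroed) each Rel-monomer total
is conserved to 1e-8 along trajectories. Species are clamped at zero on
output; undershoot beyond -1e-9 is treated as an integration error rather
than silently fixed.

## Virtual-cell ensembles

Cell-to-cell heterogeneity is modeled as parameter variability, not
intrinsic noise: each virtual cell multiplies every synthesis and
degradation rate by an independent log-normal factor (median 1, log-sd
`cv = 0.15` by default), while binding affinities - biophysical constants -
are shared. Twenty-five cells per condition is the standard ensemble.
Genotype comparisons (wild type, IkB-epsilon knock-out, IkB-alpha promoter
mutant at its documented default 0.5x synthesis) sample each population
independently and normalize per-cell readouts to the *reference ensemble
mean*, since knockout and wild-type populations are unpaired. All sampling
is seed-deterministic and never touches the caller's RNG state.

## From nuclear dimers to BH3-mimetic viability

`induce_bcl2_family()` integrates, along any trajectory,
`dX/dt = basal + sum_d w[X][d] * Hill(d_nuc) - (ln2 / t_half) X` for
X in {BCL2, BCLXL, MCL1}, initialized at the steady state of the
trajectory's first point so an unstimulated trajectory gives fold changes
of exactly 1. RelB dominates the BCLXL weights (with small promiscuous
weights from all dimers, reflecting broad subunit binding at that
promoter), cRel dominates MCL1, and BCL2 carries no NF-kB weight (no
definitive subunit binding at its TSS; it differs between cell lines as a
basal rate). Cell-line presets differ *only* in basal rates: BCL2-high
RIVA/U2932, the MCL1-high U2932 R1 subclone, BCL2-low SUDHL8. The weights
were calibrated to reproduce fold-change *orderings* (BCLXL-dominant
response at low basal; MCL1 exceeding BCL2 and the low-basal MCL1 response
at high basal), never numeric fold values.

The viability model is a deliberate minimal surrogate for the BCL2
interactome: each anti-apoptotic protein contributes sequestration capacity
`dep_X * abundance_X`, a BH3 mimetic divides its target's contribution by
`1 + dose/Ki` (and off-target proteins by `1 + dose/(specificity * Ki)`,
default specificity 1000, reflecting the loss of selectivity above ~10 uM),
and a cell survives while total capacity exceeds its requirement, which is
log-normal across the population (median 100 a.u., log-sd 0.3). Viability
is therefore `plnorm(E(dose))`, monotone non-increasing in dose, and the
per-line dependence weights `dep` encode what BH3 profiling would call the
line's anti-apoptotic dependence (BCL2-weighted for RIVA/U2932,
BCLXL-weighted with substantial MCL1 for SUDHL8). There is no
mitochondrial kinetics, no Bax/Bak, and no claim to quantitative LC50s -
only the *orderings* of LC50 between conditions are meaningful, and those
are what the tests assert.

LC50s are extracted with a standard four-parameter logistic fit on log
dose (`fit_4pl()`, Levenberg-Marquardt with multi-start over slope and
midpoint seeds), reporting the inflection dose with extrapolation and
degeneracy flags; flat curves (range under 0.05) never return an LC50.

## Quantification procedures

* **MFI normalization and fold changes** are ratios of medians
  (stained/unstained; condition/control).
* **Fingerprints** standardize per-cell intensities as z-scores of log10
  values against a pooled reference - flow intensities are log-distributed,
  so standardizing the log is the scale on which "10x apart" means a fixed
  z shift, and the whole construction is invariant to instrument gain
  (any common positive rescaling). Densities are Gaussian-kernel estimates
  (Scott's-rule bandwidth by default) on a fixed 200x200 grid over z in
  [-4, 4], renormalized to integrate to 1, with contour levels reported at
  the densities enclosing 25/50/75/95% of probability mass. Per-cell values
  are standardized and per-sample medians overlaid, matching the convention
  of plotting one median dot per experiment.
* **TSS windows** use 0-based half-open intervals; "within 1 kb" means the
  peak interval overlaps `[position - 1000, position + 1001)`, symmetric
  and strand-ignoring. A brute-force overlap scan serves as the test
  oracle.
* **ROUT outlier removal** follows the published robust-regression + FDR
  procedure specialized to a constant model: an IRLS location estimate with
  Lorentzian weights, robust scale (RSDR) from the 68.27th percentile of
  absolute residuals with an n/(n-1) small-sample correction, two-tailed
  t p-values, and removal at FDR rate `q` from the most extreme point
  inward. The commercial implementation's exact numerics are not public, so
  agreement is asserted by property - planted contaminants at >= 6 robust
  SDs are removed with probability >= 0.99, and the false-positive fraction
  on clean Gaussian data stays below 2q - rather than bit-for-bit. If the
  bulk of the data is identical (zero robust scale), any point off the
  consensus is an outlier and clean identical data yield none.

## Synthetic data and what passing tests mean

Every input the pipeline consumes can be generated with planted ground
truth: log-normal flow mixtures (including biclonal CD20 populations and
unstained controls), 4PL dose-response tables with Gaussian noise clipped
to [0, 1.05], log-normal N:C ratio tables with planted shifts, and ChIP
peak tables with known window membership and planted score outliers. Truth
travels in machine-readable sidecars; estimator tests read truth only from
there.

The synthetic dose-response default plants a Hill slope of 2. Viability
curves of BH3 mimetics are typically steep (apoptosis commitment is
cooperative), and the slope matters for what LC50 precision is achievable:
at a shallow slope near 1.2, the sampling error of an LC50 from 9 doses x 3
replicates at noise sd 0.05 exceeds 15% in roughly one trial in eight, so
the documented recovery guarantee (within 15% in >= 95% of trials) is a
statement about assays in the steep regime, not about arbitrarily shallow
curves.

What the synthetic generators do *not* emulate: spectral spillover and
compensation in flow data, autofluorescence that varies by marker, cell
debris and doublets, spatial structure in imaging, read-level ChIP-seq
artifacts, or plate effects in viability assays. Passing tests demonstrate
that the estimators recover what they claim from data matching their
stated distributional assumptions - they do not certify performance on
real instruments.

## Known limitations

The model is a 16-species reduction: no IKK cascade detail, no IkB-beta,
no explicit p52 pool, no RelA:RelA or p50:p50 dimers, no transport of
inhibitor-bound complexes. The basal-activation mapping of specific cell
lines to the endpoints of the 0-0.5% range is an anchoring choice, and the
inhibitor pharmacology is simple occupancy with configurable Ki defaults
(Amgen16 50 uM against Ki 5 uM; ibrutinib 0.1 uM against Ki 0.01 uM),
chosen to represent strong but incomplete target engagement rather than
measured affinities. Ensembles express expression heterogeneity only.
LC50s are meaningful as orderings within a cell line, not as
concentrations.

## A worked tour

```{r tour, eval = FALSE}
library(nfcrosstalk)

# the two basal states at steady state
lo <- apply_basal_activation(build_parameters(), 0.0005)
hi <- apply_basal_activation(build_parameters(), 0.005)
inhibitor_composition(nfkb_steady_state(hi), "C")

# CD40 response of a 25-cell ensemble
cells <- sample_cells(hi, n = 25, cv = 0.15, seed = 1)
ens <- run_ensemble(cells, stimulus_spec(cd40_on = TRUE))
autoplot(ens)

# downstream: BCL2-family induction and an LC50 triple
resensitization_experiment("SUDHL8", "A1331852",
                           list(type = "BTK_inh", dose = 0.1, Ki = 0.01))
```

The problem sizes used throughout the tests - 25-cell ensembles, 24-h
horizons, 500-seed recovery studies, 200-seed false-positive studies -
are the package's standard study conditions and match the documented
guarantees above.
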