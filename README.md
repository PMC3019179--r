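# ap1grn

Compartmental kinetic modeling and multivariate analysis of the
angiotensin II / AT1R gene regulatory network that drives AP-1
transcription-factor dimer dynamics and tyrosine hydroxylase (TH)
expression in brainstem neurons.

Ang II binding to AT1R activates the kinases ERK, FRK and JNK, which
phosphorylate Elk-1, c-Fos, c-Jun and ATF-2. Dual-phosphorylated c-Fos
and c-Jun form two active AP-1 species — the ppc-Fos:ppc-Jun heterodimer
and the ppc-Jun:ppc-Jun homodimer — whose sum ("Total AP-1") drives TH
transcription. The package is aimed at systems biologists studying how
this network's output stays robust: it provides the ODE model and, around
it, the full multivariate analysis pipeline — Monte-Carlo
sequential-constraint parameter screening, time-resolved variance-based
global sensitivity analysis, and decision-tree classification of
perturbed AP-1 responses.

## The model and the analyses

* **Network**: 32 species (29 ODE states + 3 kinase inputs), 48
  reactions, nuclear and cytosolic compartments. Phosphorylation cycles
  follow Michaelis-Menten kinetics
  (v = kcat [E][S] / (Km + [S])), dimerization and TF:promoter
  binding reversible mass action, synthesis/processing/degradation first
  order; 77 parameters (72 rates + 2 non-zero initial conditions + 3
  kinase scales). Stiff integration (lsoda) on a 1-min grid over
  0-60 min, with a compiled right-hand side for large screens.
* **Fitting**: candidates drawn in two-fold boxes around base values are
  filtered sequentially on the sum-squared error of four normalized
  channels: pElk-1 DNA binding, c-Fos mRNA, Total AP-1, TH mRNA.
* **Sensitivity**: Sobol-style first-order S1_i = V_i / V(Y) and
  total-effect ST_i (Saltelli/Jansen estimators over a radial design),
  per reporting minute, with low-variance times masked and the
  interaction ratio alpha_i = S1_i / ST_i.
* **Response classes**: perturbed Total AP-1 profiles are labeled by
  Pearson correlation (r > 0.95) against the nominal heterodimer,
  homodimer and Total AP-1 templates; an rpart decision tree over the
  seven most sensitive parameters maps parameter space to response
  class under a 15%-of-smallest-class split-eligibility rule.
* **Synthetic data**: unimodal kinase forcing profiles, surrogate noisy
  fitting targets, analytic sensitivity oracles and rule-labeled
  samples replace the study's inaccessible wet-lab inputs.

## A worked example

```r
library(ap1grn)

net    <- at1rgrn_network()        # validated 48-reaction network
params <- nominal_parameters()     # calibrated 77-parameter set
inputs <- synth_kinase_profiles()  # ERK/FRK/JNK forcing, 100 nM scale

traj   <- simulate_network(net, params, inputs)
hetero <- species_series(traj, "FosJun")
homo   <- species_series(traj, "JunJun")

sprintf("heterodimer peak: %.2f nM at %d min",
        max(hetero), traj$times[which.max(hetero)])
#> "heterodimer peak: 2.77 nM at 22 min"
crossover_time(traj)
#> 36.1
sprintf("homodimer at 60 min: %.2f nM (%.1f-fold over heterodimer)",
        homo[61], homo[61] / hetero[61])
#> "homodimer at 60 min: 2.48 nM (9.5-fold over heterodimer)"

trJ <- simulate_inhibition(net, params, inputs, "JNK")
100 * max(total_ap1(trJ)) / max(total_ap1(traj))
#> 0.50
```

Read: AP-1 activates first as the Fos:Jun heterodimer (peak 22 min),
the dimer composition crosses over mid-experiment (36 min), and by
60 min the Jun homodimer dominates 9.5-fold — the "dynamic balance" of
AP-1 forms. Clamping JNK to its basal activity abolishes essentially the
entire AP-1 response (0.5% of nominal), while clamping FRK only removes
the heterodimer and leaves the late response intact (try
`simulate_inhibition(net, params, inputs, "FRK")`).

The full pipeline (simulate -> sensitivity -> ranking -> classification
-> tree, with CSV/JSON/DOT artifacts) runs via:

```r
run_pipeline(default_config(), out_dir = "ap1grn-run")
```

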