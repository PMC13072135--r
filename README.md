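# polscope

Testing the pace-of-life syndrome (POLS) in zebrafish: a simulation and
analysis pipeline linking routine metabolic rate to novel-tank boldness.

## The problem

The POLS hypothesis predicts that animals with higher baseline metabolic
demands take more risks. In adult zebrafish that prediction is tested by
relating two measurements made on the same fish:

* **Routine metabolic rate (RMR)** from closed-chamber respirometry:
  dissolved O₂ is read at the start and end of a 30-min trial in the fish
  chamber and a parallel fish-free *blank* chamber, and consumption is the
  blank-corrected drop

  ```
  [O2]consumed = ([O2]f,t1 − [O2]f,t2) − ([O2]b,t1 − [O2]b,t2)
  ```

  normalized by body mass (mg O₂/l/g per trial).

* **Boldness** in the novel tank test: from a 3D swim trajectory the
  pipeline extracts bottom distance, center distance, distance traveled,
  percent of 1000 tank voxels explored, percent time immobile (< 1.5 mm/s)
  and maximum velocity (median of the top 5% of speeds); the **boldness
  index** is the sum of within-group (sex × strain) z-scores of percent
  explored and bottom distance.

The statistical battery mirrors the field's conventions: Shapiro–Wilk-gated
Pearson/Spearman correlations, one-way bootstrap ICC repeatability, 2×2
raw-permutation ANOVAs with η², normality-gated Welch t / Mann–Whitney /
paired Wilcoxon tests with Cohen's d, and conventional effect-size bands.

Because raw per-fish data for this assay family are rarely deposited, the
package ships a first-class **cohort simulator**: fish with latent
(metabolic, boldness) traits planted at a tunable correlation `rho_true`
drive both a movement model (persistent random walk with vertical
preference and an immobility Markov chain) and a respirometry model
(allometric mass scaling, blank drift, meter noise, optional fasting
effect). Every downstream claim is validated against this known ground
truth. See the methods vignette (`vignettes/polscope-methods.Rmd`) for the
models, defaults and their rationale.

## Worked example

Simulate the default four-cell cohort (TU/WIK × female/male, 30 fish per
cell, two respirometry days) with a planted metabolism–boldness
correlation of 0.6, and analyze it:

```r
library(polscope)
co  <- generate_cohort(cohort_config(n_per_cell = 30, rho_true = 0.6),
                       seed = 42)
rep <- analyze_cohort(co, n_perm = 10000, n_boot = 1000, seed = 42)

rep$repeatability
#>     sex   method     r r_p_value   icc icc_ci_low icc_ci_high  n n_dropped
#>  female  pearson 0.831  2.06e-16 0.830      0.727       0.889 60         0
#>    male spearman 0.703  0.00e+00 0.767      0.592       0.865 60         0

scr <- rep$correlation_screen
scr[scr$variable == "boldness_index", ]
#>     sex strain       variable   method coefficient  p_value  n significant
#>  female     TU boldness_index  pearson       0.586 0.000668 30        TRUE
#>  female    WIK boldness_index  pearson       0.540 0.002093 30        TRUE
#>    male     TU boldness_index spearman       0.369 0.045495 30        TRUE
#>    male    WIK boldness_index  pearson       0.562 0.001235 30        TRUE

rep$recovery
#>  quantity truth estimate
#>  rho_true   0.6    0.519
```

Reading the output: day-to-day O₂ consumption is highly repeatable
(ICC ≈ 0.8 with bootstrap CIs — the simulator's calibrated regime), the
planted POLS association is detected in all four sex × strain cells, and
the pooled estimate 0.519 sits below 0.6 by the expected attenuation
(both the index and RMR are noisy readouts of their latent traits; the
expected per-cell correlation is ≈ 0.807 × rho_true). One male-TU cell
fell back to Spearman because a variable failed the normality gate — the
report records every such decision.

The same battery runs on real data laid out as CSVs (`metadata.csv`,
`respirometry.csv`, `trajectories/<fish>.csv`) via
`run_study(study_config(mode = "ingest", path = "cohort_dir/"))`, with
schema validation up front (`validate_inputs()`).

A command-line wrapper is installed with the package:

```sh
polscope=$(Rscript -e 'cat(system.file("exec/polscope", package="polscope"))')
Rscript $polscope all --seed 7 --outdir study_out
```

Subcommands `simulate | metrics | respiro | analyze | report | all` write
plain CSV/JSON reports; identical seeds give byte-identical outputs.

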