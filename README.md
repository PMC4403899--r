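# prostab

Structure-based prediction of protein stability changes (ΔΔG) upon
single- and multi-point mutations, with a multi-agent consensus, a
confidence estimate, high-throughput mutation scanning, and a screening
mode for stabilizing disulfide bonds.

It is written for protein engineers and structural bioinformaticians who
have a wild-type structure (PDB format; single chains, biological
assemblies, or NMR ensembles) and want to ask: *how much does mutation X
destabilize this protein?*, *which n-point mutant is most stabilizing
under my constraints?*, or *where could an engineered disulfide go?*
Sign convention throughout: **negative ΔΔG = stabilizing**.

## Method in brief

* **Statistical scoring functions.** Two Sippl-style distance-dependent
  residue-pair potentials (Cα–Cα and Cβ–Cβ) and a Cα-contact potential
  are compiled from reference structures:
  `E°_ab(d) = −ln(δ_ab(d)/ρ(d))`, normalized by per-pair expected
  energies `Eᵉ_ab = Σ_d ρ(d) E_ab(d)`. A structure is scored by ranking
  its observed energies jointly with their expected counterparts
  (Wilcoxon–Mann–Whitney rank sum, `s = (W − μ_W)/σ_W` with
  `μ_W = n(2n+1)/2`, `σ_W = √(n²(2n+1)/12)`), and the three scores
  combine by Stouffer's rule, `s_c = (s_α + s_β + s_c)/√3`. Mutants are
  the same coordinates with residue types relabeled — no remodelling.
* **Agents.** Nine inputs (three score differences, protein size,
  secondary structure, relative ASA, Δmass, Δhydrophilicity, ΔpI) feed
  seven agents: MLR, and general/stabilizing/destabilizing specialists
  for ANN and ε-SVR. General agents route each query to the matching
  specialist by predicted sign; the five-value pool is pruned by
  iterative 2σ outlier removal and averaged. Confidence is
  `c_pred = 1 − σ_r/σ_max` (clamped to [0, 1]), with `σ_max` four times
  the training ΔΔG standard deviation.
* **Scanning.** Exhaustive, greedy, and multi-population evolutionary
  searches over n-point mutants under site/type/accessibility
  constraints.
* **Disulfide design.** Residue pairs with Cβ–Cβ ≤ 5 Å are mutated to
  double cysteine and ranked by
  `S_ss = (z_ΔΔG + z_Pβ + z_Pαβ)/√3`, where the penalties
  `P = 1 − f(·)` come from distance histograms of disulfide-bonded
  cysteines.

See `vignettes/prostab-methods.Rmd` for the full model description,
parameter defaults and design decisions.

## Worked example

Everything below runs self-contained — toy structures and a synthetic
training table with a known linear ground truth are generated in code:

```r
library(prostab)

structures <- list(makeToyStructure(40, "helix",  seed = 1),
                   makeToyStructure(60, "hairpin", seed = 2),
                   makeToyStructure(30, "cluster", seed = 3))
ssf <- compileSSFModels(structures)                 # the three potentials
tab <- makeTrainingTable(structures, ssf, demoBeta(),
                         noiseSd = 0.5, nRows = 600, seed = 7)
ens <- trainAgents(tab, agentConfig(hiddenGrid = 5L, gammaGrid = 1/9,
                                    costGrid = 1), seed = 1)
#> AgentEnsemble: 7 agents, sigma_max = 7.621 kcal/mol, trained on 600 records

st <- structures[[1]]
predictMutation(st, parseMutations("A:I12K"), ens, ssf)
#> StabilityPrediction: ddG = +4.328 kcal/mol (confidence 1.00, sigma_r 0.015)
#>   pruned agents: svr_specialist, svr_general, ann_specialist
```

The I12K substitution on the toy helix is predicted destabilizing
(ΔΔG = +4.33 kcal/mol); the retained agents agree tightly
(σ_r = 0.015 kcal/mol), so the confidence is ≈ 1. Scanning positions
5–15 for the most stabilizing single mutant:

```r
con <- mutationConstraint(st, nPoints = 1, positions = 5:15,
                          objective = "stabilize")
optimalScan(con, stabilityPredictor(st, ens, ssf), top = 3)@results
#>   rank mutations    ddg confidence
#> 1    1     A:R9C -4.449     0.9445
#> 2    2     A:R9L -4.044     0.9872
#> 3    3     A:R9T -3.939     0.9757
```

The same operations are available from a shell through the dispatcher
(`inst/scripts/prostab.R`) with the subcommands `predict`, `scan`,
`ssbond`, `train`, `evaluate` and `compile-ssf`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/prostab.R", package="prostab"))')" \
    predict --pdb my.pdb --mutation A:N25K --model modeldir --ssf ssfdir
```

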