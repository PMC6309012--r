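# desertSong

Demographic inference and song-playback analysis for a songbird split by
a desert filter barrier.

Filter barriers — like the transition between the Sonoran and Chihuahuan
deserts — let some taxa exchange genes while isolating others. For a
resident songbird sampled on both sides, this package answers two
coupled questions as one tested pipeline:

* **Demography.** When did the two desert populations diverge, how large
  are they, and did gene flow cross the barrier? SNP genotypes are
  reduced to an unfolded three-population joint site-frequency spectrum
  (SFS), and six structured-coalescent models — pure isolation,
  isolation with symmetric / asymmetric / unidirectional migration, and
  secondary contact — are fitted by maximum composite likelihood and
  compared by AIC, with parametric-bootstrap confidence intervals.
* **Behavior.** Do territorial males discriminate against foreign song
  dialects? Playback-trial aggression measures are reduced to a PCA
  composite (PC1) and compared across song treatments (Local, Distant,
  Across-Barrier, Control) with linear mixed models under AICc, Wald
  tests, and pairwise treatment contrasts.

Supporting statistics: Nei's G_ST and Hedrick's G'_ST from genotypes,
and the Evanno delta-K statistic on clustering log-likelihood tables. A
synthetic-data module simulates both genotype (VCF + population map) and
playback datasets under known truth, so every stage is verified by
parameter recovery.

## The core model

Backward in time, lineages sampled from the Sonoran (S), Chihuahuan (C)
and outgroup (O) demes coalesce within demes at rate C(k,2)/N_e
(haploid N_e, generations), migrate between S and C at per-lineage rates
m_S (C to S backward, i.e. forward Sonoran-to-Chihuahuan flow) and m_C
while the model's migration window is open, merge into an ancestral
desert deme of size N_eD at T_D, and into the root deme (size N_eA) at
T_A = 2,000,000 years — the calibration that, with mutation rate
mu = 2.21e-9 per site per year, turns everything into absolute units.
The expected joint SFS is accumulated from branch lengths
(E[SFS(i,j,k)] = mu x mean branch length subtending exactly (i,j,k)
samples), and an observed spectrum `O` is scored with the multinomial
composite likelihood

    l = sum over unmasked cells of O(v) log p(v),

p the normalized (floored) expected spectrum. AIC = 2k − 2l with k free
parameters per model; gaps of 2 / 10 mark significant / highly
significant support.

## Worked example

Simulate an observed spectrum of 20,000 SNPs under the reported best-fit
asymmetric-migration parameters and refit the same model:

```r
library(desertSong)

model <- getModel("ASYM")
truth <- bestFitParameters()    # NeS 153451, NeC 706389, TD 991414, ...
obs <- simulateSFS(model, truth, sampleConfig(), nSnps = 20000,
                   seed = 7, nReps = 20000)
show(obs)
#> JointSFS (unfolded): shape 11 x 11 x 3, haploid samples (10, 10, 2)
#>   unmasked mass 2e+04 over 361 cells (2 masked)

fit <- fitModel(obs, model, seed = 11)
print(fit)
#> FitResult[ASYM]: loglik -61183.854, AIC 122383.708 (k = 8, 1113 evaluations)
#>          NeS          NeC          NeO          NeD          NeA           TD
#> 2.468561e+05 5.658215e+05 2.095556e+05 4.135874e+06 1.188293e+05 1.079426e+06
#>           MS           MC
#> 7.336130e+00 1.008920e+00
```

One refit recovers the divergence time (1.08M vs 991k years generating),
the migrant counts (7.3 and 1.0 vs 8.3 and 1.6 per generation) and the
size ordering, with the sizes trading against each other along the flat
composite-likelihood ridge the methods vignette describes — single-refit
estimates carry a 10-20% spread, which is why the headline quantities
are medians over replicate refits. `selectModel()` turns a list of fits
into a delta-AIC table, `fitAllModels()` fits the whole catalog with
cross-seeded nested models, and `parametricBootstrap()` wraps the
simulate-and-refit loop into percentile intervals.

The behavioral arm runs the same way from a synthetic field season:

```r
trials <- makePlaybackDataset(playbackScenario(), seed = 1)
attr(trials, "nTrials"); attr(trials, "nDetectedTrials")
#> [1] 512
#> [1] 348
scores <- scoreAggression(reduceMeasures(trials))
cmp <- compareModels(scores)
cmp$deltaAicc      # AICc(null) - AICc(full); positive favors treatment
#> [1] 65.9
subset(cmp$contrasts, pair == "LOCAL vs CONTROL")
#>               pair estimate     se     z         p
#> 3 LOCAL vs CONTROL    3.008 0.2489 12.08 1.319e-33
```

512 trials at 67 + 61 sites, 348 after removing the sites without a
detected male; the mixed-model comparison flags the local-song effect.

A thin command-line wrapper over the same functions is installed at
`inst/cli/desertsong.R` (subcommands `sfs`, `fit`, `select`,
`bootstrap`, `gst`, `deltak`, `behavior`, `simulate`).

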