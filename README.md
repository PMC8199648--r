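# cernet

Inference of clinically relevant circRNA–mRNA co-expression networks and
circRNA–miRNA–mRNA competing-endogenous-RNA (ceRNA) triplets from paired
tumor / adjacent non-tumor expression profiles, for transcriptomics groups
screening circRNAs as tumor drivers or biomarkers.

Circular RNAs can sponge miRNAs: a circRNA and an mRNA that share a miRNA
response element compete for that miRNA, so the pair is positively
co-expressed, each is inversely correlated with the miRNA, and the pair's
correlation weakens once the miRNA is conditioned on. `cernet` turns that
mechanism into a screening pipeline over a paired cohort (one tumor and one
matched non-tumor sample per patient):

1. **Differential expression** — paired t-test per feature, calls at
   |FC| ≥ 1.5 and Benjamini–Hochberg FDR ≤ 0.05.
2. **Clinical association** — Welch t between worse/better phenotype groups
   (|FC| ≥ 1.5, p ≤ 0.05) and log-rank on a median expression split;
   prognosis call per feature (up in tumors + higher in worse groups ⇒
   worse-prognostic).
3. **Co-expression network** — all clinically associated DE circRNAs ×
   DE mRNAs, Pearson |r| ≥ 0.7 at FDR ≤ 0.05; connected components; *nodal*
   (master) circRNAs by greedy gene coverage to 93%; circRNA/host-gene
   fold-change concordance.
4. **ceRNA tiers** — miRNA–target links kept when both predictors agree and
   Spearman ρ < 0 (p ≤ 0.05); pairs sharing miRNAs scored by the
   hypergeometric test, Pearson correlation (PC), partial Pearson
   correlation (PPC: r<sub>xy|z</sub> = (r<sub>xy</sub> −
   r<sub>xz</sub>r<sub>yz</sub>)/√((1−r<sub>xz</sub>²)(1−r<sub>yz</sub>²))),
   sensitivity correlation (SPPC: r<sub>xy</sub> − r<sub>xy|z</sub>) and
   Gaussian conditional mutual information (CMI: −½ ln(1 − r<sub>xy|z</sub>²),
   stratified-permutation p). *Highly confident* = all five pass;
   *moderate* = PC + PPC. Triplets expand one per shared miRNA and are
   flagged clinically relevant when backed by a network edge.
5. **Biomarkers** — ROC (tie-corrected Mann–Whitney AUC, Youden cut) and a
   ridge-stabilized logistic panel over three grade contrasts, plus
   hypergeometric gene-set over-representation.

A paired-cohort simulator (`simulate_cohort()`) plants DE features, grade
associations and miRNA-mediated triplets with known truth, so every stage
is verifiable; `score_recovery()` reports sensitivity and false-discovery
proportion against the planted truth.

## Worked example

The `analysis/` scripts run the whole study on the default simulated
cohort (49 patients; 150/60/300 circRNA/miRNA/mRNA features; 10 planted
triplets), writing every stage table under `results/run/`:

```sh
Rscript analysis/01_simulate.R   # cohort + planted truth
Rscript analysis/02_diffexp.R    # DE per class + sample dendrogram
Rscript analysis/03_clinical.R   # clinical associations + prognosis calls
Rscript analysis/04_coexpr.R     # network, components, nodal circRNAs
Rscript analysis/05_cerna.R      # interactions, pair tiers, triplets
Rscript analysis/06_biomarker.R  # ROC / logistic panels, enrichment
Rscript analysis/07_report.R     # run report
```

The final report printed by `07_report.R` (seed 1):

```
ceRNA network pipeline run report
seed: 1
DE (|FC| >= 1.50, FDR <= 0.05):
  circRNA: 11 up / 4 down of 150; clinically associated: 10
  miRNA: 2 up / 10 down of 60; clinically associated: 8
  mRNA: 24 up / 6 down of 300; clinically associated: 22
prognosis calls: better_prognostic=6, unclear=20, worse_prognostic=14
co-expression edges (|r| >= 0.70, FDR <= 0.05): 5 in 5 component(s)
nodal circRNAs: circR0024, circR0026, circR0053, circR0082, circR0098 (coverage 1.000)
ceRNA: 20 retained links, 10 pairs (0 highly confident, 10 moderate)
triplets: 10 (5 clinically relevant)
```

Reading: of 57 DE features, the clinically associated circRNAs form a
small |r| ≥ 0.7 network whose 5 nodal circRNAs cover all network genes;
all 10 planted triplets are recovered at the moderate tier (`05_cerna.R`
prints `planted triplet recovery: 10/10`), and 5 of them sit on a
clinically relevant co-expression edge. Equivalently in R:

```r
library(cernet)
rep <- run_all("results/run", run_config(seed = 1), sim = sim_config(seed = 1))
```

The same stages compose file-by-file via `run_stage()`; both routes are
byte-identical. Networks are exported as SIF and GraphML for Cytoscape.

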