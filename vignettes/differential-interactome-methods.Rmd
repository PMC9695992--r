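---
title: "Methods: differential interactome modules as systems biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential interactome modules as systems biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffinteractome)
```

## The model

The package analyses how protein–protein interactions change between a tumor
and a normal phenotype, restricted to proteins annotated to the ten hallmarks
of cancer. The statistical object is not the expression of a gene but the
*observation* of an interaction: an edge between proteins $a$ and $b$ is
considered observed in a sample when both genes are expressed there. Writing
$f_T$ and $f_N$ for the fraction of tumor and normal samples in which an edge
is observed, the edge's interactome q-value is

$$q = \frac{f_T}{f_T + f_N},$$

the relative frequency of observation in the tumor phenotype (this is *not*
an FDR q-value). An edge is called **suppressed** in tumors when $q < 0.10$,
**activated** when $q > 0.90$, in both cases provided
$\max(f_T, f_N) > 0.20$ — an edge must be seen in at least a fifth of one
phenotype's samples before a call is made. All three inequalities are strict,
and all three thresholds are configurable
(`run_differential_interactome()`).

Proteins incident to at least one differential edge (DIHCPs) seed hub-star
modules: the hub plus all its differential partners. Modules with fewer than
10 members are dropped, and near-duplicate modules of one cancer type —
sharing at least 70% of the smaller module's proteins, the overlap
coefficient $|A \cap B| / \min(|A|, |B|)$ — are pooled iteratively. Each
surviving module is then scored twice: as a *diagnostic* biomarker (can its
genes' expression separate tumor from normal samples?) and as a *prognostic*
biomarker (does its Cox prognostic index stratify patient survival?).

## Choices the procedure leaves open, and what we chose

**Interaction observation.** Neither the differential-interactome idea nor
its published applications state how per-sample gene activity is decided.
Default: a gene is expressed when its FPKM is at least 1, the standard
expressed-gene convention. Per-gene median and per-gene quantile rules are
available (`binarize()`), and the rule used is recorded in the result's
attributes. The frequency rule is read as *either* phenotype exceeding 20%
($\max(f_T, f_N)$): an AND reading would make suppressed calls impossible,
since a suppressed edge has near-zero $f_T$ by construction.

**Module size.** "At least 10 proteins" counts the hub plus its partners;
this is the natural reading of a module's protein count.

**Pooling.** Pooling iterates to a fixed point rather than making one pass;
candidate pairs are examined in lexicographic name order and merged modules
are renamed canonically from their hub set (all-`PSM*` hubs become
`mPSMcomp`, all `YWHA*`/`SFN` hubs become `mYWHAcomp`), which makes the
result provably independent of input order. The overlap coefficient, not
Jaccard, implements "sharing 70% of the common proteins": the share is of
the smaller module.

**Diagnostics.** Each simulation draws 30 tumor and 30 normal samples
without replacement, z-scores each module gene over the drawn samples (so
high-FPKM genes do not dominate the PCA), and projects onto the first three
principal components. Sensitivity and specificity come from leave-one-out
nearest-phenotype-centroid classification in that 3-PC space — the simplest
classifier consistent with "the first 3 principal components ... were
considered in determining the sensitivity and specificity". Exactly three
PCs are always used; whether they cover 80% of total variance is recorded
separately rather than adapting the PC count, keeping the procedure fixed.
Simulations repeat until the running means of sensitivity and specificity
each move by less than 0.005 over the last 10 simulations (minimum 20,
maximum 200; all four knobs configurable). A module is diagnostic when both
means reach 0.90.

A reproducibility detail: each simulation's draw for a phenotype pool runs
on an RNG substream derived from the simulation seed and a hash of the
pool's sorted sample IDs. Draws are thereby attached to a pool's *content*,
not its label, so relabelling phenotypes swaps sensitivity and specificity
exactly at the same seed — a symmetry the test suite checks bitwise.

**Prognostics.** On tumor samples with clinical follow-up, the package fits
a Cox proportional-hazards model on the z-scored module genes (Breslow ties;
`survival::coxph` with a light ridge fallback when the information matrix is
singular), forms the prognostic index $PI = \sum_i \beta_i x_i$, splits
samples at the median PI (ties to LOW), and runs the two-group log-rank
test. The hazard ratio uses the observed/expected form
$HR = (O_1/E_1)/(O_2/E_2)$ with group 1 the high-PI group. A module is
prognostic when the log-rank p-value is below 0.01. Kaplan–Meier step
coordinates per group are returned for plotting.

**Enrichment.** DAVID-style over-representation is computed locally: the
one-sided hypergeometric tail $P(X \ge k)$ per gene set,
Benjamini–Hochberg correction across sets, significance at adjusted
$p < 0.01$. The default universe is the reconstructed hallmark network's
node set — enrichment relative to the analysed space, not the genome.

**Druggability.** Only modules whose differential edges are uniformly
activated or uniformly suppressed are screened (mixed modules are
ineligible). Activated modules match inhibitor-like drug actions
(inhibitor, antagonist, blocker, suppressor), suppressed modules
activator-like actions (activator, agonist, inducer); unlisted action
tokens never match, and only approved drugs count. The direction vocabulary
is an editable map (`default_direction_map()`).

## The synthetic-data generator

`synthetic_scenario()` / `generate_scenario()` produce all four inputs with
a ground-truth manifest. The defaults are the package's reference study
conditions: 50 tumor and 50 normal samples; 10 activated and 10 suppressed
planted interactions with per-sample co-activity 0.95 in the favoured
phenotype and 0.02 in the other; 200 decoy interactions sampled from a
preferential-attachment backbone over 200 background genes with activity
probability 0.5; expression drawn log-normally with
$\mu_{hi} = \log 8$, $\mu_{lo} = \log 0.1$, $\sigma = 0.5$, straddling the
1-FPKM activity threshold; exponential survival with baseline hazard
$10^{-3}$ per day and ~30% independent exponential censoring. Under these
conditions a planted activated edge has expected $f_T = 0.95$,
$f_N = 0.02$, hence expected $q \approx 0.979$.

Two constructions deserve explanation:

* **Planted edges are endpoint-disjoint, and decoys avoid planted genes.**
  A planted edge with $f_T = 0.95$ and $f_N = 0.02$ necessarily shifts its
  endpoints' *marginal* activity between phenotypes (equal marginals would
  force the joint probability above $2p_m - 1$, which is incompatible with
  0.02), so any decoy edge touching a planted gene would itself become
  genuinely differentially co-active. Sampling decoys only among background
  genes keeps the planted/decoy ground truth unambiguous.
* **Star modules** (for module-, diagnostic- and prognostic-level tests) add
  a fresh hub with $k$ fresh partners whose per-gene activity probability is
  $\sqrt{p_{on}}$ per phenotype, giving each hub–partner edge co-activity
  $p_{on}$ under independence.

Survival times are exponential with hazard
$\lambda_0 \exp(\gamma z)$, where $z$ is the z-scored mean expression of the
designated module's genes across tumor samples; the manifest records the
designated genes and $\gamma$.

What the generator does *not* emulate: correlated expression beyond planted
edges, batch effects, dropout or library-size artefacts, non-proportional
hazards, and identifier noise. Passing tests on these data demonstrate the
pipeline's statistical behaviour under its own model, not performance on
real cohorts.

## Numerical choices and degenerate inputs

Binarization uses the $\ge$ convention at every threshold. Edges observed in
neither phenotype have undefined q and are reported `UNOBSERVED` rather than
dropped. Zero-variance genes are dropped per diagnostic draw and before Cox
fitting (with warnings). The Cox fit uses a relative tolerance of $10^{-9}$
and at most 100 iterations, with a ridge penalty of $10^{-4}$ as fallback;
an all-identical prognostic index is an error ("degenerate PI") rather than
an arbitrary split. Log-rank risk tables with zero variance raise an error.
BH adjustment validates that p-values lie in $(0, 1]$.

Problem sizes in the test-suite and acceptance computations (50
oracle-comparison instances of 20 genes by 40 samples, 100-simulation
diagnostic runs, 500-replicate null calibrations, Cox recovery at $n=500$)
were chosen so that Monte-Carlo standard errors are small relative to the
tolerances being checked.

## Known limitations

* The prognostic index is fit and evaluated on the same cohort. The log-rank
  test on a median split of an in-sample PI is therefore anti-conservative,
  and increasingly so with module size: in null simulations the rejection
  rate at nominal $p < 0.01$ is roughly 1.5% for a single gene but can
  exceed 50% for 13-gene modules. This mirrors the procedure as originally
  described; interpret `is_prognostic` as a ranking criterion within a
  study, not as a calibrated error rate. A held-out or cross-validated PI
  would be the statistically safer design.
* Gene and protein identifiers are treated as the same token (official gene
  symbols); no identifier mapping is performed.
* The hub-star module definition does not discover communities; partners of
  partners are not included.
* Interaction-type and throughput filtering of the input interactome is
  assumed done upstream.

## A small worked run

```{r example, eval = FALSE}
sc <- synthetic_scenario(seed = 9, gamma = 1.2,
                         stars = list(list(state = "ACTIVATED",
                                           n_partners = 12)))
paths <- write_scenario(generate_scenario(sc), "scenario")
summary <- run_pipeline(
  list(expression = paths[["expression"]], phenotype = paths[["phenotype"]],
       network = paths[["network"]], gene_sets = paths[["gene_sets"]],
       survival = paths[["survival"]], drugs = paths[["drugs"]],
       cancer_type = "SYN", seed = 1),
  "results")
str(summary)
```
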