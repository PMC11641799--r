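---
title: "Detecting transcriptional memory across clonal generations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcriptional memory across clonal generations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The experimental design the pipeline models

clonemem analyses multi-generation stress-priming experiments in clonally
propagated plants such as duckweed. A founder generation is split into a
control lineage and a stressed lineage (stage P1, conditions CK and S); the
stressed lineage is then propagated under control conditions for two
recovery generations (P2, P3) and finally re-exposed to the stressor (P4).
Five groups are transcriptome-sequenced — CK, S, P1S-P2CK, P1S-P3CK and
P1S-P4S — each with three biological replicates, and a panel of
morphological/physiological traits is measured with about six replicates
per group. Because only the single P1 control is sequenced, all four
differential-expression contrasts use CK as the reference; there is no
stage-matched control, and the pipeline makes no attempt to invent one.

The scientific questions are: which genes remember the stress (stay
differentially expressed in the same direction through recovery and
re-exposure), which traits are pre-adapted (weaken) or sensitized
(strengthen) by parental exposure, and whether memory genes concentrate in
co-expression modules associated with those traits.

# Differential expression

Counts are normalized with median-of-ratios size factors rescaled to
geometric mean one. Per-gene NB dispersions (variance $m + \phi m^2$) are
estimated by a pooled within-group method of moments,
$\hat\phi = \max\!\big(0, (v - m)/m^2\big)$ combined across the five groups
with df weights. With three replicates per group this estimator is very
noisy and frequently truncates to zero, so a log-linear mean–dispersion
trend is fitted across genes and used as a floor: the working dispersion is
$\max(\hat\phi_{\text{gene}}, \hat\phi_{\text{trend}})$. We initially
shrank gene-wise estimates 50% toward the trend instead; on fully null
simulations that version rejected at 0.080 at the nominal 0.05 level
(0.0985 for a log-scale shrink), because below-trend and zero-truncated
estimates understate the variance. The floor version rejects at 0.047,
which is why it is the default. The cost is power on genuinely low-variance
genes, a trade we accept: an anticonservative Wald test corrupts every
downstream memory call.

The test itself is a per-gene Wald comparison of normalized-count group
means: $\log_2\!\mathrm{FC} = \log_2(m_B/m_A)$ (an all-zero group mean is
floored at 0.5), with a delta-method standard error from the NB variance
and a two-sided normal p-value, BH-adjusted across genes. Calls are ternary
at `p_adj < 0.05` and `|log2FC| > 0.5`; both thresholds are arguments. Fold
changes are not shrunk. An adapter (`contrast_from_table()`) accepts DE
tables produced by external tools so the memory step can be driven by, for
example, a DESeq2 analysis instead of the native engine.

# Memory classification

Direction calls from the four contrasts form one ternary 4-tuple per gene
(the universe is the intersection of genes tested in all four contrasts).
Membership is pure set logic:

* **robust responsive** — same non-ns direction at P1 and P4;
* **TMG2** — robust and the same direction at P2;
* **TMG3** — TMG2 and the same direction at P3 (always nested in TMG2).

The remaining taxonomy is fixed as: *transient* (DE in exactly one
contrast), *fluctuating* (DE in two or more contrasts with conflicting
signs, not robust), *non-responsive* (everything else, including same-sign
multi-contrast patterns that are not robust at P1/P4). Each gene receives
exactly one label, with TMG3 > TMG2-only > robust > transient >
fluctuating priority. TMG3 is defined by persistence into P3; one
sometimes sees it phrased as a further intersection with the P4 contrast,
but P4 agreement is already part of robustness, so that phrasing would
collapse TMG3 onto TMG2 — persistence through the second recovery
generation is the definition implemented here.

# Trait reaction norms

Fisher's LSD is the unprotected pairwise procedure: one-way ANOVA pooled
MSE with $df = N - k$, pairwise
$t = (m_i - m_j)/\sqrt{MSE\,(1/n_i + 1/n_j)}$, no multiplicity correction.
The omnibus F is reported alongside so users who prefer the protected
variant can gate on it. When MSE is exactly zero the comparison is
degenerate and flagged: p is 1 for zero differences, 0 otherwise. Compact
letter displays are built greedily, visiting groups in descending mean
order and joining the first letter group whose members are all
non-different at the chosen level.

A trait is classified from its P4 reaction norm. With
$\Delta_{CK} = \bar y(\text{P1CK-P4S}) - \bar y(\text{P1CK-P4CK})$ and
$\Delta_{S} = \bar y(\text{P1S-P4S}) - \bar y(\text{P1S-P4CK})$, and $L$
the LSD p-value comparing the two stressed P4 groups across lineages:

* **weaken**: $\Delta_{CK} < 0$, $\Delta_S < 0$, $\Delta_S > \Delta_{CK}$,
  $L < 0.05$ — the stress-induced suppression is attenuated in the primed
  lineage;
* **strengthen**: $\Delta_{CK} > 0$, $\Delta_S > 0$,
  $\Delta_S > \Delta_{CK}$, $L < 0.05$ — the stress-induced rise is
  amplified;
* **unclassified** otherwise.

The two classes are deliberately not mirror images: weaken is an
*attenuated* response and strengthen an *amplified* one, so negating a
weaken trait produces an attenuated increase that matches neither
definition. The rule is invariant to positive affine rescaling (unit
changes). Earlier-stage (P1) dose–response behaviour is reported
descriptively but plays no role in the classifier. Relative qPCR
quantification is the standard $2^{-\Delta\Delta C_t}$ computation.

# Co-expression network

Expression for the DEG union is log2(x+1)-transformed and z-scored per
gene after dropping genes missing in more than half the samples or with
zero variance; this plays the role WGCNA's `goodSamplesGenes` plus limma
standardization play in a conventional workflow (quantile normalization is
not applied). The network is unsigned, $a_{ij} = |\mathrm{cor}_{ij}|^\beta$
with $\beta = 20$ by default, and similarity is the topological overlap
$\omega_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$.

Three numerical choices deserve note:

* **Scale-free fit.** Connectivities are binned into 10 equal-occupancy
  bins and the log empirical *density* (proportion divided by bin width)
  is regressed on log mean connectivity; with equal-occupancy bins the
  per-bin proportion is constant by construction, so the density carries
  the distribution. The index is signed ($-\mathrm{sign}(slope)\cdot R^2$).
* **Module detection.** Instead of WGCNA's dynamic hybrid tree cut we use
  a static cut of the average-linkage TOM dendrogram, choosing the scanned
  height (fractions 0.9999, 0.999, 0.995, 0.99, 0.98, … of the maximal
  merge height) that yields the most modules of at least `minModuleSize`
  (30) genes, ties resolved toward the higher cut. Scanning only from 0.99
  downward left up to 16% of genes unassigned at $\beta = 20$ on
  planted-block benchmarks; the near-top grid recovers planted structure
  exactly (adjusted Rand index 1.0 at $\beta$ 6 and 20). Modules whose
  eigengenes correlate at or above 0.75 (merge cut 0.25) are merged
  iteratively; unassigned genes are grey.
* **Eigengenes.** Per module, the first right-singular vector of the
  gene-centered submatrix, sign-aligned to the module's mean profile.

Module–trait association correlates eigengenes with per-sample trait
values; each RNA sample receives its group's trait mean, since trait
replicates are not paired with RNA replicates (n = 15 correlation points —
an approximation, and group means understate within-group trait noise).
Significance is `PCC > 0.5` and `p < 0.05` (t approximation, df = n − 2),
taking the threshold on the signed coefficient as stated; modules are
weaken-/strengthen-related according to their significant traits, largest
|PCC| winning conflicts. Edges are ranked by TOM weight and the top 30%
retained; degree on that filtered graph defines each module's top-10%
(ceiling) hub genes, ties broken by incident weight then gene id. The TMG
share of each module class is compared with a 2×2 Fisher exact test
(trait-related vs other × TMG vs not).

One behaviour of unsigned networks is worth flagging: up- and
down-regulated memory genes share $|\mathrm{cor}|$ structure and typically
land in one module, so a single "memory module" with a very high TMG
fraction is the expected outcome on synthetic data, rather than separate
up/down modules.

# The synthetic-data generator

`simulate_counts()` draws NB counts with mean
$\text{baseline} \times \text{libsize} \times 2^{\mathrm{lfc}}$, variance
$m + \phi m^2$. Defaults define the study conditions used throughout the
tests: 5000 genes, 3 replicates per group, baseline means log-uniform on
[20, 2000], dispersions log-uniform on [0.01, 0.5], library-size factors
uniform on [0.7, 1.4] (so normalization is actually exercised), base
effect 2 log2 units in P1 attenuated by 0.7 (P2) and 0.5 (P3) and
amplified by 1.2 (P4) for memory genes. Planted classes: 150 + 150 tmg3
(up/down), 100 + 100 tmg2-only (P3 multiplier 0), 200 transient (effect
only in S, alternating signs), 100 fluctuating (signs +,−,+,− across the
four contrast groups), remainder null. Effect sizes and class counts are
the package's own choices — the source study reports none — picked once so
that every class clears the |log2FC| > 0.5 gate in expectation at its
active stages.

`simulate_traits()` draws Gaussian replicates (default 6) around cell
means placed so that weaken traits drop by one effect unit under stress
and recover to 60%/30% deviation through P2/P3, with the primed lineage
showing half the naive drop on re-exposure; strengthen traits mirror this
upward with a 1.5× amplified primed response. Replicate noise defaults to
5% of the effect. `simulate_module_expression()` produces block-factor
expression (within-block correlation 0.8) for network benchmarks.

What the generator does *not* emulate: mean–dispersion coupling, gene–gene
correlation outside planted blocks, count outliers, batch effects,
library-composition bias, or any coupling between the planted trait norms
and specific genes beyond shared group structure. Green tests therefore
demonstrate correctness of the machinery under a clean NB world, not
robustness to every pathology of real RNA-seq.

# Power under the default conditions, honestly stated

With three replicates and dispersions up to 0.5, the P2 contrast (1.4 log2
units for memory genes) is the binding constraint on recovering planted
TMG2 genes. A Wald test given the *true* dispersions attains about 0.70
sensitivity for the TMG2 union, and DESeq2 on the full five-group design
about 0.72: genes in the upper dispersion range are simply undetectable at
this replication ($SE(\log_2 FC) \approx 0.83$ at $\phi = 0.5$). The
calibrated default engine lands at ~0.71 with FDR ≈ 0.01. Estimators that
understate variance can look more sensitive (the 50%-shrink variant
reaches 0.79) but only by breaking null calibration, which we decline to
do.

# Problem sizes

The bundled tests and the acceptance script run the default 5000-gene
design over 10 seeds, 2000-gene null calibrations, a 500-gene five-block
network benchmark, and 100–200-replicate Monte-Carlo loops for the trait
classifier — sizes chosen so the whole suite completes in well under a
minute per stage on a single core while keeping Monte-Carlo error small
relative to every asserted margin.

# Known limitations

* All contrasts share the single P1 control; generation effects and
  stage-matched controls are confounded by design.
* The Wald normal reference with plug-in dispersions is approximate at
  n = 3; calibration is verified by simulation rather than theory.
* Group-mean trait mapping inflates effective n in module–trait p-values.
* The static tree cut is simpler than WGCNA's dynamic hybrid cut and may
  fragment modules with nested structure; it is validated only on
  planted-block benchmarks.
* GO/functional enrichment of modules and memory genes is out of scope
  (it requires an external annotation database).
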