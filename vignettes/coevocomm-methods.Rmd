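---
title: "Statistical methods for coevolution community experiments"
author: "coevocomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for coevolution community experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevocomm)
```

# Scope

`coevocomm` implements the three bespoke statistical stages of a
predator–prey coevolution community experiment, in which replicate
populations of a focal prey bacterium evolve with or against a ciliate
predator and the surrounding multi-species community is profiled by
metatranscriptomics:

1. **Parallel molecular evolution** across replicate resequenced
   populations, via nucleotide and gene multiplicity statistics against
   uniform null models and an empirical-null critical-p FDR procedure.
2. **Species-resolved differential expression** for community
   transcriptomes, via within-taxon sum scaling, negative binomial GLMs
   with a taxon-abundance covariate, heavy-tailed shrinkage of log fold
   changes, a regularized log transform, and hypergeometric pathway
   over-representation.
3. **DiSTATIS compromise analysis** of per-taxon expression distance
   tables, with table bootstraps, k-means clustering with Krzanowski–Lai
   selection of k, and PERMANOVA/PERMDISP on the compromise scores.

A synthetic-data module generates inputs with exactly the statistical
structure these methods assume, so every claim below is validated by tests
that run from nothing but code and a seed.

# Parallel evolution statistics

## Multiplicity and the uniform nulls

For replicate populations $r = 1 \dots R$ carrying $n_r$ mutations on a
genome of $L$ sites, *nucleotide multiplicity* of a site is the number of
populations with a mutation there (by default the same alternative allele;
`match_alt = FALSE` relaxes to position only, since "the same mutation" can
reasonably mean either). Under uniform placement each population hits a
given site with probability $1 - (1 - 1/L)^{n_r}$, so the expected number
of sites with multiplicity $\ge k$ follows from the Poisson–binomial
distribution over populations; `nucleotide_null()` evaluates this closed
form and a Monte-Carlo p-value for the observed $N_k$ with the $+1$
correction $(1 + \#\{N_k^{sim} \ge N_k^{obs}\})/(B+1)$.

*Gene multiplicity* rescales gene $i$'s mutation count $n_i$ (pooled over
replicates) by gene length: $m_i = n_i \,\bar L / L_i$, so all genes share
the null expectation $\bar m = n_{tot}/G$ under length-proportional
placement over genic space. The evidence for parallelism is the
log-likelihood excess

$$\Delta\ell \;=\; \sum_i n_i \log (m_i/\bar m) \;=\; n_{tot}\,
\mathrm{KL}(\hat p \,\|\, p^0), \qquad
\hat p_i = n_i/n_{tot},\; p^0_i = L_i/\textstyle\sum_j L_j,$$

nonnegative and zero exactly at proportionality. The KL identity holds
when each variant hits one gene; a variant overlapping $k$ genes increments
each gene's $n_i$ while $n_{tot}$ counts unique variants (a documented
asymmetry — overlaps are rare in bacterial genomes and the alternative,
fractional attribution, would break the integer count model). Intergenic
variants are excluded from the gene-level $n_{tot}$, because
$\bar m = n_{tot}/G$ only holds over genic space.

Per-gene p-values are the Poisson survival function
$P(N \ge n_i)$ at $\lambda_i = n_{tot} L_i / \sum_j L_j$ (no mid-p
correction), or the $+1$-corrected tail of a multinomial re-placement null
(`method = "montecarlo"`). The two agree to about 1% absolute; they are
*not* identical, because the multinomial null conditions on $n_{tot}$ so
its per-gene marginal is Binomial$(n_{tot}, L_i/\sum L)$, whose tails the
Poisson approximation overstates by a relative factor growing with
$n_{tot} (L_i/\sum L)^2$. At $B = 10^5$ Monte-Carlo replicates this
systematic gap is resolvable (several MC standard errors); the package
keeps both methods and treats the Poisson form as the default analytic
approximation.

## The critical-p FDR procedure

Observed p-values are compared with a seeded ensemble of $B$ full null
p-vectors computed on the same catalog and $n_{tot}$. Scanning the unique
observed p-values $t$ in increasing order,

$$\widehat{\mathrm{FDR}}(t) = \frac{\text{mean}_b \#\{p^{null}_b \le t\}}
{\max(1, \#\{p^{obs} \le t\})},$$

and the critical value $p^\*$ is the largest $t$ with
$\widehat{\mathrm{FDR}}(t) < 0.05$ (none qualifying flags nothing). On 200
null datasets ($G = 1000$, $R = 3$, $n_{tot} = 150$) the realized
false-discovery proportion is $\approx 0.04$, within the Monte-Carlo band
of the nominal 0.05.

Because the per-gene counts are small and discrete, power changes in steps:
with an enrichment multiplier $\theta = 20$ on 10 of 1000 genes and
$n_{tot} = 300$, a target gene receives on average
$300 \times 20/1190 \approx 5.0$ mutations while the null rate is 0.3, and
the critical-p procedure admits genes with $\ge 4$ hits but not $\ge 3$;
the attainable per-gene recovery is therefore
$P(\mathrm{Pois}(5.0) \ge 4) \approx 0.74$ (measured 0.70 with
gamma-distributed gene lengths and ~10% intergenic DNA). Detecting
essentially all such targets requires either more mutations
($n_{tot} \gtrsim 400$) or stronger enrichment.

## Variant filters

Filtering is an explicit stage, not a side effect of reading: records in
the ancestor at frequency $\ge 0.95$ ("fixed"; the threshold is
configurable since no canonical value exists) are removed from every
population, then records below the 20% detection frequency are dropped.
The synthetic generator draws frequencies uniform on $(0.05, 1)$ so this
filter is genuinely exercised.

# Species-resolved differential expression

## Why within-taxon sum scaling

In a community transcriptome, a taxon that doubles in abundance doubles
every one of its genes' counts without any regulatory change. Library-size
normalization cannot remove this signal — worse, compositionally it smears
it across all other taxa. Within-taxon sum scaling (WTSS) normalizes each
gene against its own taxon's total: with $T_{t,s}$ the taxon-$t$ total in
sample $s$,

$$s_{t,s} = T_{t,s} \Big/ \Big(\prod_{s'} T_{t,s'}\Big)^{1/S},$$

so factors have geometric mean 1 across samples within each taxon and
enter the GLM as offsets $\log s_{t,s}$. Taxon-samples with zero totals
are excluded from that taxon's tests. In addition the amplicon-derived
relative abundance of the gene's taxon enters the design as a covariate,
$\log_2(\text{relabund} + 10^{-6})$, centered; it absorbs residual
DNA-template variation that the realized mRNA totals miss. When abundance
is confounded with a treatment, this covariate is nearly collinear with the
treatment coefficient — the fit then reports an honestly uninformative
(large-SE) treatment effect rather than a spurious one, which is exactly
the desired behavior under a confound. If a taxon's covariate is
numerically constant it is dropped from that taxon's design.

Sum scaling (unlike DESeq2's median-of-ratios) is not robust to genuinely
regulated genes: if a gene set with expression share $u$ is induced
$2^\delta$-fold, the taxon total inflates by $1 + u(2^\delta - 1)$ and all
log fold changes of that taxon shift down by the log of that factor. With
realistic shares ($u \lesssim 5\%$) the bias is $\lesssim 0.35$ log2
units; it is a property of the normalization the experiment prescribes,
and the recovery simulations below quantify it rather than hide it.

## Dispersions, tests, shrinkage

Per-gene NB dispersions ($\mathrm{Var} = \mu + \phi\mu^2$) are estimated by
method of moments on normalized counts, with the variance pooled within
design cells (predation × coevolved prey × day) so treatment effects do
not masquerade as biological dispersion; a robust $a/\mu + b$ trend is
fitted across genes (`MASS::rlm`) and log-dispersions are shrunk toward
the trend with weight $\sigma^2_{samp}/(\sigma^2_{samp} + \sigma^2_{prior})$,
the sampling variance taken as $2/\mathrm{df}_{resid}$ and the prior
variance as the MAD² of the residuals (floored at 0.1). Genes at or below
the Poisson limit take the trend value. On simulations with true
$\phi = 0.1$ at high counts the median estimate lands within $[0.05, 0.2]$.

Each gene is fitted by IRLS (`stats::glm.fit` with a fixed-θ negative
binomial family, log link, WTSS offsets). The Wald statistic
$\hat\beta/\widehat{SE}$ is referred to a Student-t with the fit's residual
degrees of freedom rather than the normal limit: with 12 samples and 5
coefficients the SE is itself noisy, and the t reference measurably
improves calibration (KS distance from uniform 0.025 vs 0.037 on a
2000-gene null simulation) while keeping the far tail honest. BH
adjustment is joint across all tested genes of all taxa (the treatments
act on the whole community, and a joint FDR is interpretable at the
community level; a per-taxon mode exists). Non-converged genes are
excluded from adjustment. The DE call is `padj < 0.1` and
`|shrunken LFC| > 2`.

Fold changes are moderated by a posterior mode under a Cauchy
(Student-t, df 1) prior on the contrast coefficient. The prior scale is
the median exceedance $\sqrt{\max(\hat\beta^2 - SE^2, 0)}$ over genes
(floored at 0.05 when no gene exceeds its SE): a heavy-tailed prior leaves
strong signals essentially untouched ($|\hat\beta| \gg SE$) while pulling
noise to zero. The 1-D posterior mode is found by a coarse grid bracketed
`optimize()`; a grid-search oracle in the tests confirms it to $10^{-5}$.

## rlog, gene selection, inclusion, enrichment

The regularized log transform shrinks per-gene log2 normalized counts
toward the gene's intercept: $y_{g,s} = \log_2((K_{g,s}+0.5)/s_{t(g),s})$,
$\mathrm{rlog}_{g,s} = \bar y_g + w_g (y_{g,s} - \bar y_g)$ with
$w_g = 1/(1 + \phi_g c)$. The constant $c$ is the median positive
normalized count: genes measured near or below that depth — whose trend
dispersion is large — shrink strongly, while well-measured genes keep
$\mathrm{rlog} \approx y$. The transform is monotone within a gene and
never increases the across-sample variance.

Per taxon, the `n = 500` most variable rlog genes (ties broken by gene id,
so selection is order-stable) feed the ordination; taxa must exceed 0.5%
of total counts in *every* sample to be analyzed (the stricter reading of
"per sample"; a mean-share mode exists). Pathway over-representation of a
DE set uses the hypergeometric tail $P(X \ge x)$ with BH across pathways
and an enrichment call at adjusted p < 0.05.

# DiSTATIS

Each taxon's distance table ($D_k$, Euclidean on its rlog submatrix) is
converted to a normalized cross-product
$\tilde S_k = -\tfrac12 \,\Xi D_k^{(2)} \Xi^\top / \lambda_1$, with
$\Xi = I - \mathbf 1 m^\top$ and uniform masses (none are given by the
design). Table weights $\alpha$ are the first eigenvector of the RV
congruence matrix $C_{jk} = \langle \tilde S_j, \tilde S_k\rangle /
(\|\tilde S_j\| \|\tilde S_k\|)$, sign-fixed nonnegative, scaled to sum 1.
The compromise $S^+ = \sum_k \alpha_k \tilde S_k$ is eigendecomposed;
factor scores are $F = V\Lambda^{1/2}$ and each table's partial scores
$F_k = \tilde S_k V \Lambda^{-1/2}$, so $\sum_k \alpha_k F_k = F$ exactly
(asserted to $10^{-10}$ on every run). Axis signs follow the
largest-magnitude-loading-positive convention so plots and tests are
reproducible. With identical tables the procedure reduces exactly to
classical MDS of the shared table — the package's exactness oracle.

Uncertainty comes from resampling the *tables* (species transcriptomes)
with replacement, recomputing $\alpha$ and the compromise, and projecting
onto the reference axes; each sample's bootstrap cloud on axes 1–2 is
summarized by a 95% normal-approximation ellipse. Resampling tables (not
samples) is the choice consistent with "compromise bootstraps": the
uncertainty quantified is in how individual species' structures combine.

Cluster number: k-means (25 seeded restarts per k, k in 2..min(8, n−2))
scored by the Krzanowski–Lai index
$\mathrm{KL}(k) = |\mathrm{DIFF}(k)/\mathrm{DIFF}(k{+}1)|$,
$\mathrm{DIFF}(k) = (k{-}1)^{2/p} W_{k-1} - k^{2/p} W_k$; on three
well-separated Gaussian blobs the index selects $k = 3$ in ≥ 95/100 seeds.

PERMANOVA uses the squared-distance decomposition ($SS_T = \sum d^2/N$,
within-group analogues) on Euclidean distances over the leading compromise
axes cumulatively explaining 99% of variance; the p-value is the
$+1$-corrected tail over free label permutations, or the exact enumeration
over all distinct assignments for small two-group designs (the 6-sample
toy yields exactly $2/20$). PERMDISP embeds the distances by principal
coordinates, computes distances to group centroids, and permutes those
distances under an ANOVA F — the same scheme as vegan's `betadisper`
(centroid type), against which the F statistic is cross-checked in tests.

# The synthetic-data generator

`simulate_genome()` places gamma-length genes (default mean 900 bp, shape
10 — a realistic bacterial gene-length distribution) left to right with
random intergenic gaps on a single contig (multi-contig structure adds
nothing to any statistic here). `simulate_mutations()` drops each
population's mutations with per-bp weight 1, times $\theta$ inside target
genes, collapsing repeated hits within a population; $\theta = 1$ is the
exact uniform null (verified by chi-squared screens across seeds).
Frequencies are uniform on $(0.05, 1)$ so the 20% filter acts.

`simulate_community()` draws NB counts with expected value
$\text{libsize}_s \times A_{t(g),s} \times q_g \times 2^{x_s^\top\beta_g}$:
compositional taxon abundances $A$ (optionally shifted by treatment — the
confound), within-taxon relative expression $q$ (log-normal, normalized per
taxon), per-gene dispersions from a gamma (default mean 0.05, shape 4,
typical of RNA-seq), log-normal library sizes, and log2 effects attached
to the predation, coevolution, or interaction coefficient. The amplicon
table is $A$ observed with Dirichlet noise (default concentration 5000,
i.e. ~2% relative error — amplicon estimates are precise but not exact).
All draws flow from one seeded stream per call and leave the global RNG
untouched; identical seeds give bit-identical outputs.

What the generator does *not* emulate: rRNA contamination, mapping
ambiguity between related genomes, zero inflation beyond NB sampling,
phylogenetic correlation between taxa, and time-series dynamics between
sampling days. Passing tests therefore validate the statistical machinery
under the model's own assumptions, not robustness to these violations.

# Numerical and design notes

- Problem sizes in the validation suite: 200 null datasets for FDR
  calibration ($G = 1000$, $n_{tot} = 150$), 50 enrichment datasets for
  power, 2000-gene null and 4500-gene recovery simulations for DE (three
  replicates per cell, one day), $10^5$-replicate Monte-Carlo oracles for
  the closed forms, 100 seeds for cluster-number selection. These sizes
  give Monte-Carlo error well below each property's tolerance.
- Degenerate inputs error early and by name: all-zero distance tables,
  all-zero taxa, rank-deficient designs (aliased columns listed),
  singleton PERMANOVA groups, catalogs whose genes cannot fit the genome.
- Ties: top-variable selection breaks ties lexicographically; the
  critical-p scan visits unique observed p-values in increasing order;
  eigenvector signs are fixed by the largest loading.
- The pipeline (`run_all()`) derives per-stage seeds from one global seed
  and a stage-name hash, writes all tables with a version-stamped comment
  line, and reruns byte-identically; days are analyzed separately
  throughout, matching the experimental design.
- Known limitations: WTSS's sensitivity to large regulated expression
  shares (quantified above); Poisson-vs-multinomial discrepancy in deep
  per-gene tails (documented above); bootstrap ellipses assume a locally
  normal cloud; PERMANOVA assumes exchangeability under free permutation
  (no strata for replicate structure in v1).
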