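---
title: "Hitting-time inference on phenotype-gene networks: models, parameters and design"
author: "cipherhit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hitting-time inference on phenotype-gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package operates on a *heterogeneous network*: one undirected,
weighted graph merging three layers,

* a protein-protein interaction (PPI) network over genes, every
  interaction carrying weight 1;
* a phenotype-phenotype similarity network, keeping only pairs whose
  text-mining-style similarity score is **strictly greater than** the
  threshold `sim_threshold` (default 0.4) and using the score as the
  edge weight;
* gene-phenotype association edges.

The association edge between gene $g$ and phenotype $p$ is weighted

$$w(g,p) \;=\; \sqrt{\frac{s_G(g)}{k_g}\cdot\frac{s_P(p)}{k_p}},$$

where $s_G(g)$ is the total PPI weight at $g$, $s_P(p)$ the total
similarity weight at $p$, and $k_g$, $k_p$ the association counts of the
two endpoints. When both endpoints carry a single association this makes
the *average* probability of stepping onto the other sub-network at $g$
and at $p$ exactly $1/2$ — the design contract of the weighting — and
approximately $1/2$ otherwise. The identity is exact algebra: with
$a=s_G$, $b=s_P$ and $w=\sqrt{ab}$,
$\tfrac12\!\left(\frac{w}{w+a}+\frac{w}{w+b}\right)=\tfrac12$. When an
endpoint has zero within-layer strength the weight falls back to 1 (and
is logged); such pairs are excluded from the contract diagnostic. After
merging, the network is restricted to its largest connected component so
that every hitting time below is finite.

A random walk on the merged weight matrix $W$ has transition matrix
$P(i,j)=W(i,j)/\sum_{j'}W(i,j')$. All inference is built from two
closeness measures:

* **Scaled mean hitting time.** $E_a[\tau_B]$, the expected number of
  steps for the walk started at $a$ to first visit the node set $B$, is
  the minimal nonnegative solution of a linear system (identity on $B$,
  $x = 1 + Px$ elsewhere), solved here as one sparse direct solve over
  the non-target rows. Raw expectations are divided by the largest
  finite value over *all* nodes of the network, so the closeness
  MHT$(a,B)$ lies in $[0,1]$ with the farthest node at exactly 1.
* **Scaled conditional mean hitting time.** CMHT$(a,B\mid A)$ is the
  expected time to reach $B$ conditioned on reaching $B$ before the
  avoid set $A$. It is computed through the harmonic potential
  $h(v)=\mathbb{P}_v(\tau_B<\tau_A)$ (boundary-value system: 1 on $B$, 0
  on $A$, harmonic elsewhere) and the Doob h-transform: with $y=h\cdot
  x$, $y$ solves $(I-P_{II})\,y_I = h_I$ over the interior, and
  $x=y/h$ wherever $h>0$. Starts with $h=0$ cannot satisfy the
  conditioning event; their value is explicitly *undefined* (`NA`),
  excluded from the scaling maximum, and ranked after all defined
  values downstream. Simulation is never used on the main path — the
  Monte-Carlo and path-space enumeration routines exist only as
  independent oracles for testing.

## Prioritization and the modularity level

For a target phenotype $p$, its *adjacency set* $U(p)$ holds its known
disease genes and the phenotypes connected by a retained similarity
edge; every walk into $p$ crosses this set. Candidate genes are ranked
by MHT$(g,\{p\})$ ascending (ties broken by gene label, so reruns are
bit-identical). The *modularity level* of an adjacent node is

$$M_p(u_i) \;=\; \min_{u_j \in U(p)\setminus\{u_i\}}
  \mathrm{CMHT}(u_i, \{u_j\} \mid \{p\}),$$

the scaled conditional closeness to its best-connected companion,
excluding walks through $p$ itself. Small values mean $u_i$ sits in a
tight module with other references. The walk runs from $u_i$ towards
the companion (not the reverse), the aggregate over companions is the
minimum, and the scaled (not raw) variant is used so that the threshold
$\theta_M$ is meaningful on $[0,1]$. Thresholding at $\theta_M$ (default 0.3) splits $U(p)$ into
the credible references `U_high` ($M_p<\theta_M$; nodes with undefined
$M_p$ go to `U_low`).

A gene is *prioritized* when MHT$(g,\{p\})<\theta_R$. The automatic
$\theta_R$ is the *critical point* of the empirical distribution
function of the scores, operationalized as the knee: the abscissa
maximizing the perpendicular distance between the ECDF and the chord
joining its endpoints. On degenerate ECDFs (all scores equal, or
indistinguishable from the chord) the selector refuses and asks for an
explicit threshold; an explicit value always overrides. A gene is
*credible* when it is prioritized and its rank strictly improves once
closeness is measured to `U_high` while avoiding `U_low`
(RANK/RANK$'$ > 1).

## Subtype detection

The feature of gene $g$ against adjacent node $u_i$ is
$c_p(g,u_i)=\mathrm{CMHT}(g,\{u_i\}\mid U(p)\setminus\{u_i\})$ — the
closeness through the channel of $u_i$ only. The phenotype itself is not
added to the avoid set: its neighbourhood *is* $U(p)$, so any walk
reaching $p$ first has already crossed the avoid set. Genes associated
with $p$ are degenerate columns (they sit inside the avoid set of every
other row), so the subtype pipeline analyses candidate genes *not*
adjacent to $p$; a gene is retained for clustering when it is close
(below `min_attachment`, default $\theta_M=0.3$) to at least a quarter
of the adjacency set — the column-wise analogue of a high modularity
level — and, symmetrically, an adjacent node is retained only when at
least a quarter of the retained genes are close to it (a loosely
attached disease gene carries no sub-module information and would
otherwise dominate the row clustering as an outlier). Retained columns
(and rows) are clustered agglomeratively:
Euclidean distance on the bounded features, average linkage, undefined
entries imputed to 1 (maximally distant); all three choices are
arguments. The two-way reordering exposes the block structure; the
default cut yields 2 gene groups, and `n_groups = "auto"` chooses the
cut in $2..\min(6,k-1)$ by average silhouette width.

The gene *sub-modules* themselves are derived from the adjacent-node
groups rather than read off the raw column dendrogram: each node group
leads to the gene group attached to it (smallest mean closeness), and a
gene whose best and second-best group closeness differ by less than a
factor of two stays *unassigned*. The motivation is empirical: real and
simulated networks contain genes genuinely attached to several
sub-modules at once, and any forced $k$-way cut lets them glue the
clean blocks together; leaving them out reproduces the practice of
reading only the coherent blocks of the reordered matrix. The raw
column clustering is still reported (`gene_groups_all`), as is the
cross-block mean closeness matrix; no pairing rule between row and
column dendrograms is asserted beyond the attachment itself.

Topological separation of the resulting gene groups is tested per
subgroup with a one-sided Fisher's exact test on the $2\times 2$ table
of gene pairs (within vs between the subgroup, similar vs dissimilar),
where a pair is *similar* when its scaled pairwise mean hitting time —
symmetrized as the minimum of the two directed values; the mean is a
config switch — falls below a threshold. By default that threshold is
the ECDF knee of the pair statistics themselves: it is label-independent
(so the Fisher conditioning is untouched), and unlike the
prioritization threshold it lives on the same scale as the statistic it
binarizes. On desk-scale networks the two scales differ noticeably;
passing the prioritization $\theta_R$ explicitly reproduces the
published usage.

## Cross-validation

Every gene-phenotype association is one validation case: the edge is
removed, association weights are recomputed (the counts $k_g$, $k_p$
change), the requested mode's score is recomputed for all genes, and
the held-out gene's score and rank are recorded. A case *succeeds at
threshold $\theta$* when its score is strictly below $\theta$ (at the
grid maximum $\theta\ge 1$ the comparison is inclusive). The ROC plots
sensitivity against the threshold itself as the abscissa — a sweep of
the prioritization cutoff, not a per-case false-positive fraction; a
conventional score-based ROC can be derived from the per-case table.

Modes: `all_adjacent` scores by MHT$(\cdot,\{p\})$; `modular_high` by
CMHT$(\cdot,$ `U_high` $\mid$ `U_low`$)$; `low_only` by the mirror
image; `rwr_baseline` by a random walk with restart (restart rate 0.7,
the conventional value — the baseline exists to show the contrast with
the parameter-free hitting-time measures), converted to a rank-percentile
loss so it shares the threshold axis. When the partition of a case is
trivial (`U_high` or `U_low` empty) there is no modularity contrast:
neither partition mode makes a prediction and the case fails at every
threshold, *symmetrically for both modes*. An asymmetric fallback (e.g.
scoring by plain MHT) was rejected because it silently turns one mode
into full-adjacency inference wherever the other side of the partition
is empty, corrupting the comparison. A removal that disconnects the
held-out gene censors the case (failure at all thresholds, flagged).

## The synthetic generator

The generator emulates the modularity premise of disease genetics —
similar phenotypes are caused by functionally related genes that sit
close together in the interactome — with planted, known structure:

* **PPI layer**: a sparse Erdős–Rényi background
  (`p_background = 0.01`) with dense planted modules
  (`p_within = 0.9`, `module_size = 12`). Degree contrast is essential:
  when every gene has similar total degree, the effective resistance
  between any two nodes approaches the sum of their degree reciprocals
  and scaled hitting times plateau near 0.5 for module mates and
  strangers alike. Modules must be dense *relative to a sparse
  background* for the method's own modularity statistic to see them.
* **Phenotype layer**: clusters of 10 mutually similar phenotypes;
  scores drawn from normals (within-cluster mean 0.6, background mean
  0.2, sd 0.1) clipped to $[0,1]$, so the 0.4 threshold separates the
  two populations imperfectly on purpose.
* **Target structure**: the target phenotype (first of its cluster) has
  two subtypes, each owning one module. A module's first 8 genes are
  disease genes of the target; 4 companion phenotypes per subtype from
  the target's similarity cluster each share a block of those disease
  genes (the pattern of a gene associated with both the disease and a
  related syndrome) and adopt module genes beyond the disease set as
  their own — the latter carry a single association each, which
  realizes the exact-0.5 cross-walk geometry. Four extra disease genes
  are drawn from outside all modules (the loosely attached adjacent
  nodes that populate `U_low`).
* **Global modularity**: every other phenotype cluster also owns one
  gene module and its phenotypes associate with genes of that module
  (1 to 3 each). Without this, genome-wide cross-validation is
  dominated by structureless cases in which neither reference mode can
  work, which measures nothing about the modes.
* **Null preset**: same sizes, but nothing planted — module density
  equals background *and* association wiring is randomized. Ablating
  only the PPI density would leave subtype signal in the two-hop
  gene-phenotype-gene paths through the companions.

All randomness flows through the single mandatory seed; identical specs
produce byte-identical files. What the generator does *not* emulate:
scale (hundreds of genes, not the $\sim$13,500 nodes of a real
gene-phenotype compendium — absolute values of scaled closeness, and
hence useful thresholds, shift with scale), scale-free degree
distributions, weighted interactions, and annotation noise beyond the
random background wiring. Tests passing on these networks demonstrate
the machinery and its qualitative claims (modular references beat
non-modular ones; planted sub-modules are recoverable; the separation
test does not hallucinate structure), not performance on real
compendia.

## Numerical choices and degenerate inputs

* Direct sparse LU (`Matrix::solve`) on the restricted systems; at the
  problem sizes used here (hundreds of nodes, hundreds of systems per
  analysis) each solve is sub-millisecond, so no iterative fallback is
  engaged.
* Before every solve the system is restricted to nodes from which the
  boundary is reachable; unreachable starts get $+\infty$ (unconditional)
  or undefined (conditional). This also keeps edge-removal during
  cross-validation safe when it splits the graph.
* Scaling maxima are exact: the argmax is set to 1.0, not to a rounded
  quotient.
* Rank ties break by node label; all reported tables are sorted, so
  identical inputs give identical bytes.
* `select_theta_r` requires at least 10 finite scores, a non-constant
  ECDF and a knee distance above $10^{-3}$.
* Duplicate input edges collapse to the maximum weight with a warning;
  self-edges are dropped with a warning; gene symbols are upper-cased,
  phenotype accessions kept verbatim.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
the generator's default conditions (200 genes, 40 phenotypes): 20-seed
replications for the cross-validation comparison and subtype recovery,
50 (tests) / 20 (script) seeds for the null calibration, and
10-seed replications for the script's cross-validation summary. These
sizes give stable qualitative outcomes on a single CPU in minutes while
exercising every code path; they are the package's chosen study
conditions, not estimates of real-data runtime.

## Known limitations

* The ECDF-knee threshold is sensitive to small outlier masses on small
  networks (a handful of directly associated genes can anchor the
  chord); the explicit override exists for exactly this case.
* Scaled closeness values are network-size dependent, so $\theta_M$ and
  $\theta_R$ defaults carry meaning relative to the network they were
  defined on; on much smaller or larger networks they should be
  re-examined against the relevant ECDFs.
* The conditional closeness of a gene to an adjacent node is undefined
  whenever the gene cannot reach it before the rest of the adjacency
  set; dense adjacency sets therefore produce sparse feature matrices,
  which is why imputation-to-1 and the attachment filter exist.
* Hitting times are asymmetric; the pairwise symmetrization (min by
  default) is a modelling choice, switchable to the mean.
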