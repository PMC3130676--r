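# cipherhit

Random-walk hitting-time inference on phenotype–gene heterogeneous
networks: credible disease-gene prioritization through a modularity
statistic, and detection of disease subtypes as sub-modules of the
prioritized genes.

## The problem

Candidate disease genes are routinely ranked by their closeness, on a
merged network of protein–protein interactions, phenotype–phenotype
similarities and gene–phenotype associations, to what is already known
about a disease: its genes and its similar phenotypes (the *adjacency
set* U(p) of the target phenotype p). Two questions follow. First, not
every known reference is equally trustworthy — references that form a
tight module with each other support credible predictions, scattered
ones do not. Second, when the references split into several tight
groups, the prioritized genes may split accordingly, suggesting genetic
subtypes of the disease. `cipherhit` addresses both with one
parameter-light closeness measure, the scaled mean hitting time of the
random walk, and its conditional variant.

## The measures

For a walk with transition matrix `P(i,j) = W(i,j)/Σ_j' W(i,j')`:

* **MHT(a, B)** — the expected number of steps to first reach the node
  set B from a, solved exactly as a sparse linear system and scaled by
  the maximum over all nodes, so values lie in [0, 1] (small = close).
* **CMHT(a, B | A)** — the expected time to reach B *conditioned on
  reaching B before A*, computed via the harmonic potential
  h(v) = P_v(τ_B < τ_A) and a Doob h-transform; undefined (NA) where
  h = 0.
* **Modularity level** `M_p(u) = min_{u'} CMHT(u, {u'} | {p})` — how
  easily an adjacent node reaches its best companion without passing
  through the phenotype. Thresholding at θ_M (default 0.3) splits U(p)
  into credible references `U_high` and the rest.
* A gene is **prioritized** when `MHT(g, {p}) < θ_R` (θ_R chosen at the
  knee of the score ECDF, or given explicitly) and **credible** when
  its rank strictly improves once closeness is measured to `U_high`
  avoiding `U_low`.
* The association edge between gene g and phenotype p carries weight
  `w(g,p) = sqrt((s_G(g)/k_g) · (s_P(p)/k_p))`, which makes the average
  probability of stepping across sub-networks at the two endpoints
  exactly 0.5 for single-association pairs.

Subtypes: the feature `c_p(g, u_i) = CMHT(g, {u_i} | U(p)\{u_i})`
measures the closeness of a gene to one reference with the influence of
all others removed; two-way hierarchical clustering of that matrix
yields gene sub-modules, whose topological separation is tested per
subgroup by a one-sided Fisher's exact test on similar/dissimilar gene
pairs within versus between subgroups.

## A worked example

The package ships a seeded generator of heterogeneous networks with
planted disease modules and subtypes, so everything below is
reproducible offline:

```r
library(cipherhit)

s   <- synth_hetnet(synthetic_spec("default", seed = 1))
net <- s$net
net
#> Phenotype-gene heterogeneous network
#>   nodes: 177 genes, 40 phenotypes
#>   edges: 486 PPI, 186 similarity, 115 association
#>   2 node(s) removed outside the main component
#>   mean cross-walk probability (single-association pairs): 0.500000

fit <- cipher_hit(net, "PH01", theta_r = 0.6)
fit
#> CIPHER-HIT prioritization for phenotype PH01
#>   theta_r = 0.6 (manual), theta_m = 0.30
#>   177 candidate genes: 55 prioritized, 29 credible
#>   adjacency: |U_high| = 25, |U_low| = 4
```

The network's 25 modular references (`U_high`) are the planted subtype
modules and their companion phenotypes; the 4 loosely attached disease
genes land in `U_low`. The per-gene table (`fit$genes`) holds the
scaled hitting time `mht`, its rank, the conditional score to `U_high`,
the second rank, and the prioritized/credible flags; genes whose
conditional score is undefined (they cannot reach `U_high` before
`U_low`) rank last.

```r
st <- cipher_subtypes(net, "PH01")
st
#> Sub-module clustering (phenotype PH01)
#>   2 gene groups (14/12 genes); 2 adjacent-node groups
#>   G1: G009, G010, G011, G012, G069, ...
#>   G2: G021, G022, G023, G024, G073, ...
st$separation
#>   group within_high within_low between_high between_low  p_value
#> 1     1          21         70            0         168 5.43e-11
#> 2     2          30         36            0         168 8.56e-20
```

The two recovered sub-modules contain exactly the two planted subtype
modules (genes G009–G012 belong to the first planted module, G021–G024
to the second), and both are topologically separated at p < 1e-10.

Leave-one-out cross-validation quantifies the value of the modular
references — scoring held-out disease genes against `U_high` clearly
beats scoring them against `U_low`:

```r
cv <- loocv(net, modes = c("modular_high", "low_only"),
            phenotypes = "PH01")
cv
#> Leave-one-out cross-validation: 20 cases
#>   modular_high  AUC = 0.8417
#>   low_only      AUC = 0.4550
```

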