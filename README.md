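# pminr

Network regression for case–control studies of biological networks, with
**pointwise mutual information (PMI) edge features**.

## The problem and who this is for

Given a known network topology over p measured biomolecules (a pathway, a
co-expression module, a methylation network), a samples-by-nodes matrix,
optional covariates and a binary outcome, `pminr` asks three questions in
one model:

* is the **whole network** associated with the outcome?
* which **nodes** (levels of individual molecules) drive the association?
* which **edges** (strengths of pairwise connections) drive it?

It does so by fitting the logistic network regression

```
logit P(Y = 1) = β₀ + Σₛ αₛ Zₛ + Σᵢ βᵢ xᵢ + Σ_{i<j} I_ij γ_ij E_ij
```

where `I_ij` indicates membership of the edge set and `E_ij` is a
*per-individual* edge feature. The primary choice of `E_ij` is the kernel
estimate of the pointwise mutual information

```
PMI(x, y) = log p(x, y) − log p(x) − log p(y)
```

evaluated at each individual's own pair of values, with the joint density
from bivariate normal-kernel density estimation (diagonal Scott
bandwidths) and marginals from the univariate analogue. PMI is zero
exactly under independence and responds to linear *and* nonlinear
dependence, so edge tests keep power when relationships are quadratic or
sinusoidal. A product-moment variant (`method = "product"`, edge feature =
standardized node cross-product, the per-individual Pearson summand) is
included as the linear baseline. Inference: per-term Wald tests
(`z = estimate/se`, normal reference) and a global likelihood-ratio test
of all node + edge terms on `p + |edges|` degrees of freedom. A
Monte-Carlo harness reproduces the type-I error / power study design
(four dependence scenarios × five effect situations) on a packaged
26-node / 37-edge pathway topology.

Intended users: statistical-genomics and systems-biology analysts who
have a pathway and a case–control matrix and want node- and
edge-resolved association tests with covariate adjustment.

## Worked example

```r
library(pminr)
library(dplyr)

net <- insulin_resistance_network()   # packaged 26-node / 37-edge topology
net
#> <network_topology: 26 nodes, 37 edges>

# one synthetic case-control dataset: quadratic dependence on a random
# edge, effects on node X8 (β = 0.3) and edge X7~X8 (γ = 0.2)
cfg <- sim_config("quadratic", "node_edge_on_edge", n = 400, replicates = 1)
d <- simulate_network_data(cfg, seed = 7)

fit <- fit_pminr(d, net, response = "y", method = "pmi")
fit
#> <pminr_fit: PMI edge features, 400 individuals, 26 nodes, 37 edges>
#> global network LRT: statistic 88.329 on 63 df, p = 0.01935
#> 2 node/edge term(s) with Wald p < 0.05

tidy(fit) |> filter(role != "intercept") |> arrange(p.value) |> head(3)
#>   term    role  estimate std.error statistic    p.value
#> 1 X8      node     0.539     0.111      4.84 0.00000129
#> 2 X18~X19 edge     0.921     0.412      2.24 0.0252
#> 3 X24     node    -0.298     0.160     -1.86 0.0630
```

Reading this: the global test rejects (p = 0.019), so the network as a
whole carries outcome information; the planted node effect on `X8` is
recovered decisively (p = 1.3e-6). The planted quadratic edge effect on
`X7~X8` is missed in this single n = 400 draw (p = 0.62) — edge effects
need larger samples, which is exactly what the power curves from
`run_operating_characteristics()` quantify (PMI edge power ≈ 0.95 at
n = 600 under this scenario, versus ≈ 0.01 for the product-moment
baseline). `glance(fit)` gives the one-row summary, `autoplot(fit)` the
per-term evidence plot.

A command-line front end wraps the same functionality:

```sh
Rscript inst/cli/pminr.R fit --matrix data.tsv --network edges.tsv \
    --response status --method pmi --out results.tsv
Rscript inst/cli/pminr.R simulate --config sim.yaml --seed 42 --out oc.tsv
```

Every run writes a JSON manifest (seed, config hash, package version)
next to its output. Published cohort analyses (GEO GDS2771 lung-cancer
expression; ROSMAP methylation) are supported as a documented recipe over
user-downloaded data — see `real_data_recipe()`; no downloader is
shipped.

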