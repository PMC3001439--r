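# diffanno

Enzyme function annotation by competitive label diffusion over
protein-similarity networks.

Structural genomics yields protein structures whose molecular function is
unknown. Local structural-template matching links such chains to chains of
known function, but each match is noisy local evidence. diffanno turns the
full set of pairwise matches into a weighted network and propagates
Enzyme Commission (EC) annotations globally: for each candidate function,
evidence labels diffuse link by link, every unannotated chain gets a
confidence z-score for every function, and the highest z-score wins. The
package is for computational biologists benchmarking annotation-transfer
strategies and for anyone with a table of pairwise structure-match scores
and a partial annotation table.

## The model

Reciprocal template matches between chains *i* and *j* (A matched B and B
matched A) become edges weighted by match quality,

    w_ij = logistic( ( (mu_rmsd - rmsd_ij)/sigma_rmsd
                     + (mu_ET  - ET_ij )/sigma_ET ) / 2 )  in (0, 1),

standardized against the full match table (population moments), so
better-than-average matches weigh more than 0.5. For one candidate
function, prior labels y_i ∈ {+1, −1, 0} (has it / has another function /
unknown) diffuse by minimizing the Laplacian-regularized quadratic cost

    sum_i (f_i - y_i)^2 + alpha * sum_{i<j} w_ij (f_i - f_j)^2,

i.e. solving the sparse SPD system `(I + alpha L) f = y`, `L = D − W`.
Diffused values at unlabeled nodes are normalized into z-scores,
`z_i = (f_i − mean_u f) / sd_u f`, which removes label-frequency bias and
makes functions of different prevalence comparable at one node; the
function with the highest z at a query is its annotation. A weighted
nearest-neighbor baseline, confidence-stratified accuracy/coverage and
sensitivity/precision curves, a negative-label ablation, path-length
diagnostics, and a planted-partition benchmark generator complete the
toolkit.

## Worked example

```r
library(diffanno)

sim <- planted_network(planted_config(seed = 11))   # 5 functions x 30 chains
net <- match_network(sim$matches)                   # reciprocal, weighted
net
#> Similarity network: 150 nodes, 710 edges (reciprocal matches only)
#>   weights in [0.027, 0.733]

fit <- ec_diffusion(net, sim$labels, queries = sim$queries)
fit
#> Competitive diffusion annotation (EC level 4, alpha = 1)
#>   75 queries, 5 candidate functions, holdout = batch, with negative labels
#>   confidence z in [1.507, 2.217]; 0 isolated queries

head(predict(fit), 3)
#>    node     fun confidence    method isolated
#> 1 c001A 1.1.1.1   2.092715 diffusion    FALSE
#> 2 c002A 1.1.1.1   2.088121 diffusion    FALSE
#> 3 c004A 1.1.1.1   2.092272 diffusion    FALSE

curve <- accuracy_coverage_curve(fit$predictions, sim$truth, level = 4,
                                 test_size = length(sim$queries))
tail(curve, 2)
#>    threshold tp fp fn accuracy  coverage sensitivity precision
#> 74  1.662906 74  0  1        1 0.9866667   0.9866667         1
#> 75  1.506838 75  0  0        1 1.0000000   1.0000000         1
```

Every query recovers its planted function (accuracy 1 down to full
coverage); the z-scores near 2 say each winning function stands about two
population standard deviations above the unlabeled background. On bridge
topologies — query chains whose direct neighbors are all unlabeled —
`nn_annotate()` returns nothing while `ec_diffusion()` still reaches the
labeled cluster two hops away (`bridge_fixture()` demonstrates this).

A command-line wrapper with subcommands `simulate`, `build-graph`,
`predict`, `nn-predict`, `evaluate`, `ablate`, `path-hist` and
`sweep-alpha` is installed at `inst/cli/diffanno.R`:

```sh
Rscript inst/cli/diffanno.R simulate --seed 7 -o bench
Rscript inst/cli/diffanno.R build-graph --matches bench.matches.tsv -o net
```

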