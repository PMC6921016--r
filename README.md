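# subcomplex

Protein complexes are catalogued as flat subunit lists, but their subunits
are not all in direct physical contact. `subcomplex` is an R package for
researchers studying complex architecture: it predicts which co-complexed
gene pairs are **direct (physical) contacts** versus **indirect
interactions**, and then partitions each complex into **sub-complexes**.

The framework has two phases:

1. **Direct-contact classification.** Within-complex gene pairs are encoded
   over the GO term universe *G* as sparse {0,1,2} vectors (component *g* is
   2 when both genes carry term *g*, 1 when one does), once from the genes'
   own annotations (*target instance*) and once from homolog-transferred
   annotations (*homolog instance*). An L2-regularized logistic regression
   minimizing ½ωᵀω + C Σᵢ log(1 + exp(−yᵢ ωᵀxᵢ)) is trained on both
   instances. Negatives are sampled from co-complexed non-edges under a
   shortest-path constraint: *no-path* pairs and *no-less-than-two* pairs
   (distance ≥ 2) mixed at ratio λ (default 4:1). Each pair's decision value
   is the larger-magnitude instance confidence m = P(+1|x) − 0.5, filtered
   by a threshold δ into +1 / −1 / undetermined.
2. **Substructure inference.** Each complex's predicted contact network is
   triaged by connection degree 2M/(N(N−1)): partially connected complexes
   are partitioned by greedy **maximum modularity clustering** (best-merge
   coarsening plus Kernighan–Lin-style single-vertex refinement of
   Q = Σᵢ [f(Cᵢ,Cᵢ)/f(V,V) − dev(Cᵢ)²/dev(V)²]); fully connected complexes
   are partitioned by average-linkage clustering on **Wang GO semantic
   similarity** (edge weights 0.8 is-a / 0.6 part-of, max-strategy gene
   similarity).

Inputs are generic text formats: OBO ontologies, GAF 2.x or two-column
annotation tables, whitespace edge lists and `complex<TAB>gene` membership
tables. A synthetic-data generator (`generate_world()`) builds complete
in-silico benchmarks so every stage is testable without database downloads.

## Worked example

```r
library(subcomplex)

world <- generate_world(seed = 1)   # in-silico benchmark
#> Synthetic world: 615 genes, 60 complexes ( 36 fully connected ),
#>   3032 true contacts, 527 GO terms

truth <- truth_tables(world)
run <- run_pipeline(world$complexes, world$interactome, world$target,
                    world$homolog, dag = world$dag, seed = 1,
                    reference = truth$subcomplexes)
run
#> subcomplex pipeline run
#>   pairs: 1139 positive / 1139 negative
#>   CV AUC: combined 0.9719 | target 0.9739 | homolog 0.9691
#>   triage:  fully 53.3%, partially 30.0%, isolated 16.7%
#>   clustered complexes: 50
#>   vs reference: precision 0.432 recall 0.856 F 0.574
```

The cross-validation AUCs say the model separates direct from indirect
pairs equally well whether it sees combined, target-only or homolog-only
instances — homolog transfer keeps poorly annotated genes predictable. The
triage line reports the fraction of complexes whose predicted subunit
networks are (near-)complete, partially wired, or empty. The final line
compares all inferred sub-complexes against the generator's planted ones at
Jaccard ≥ 0.5: recall 0.856 means most planted sub-complexes are recovered.

Zooming into one partially connected complex:

```r
run$profiles[run$profiles$complex == "CPX007", ]
#>    complex  N  M    degree  category
#> 49  CPX007 14 12 0.1318681 partially

mmc_cluster(run$networks[["CPX007"]])
#> MMC clustering: 7 clusters, Q = 0.0646851
```

Here a 14-subunit complex has 12 predicted contacts; modularity clustering
pulls out a 6-gene module (the complex's densely wired core) and leaves the
sparsely attached subunits as singletons.

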