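# dirank

Network-based prioritization of candidate disease genes by integrating
heterogeneous data sources.

Linkage and association studies leave investigators with long lists of
candidate genes that cannot all be validated experimentally. `dirank`
ranks those candidates against a family of known disease genes using the
guilt-by-association principle applied across **multiple** data sources at
once: protein interactions, gene co-expression and pathway co-membership
are each represented as an undirected gene network, pairwise gene
relationships are measured globally with a graph diffusion kernel, and the
per-network similarities are normalized into percentile *importance*
scores that are comparable across networks.

## The model

For each network with adjacency matrix $A$ and degree matrix $D$, the
diffusion kernel $K = e^{\beta(A - D)}$ gives a global node similarity
(zero exactly across connected components). The importance of a connected
pair is one minus the percentile of its kernel similarity among the
network's $P$ connected pairs, $I = (c_{>}+1)/(P+1)$; unconnected pairs
have $I = 1$. Importance becomes evidence via $ev(I) = 1 - I$ (or
$-\log_{10} I$), and a candidate gene $g$ is scored against the family's
disease genes $D$ with the data integration rank score

$$DIR(g,F) = \frac{\sum_{d \in D} \max_n \, ev(I_n(g,d))}{1 + |\{d : \min_n I_n(g,d) < 1\}|},$$

so each disease gene contributes through its most informative network.
The meta score $Q_F$ applies the same evidence to the family's own gene
pairs and serves as an adaptive declaration threshold (the Q+1 and
Q+1OR10 rules), and the informativeness
$Inf_n(F) = -\log_{10}(\text{mean pairwise } I_n)$ flags families for
which a network carries real signal ($Inf > 2$, i.e. mean importance
$\le 0.01$). A leave-one-out cross-validation harness with
nearest-neighbor / random / genome-wide control sets, ROC/AUC and
enrichment summaries, and a degree-preserving rewiring null completes the
evaluation stack, and a synthetic fixture generator with planted modular
structure makes the whole pipeline testable without any external
downloads.

## Worked example

```r
library(dirank)

fix  <- generate_fixture(fixture_spec(seed = 1))   # planted-module bundle
nets <- fixture_networks(fix)                      # ppi / coexpr / pathway
imps <- compute_importances(nets, beta = 0.1)

fam <- fix$families$fam01
informativeness_table(imps, list(fam))
#>   family_id network       inf
#> 1     fam01     ppi 1.0160363
#> 2     fam01  coexpr 0.8035858
#> 3     fam01 pathway 0.5971506

candidates <- setdiff(nearest_control_set(fam$genes[1], fix$positions,
                                          k = 20, exclude = fam$genes),
                      fam$genes)
ranked <- rank_candidates(candidates, fam, imps, seed = 7)
head(ranked[, c("gene", "dir_score", "rank", "contributing_count")], 4)
#>    gene dir_score rank contributing_count
#> 1 g0022 0.8648229    1                  8
#> 2 g0019 0.8644741    2                  8
#> 3 g0015 0.8590178    3                  8
#> 4 g0007 0.8552843    4                  8
```

All three networks are informative for `fam01` (informativeness well above
0, i.e. mean pairwise importance far below 1), and the top-ranked
neighboring genes draw evidence from all 8 family genes
(`contributing_count`), with DIR scores near 0.86 — these candidates sit
in the family's own planted module. Cross-validation over all 10 families:

```r
cv <- loocv(fix$families, nets, method = "DIR", controls = "nearest",
            k = 100, positions = fix$positions, seed = 7,
            importances = imps,
            criteria = list(top_k(1), top_k(10), q_plus_1(), q_plus_1_or_10()))
cv_summary(cv)
#> LOOCV: 80 runs | AUC 0.914 | enrichment 9.8 | first-ranked 6 | top-10 45
#>  criterion    tpr         fpr n_runs
#>        Q+1 0.0750 0.010148515     80
#>    Q+1OR10 0.0750 0.010148515     80
#>      Top-1 0.0750 0.009158416     80
#>     Top-10 0.5625 0.093440594     80
```

Each of the 80 runs holds out one disease gene and ranks it among its 100
nearest same-chromosome neighbors; an AUC of 0.91 means the held-out gene
outranks 91% of its controls on average, and 45 of 80 held-out genes land
in the top 10. The Q-based criteria keep the false-positive rate an order
of magnitude below Top-10.

## Command-line interface

A thin wrapper over the same functions is installed at
`inst/scripts/dirank`:

```sh
Rscript inst/scripts/dirank simulate --seed 1 --out-dir fx
Rscript inst/scripts/dirank build-coexpr --expr fx/expression.tsv --threshold 0.5 --out coexpr.tsv
Rscript inst/scripts/dirank prioritize --families fx/families.gmt --family fam01 \
    --net fx/ppi.tsv --net coexpr.tsv --beta 0.1 --seed 7 --out ranks.tsv
Rscript inst/scripts/dirank crossvalidate --families fx/families.gmt \
    --net fx/ppi.tsv --method dir --controls nearest:100 \
    --positions fx/positions.tsv --seed 7 --out cv
```

Every output file carries a provenance header (version, subcommand,
config, seed) and identical invocations are byte-identical.

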