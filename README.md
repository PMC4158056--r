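# rhodonet

Comparative gene co-expression analysis for bacteria (and other compact
genomes): signed weighted co-expression networks, permutation-based module
preservation between datasets, and Local Network Similarity (LNS) as a
per-gene expression-conservation score.

The package is aimed at groups who have condition-series expression data
for two related species (or mRNA and protein abundance for one species)
and want to know *which co-expressed gene modules are conserved, which
have diverged, and how conserved each individual ortholog's co-expression
neighborhood is* — without requiring matched experimental conditions
between the datasets.

## What it computes

**Network and modules.** Genes are standardized to robust z-scores
(`(x − median) / MAD`, unscaled MAD). Pairwise biweight midcorrelation
`bicor(x, y) = Σx̃ỹ / (√Σx̃² √Σỹ²)` (Tukey biweights,
`u = (x − med)/(9·MAD)`, weights `(1 − u²)² 1[|u| < 1]`) feeds a signed
adjacency `a_ij = ((1 + r_ij)/2)^β` with `β = 18`, topological overlap
`TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`, and
average-linkage clustering with an adaptive branch cut (minimum module
size 15, kME-based PAM-like assignment, eigengene merging at dissimilarity
0.15).

**Module preservation.** For a reference partition and a test dataset
restricted to shared (ortholog) genes, density statistics (meanCor,
meanAdj, propVarExplained, meanKME) and connectivity statistics (cor.kIM,
cor.kME, cor.cor) are compared against a null built by permuting module
labels; `Z = (obs − null mean)/null sd`,
`Zsummary = (median Z_density + median Z_connectivity)/2`, plus
medianRank. `Zsummary > 2` is weak-to-moderate, `> 10` strong evidence of
preservation; the same machinery run reference-vs-itself gives module
*quality*.

**LNS.** Correlation matrices are atanh (Fisher) transformed; the LNS of
an ortholog pair is the Pearson correlation of their matched correlation
vectors over all other orthologs (self-entries removed). The null
randomizes the ortholog mapping table (network topology untouched); a
split-half variant measures within-dataset LNS per gene.

**Gene sets.** Hypergeometric over-representation of gene sets in modules
with Benjamini–Hochberg FDR, and a rank-based permutation test for
differential DNA packaging (module ranks vs 1000 random same-size gene
sets, one-sided rank-sum tests at α = 0.01, 85% criterion).

**Synthetic truth.** A two-species generator plants modules of chosen
sizes driven by latent condition profiles (`ρ·latent + √(1−ρ²)·noise`),
marks a subset as preserved in species B, adds a proteomics-like layer
with missing values and a shifted packaging signal, and records full
ground truth — the package's test bench.

## Worked example

Five planted 40-gene modules (three preserved in species B, two not),
ρ = 0.9, 30 conditions per species, 100 background genes:

```r
library(rhodonet)

spec <- synth_spec(n_genes_A = 300, n_conditions_A = 30, n_conditions_B = 30,
                   module_sizes = rep(40, 5),
                   preserved_flags = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                   within_module_cor = 0.9, ortholog_fraction = 1, seed = 11)
d  <- gen_two_species(spec)
zA <- robust_z(d$exprA); zB <- robust_z(d$exprB)

part <- detect_modules(zA)
part
#> module_partition: 300 genes, 5 modules, 100 unassigned

rc  <- restrict_to_common(zA, zB, d$map, part)
rep <- module_preservation(rc$ref, rc$test, rc$labels, n_perm = 200, seed = 1)
rep
#> preservation_report: 5 modules, 200 permutations (seed 1)
#>   module size     Zdensity Zconnectivity   Zsummary medianRank cor_kME_all
#> 1      1   40 31.424711361    -0.7260983 15.3493065          2  0.07141441
#> 2      2   40 26.857075963    -1.2475157 12.8047801          3 -0.01793521
#> 3      3   40 33.871975856    -0.4054960 16.7332399          1  0.12818156
#> 4      4   40  1.890993318    -1.2013125  0.3448404          4  0.05724282
#> 5      5   40 -0.007028502    -1.1396142 -0.5733214          5 -0.07503475

ln  <- lns_from_expr(zA, zB, d$map, n_perm = 100, seed = 1)
round(median_lns_per_module(ln$table, part), 2)
#>     0     1     2     3     4     5
#> -0.01  0.85  0.85  0.85  0.06  0.01
```

All 200 planted module genes are recovered into five modules and the 100
background genes stay unassigned. The three preserved modules score
`Zsummary` 12.8–16.7 (strong evidence) and median-LNS ≈ 0.85; the two
non-preserved modules score `Zsummary` < 1 and median-LNS ≈ 0, and
medianRank orders the modules the same way. `cor_kME_all` is near zero
here because exchangeable planted members give the kME vector no internal
spread for a robust correlation to latch onto — see the vignette.

`run_pipeline(run_config(seed = 1), "out/")` chains all stages on the
default 2000-gene scenario and writes TSV artifacts plus a JSON manifest
with md5 digests; a rerun with the same config is digest-identical.

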