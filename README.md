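# schicdd

Unsupervised embedding and clustering of **single-cell Hi-C** contact maps
by diagonal diffusion operators.

Single-cell Hi-C assays measure chromatin contacts in individual cells, but
at 1 Mb resolution a cell's intrachromosomal matrices are so sparse (most
off-diagonal entries are zero) that standard clustering on the raw maps
fails. `schicdd` turns each cell's set of per-chromosome contact matrices
$A^k_s$ into a low-dimensional embedding through a fully deterministic,
label-free cascade:

1. **Imputation** — regularized graph Laplacian kernel
   $\bar A = (2I - D^{-1}(A+I))^{-1}$, bicubic resize to a common dimension
   $r = \mathrm{round}(\sum_k n_k / b)$, $3{\times}3$ Gaussian smoothing
   ($\sigma = 0.5$, replicate padding), and the dissipative matrix
   exponential $B = e^{-A''/\Sigma A''}$, which sharpens local contact
   structure instead of blurring it.
2. **Band features** — for each superdiagonal offset $w = 0,\dots,\zeta$,
   the z-scored concatenated bands and their trinarized consecutive
   differences; cells are compared by cosine distance on both, combined as
   $K^w_{ij} = e^{D'^w_{ij} + D^w_{ij}}$.
3. **Reduction** — per-offset nonmetric MDS (to $p$) + PCA (to $q$),
   feature stacking with column softmax, L1 distances, and a second MDS to
   the latent embedding $V$ ($a \times \epsilon$).
4. **Spectral step** — Gaussian similarity on $V$, $\lceil\ln a\rceil$-NN
   sparsification, random-walk (Shi–Malik) Laplacian eigenvectors giving
   $C$ ($a \times (l{-}1)$), then k-means++ into $l$ clusters.

Accuracy against ground-truth labels is scored with exact implementations
of the adjusted Rand index (ARI) and normalized mutual information (NMI).
The package also ships readers/writers for `.scool`/`.cool`, 4DN `.pairs`
and sparse triplet text, the customary cell/chromosome quality filters, a
labeled synthetic single-cell Hi-C generator (distance decay + shifted
TAD-like blocks), hyperparameter-sweep and chromosome-subsampling drivers,
and a command-line front end.

## Worked example

```r
library(schicdd)

spec <- synthetic_spec(n_cells = 60, chrom_sizes = c(80, 70),
                       contacts_per_cell = 2e4, seed = 42)
ens <- sample_ensemble(spec)
print(ens)
#> cell_ensemble: 60 cells x 2 chromosomes at 1e+06 bp bins
#>   bins per chromosome: chr1=80, chr2=70
#>   labels: type1:26, type2:13, type3:21

fit <- run_pipeline(ens, pipeline_params(zeta = 10, epsilon = 5, seed = 1))
print(fit)
#> schicdd_fit: a = 60 cells, b = 2 chromosomes, r = 75, l = 3
#>   zeta = 10, epsilon = 5, embedding = C, fast = FALSE
#>   mean ARI = 1.000 (sd 0.000), mean NMI = 1.000 (sd 0.000) over 10 repeats
#>   elapsed: 2.0 s

table(fit$labels, fit$cluster$cluster)
#>          1  2  3
#>   type1 26  0  0
#>   type2  0  0 13
#>   type3  0 21  0
```

The generator planted three cell types that differ only in TAD-boundary
positions; the printed scores say the k-means++ labels on the spectral
embedding `C` match the planted types exactly (ARI = NMI = 1) across 10
clustering repeats, and the confusion table shows the three recovered
clusters are the three types up to label naming. `write_results(fit, dir)`
exports `V.tsv`, `C.tsv`, predicted `labels.tsv`, `scores.json` and the
resolved `config.yaml`; a run is bitwise-reproducible from that config.

On real data, point the same pipeline at a cooler container:

```r
ens <- read_contacts("cells.scool", format = "scool", labels = "labels.tsv")
fit <- run_pipeline(ens, pipeline_params())   # zeta = 25, epsilon = 5
```

or use the CLI (`inst/cli/schicdd`): `schicdd simulate`, `schicdd run`,
`schicdd sweep`, `schicdd chrom-curve`, `schicdd score`.

`pipeline_params(fast = TRUE)` switches the Neumann-series kernel,
truncated-Taylor exponential and classical MDS in together for large
ensembles, at a small accuracy cost.

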