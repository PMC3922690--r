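# chromcode

Chromatin at a locus rarely carries a single histone modification: marks are
written and erased together, and it is the *combinations* that are
biologically informative. `chromcode` discovers such combinatorial patterns
— "codes" — from ChIP-seq data by sparse non-negative matrix factorization
(NMF) of a locus-by-mark signal matrix, and turns them into quantitative
per-locus variables suitable for regression, classification and gene-set
analysis. It is aimed at computational biologists who have per-mark BAM
files and a BED file of loci (promoters, enhancers, peak regions) and want
a small, interpretable, de-correlated set of chromatin variables instead of
a pile of highly collinear mark levels.

## The model

Let `V` be the non-negative `n x m` matrix of sigmoid-scaled mark signals
(`n` loci, `m` marks). chromcode factorizes

```
V ~ W H,     W >= 0 (n x c),  H >= 0 (c x m)
```

by minimizing `||V - WH||_F^2 + lambda * sum(H)` with block coordinate
descent. Rows of `H` are sparse basis patterns (codes) of co-occurring
marks; rows of `W` give each locus its non-negative code weights. The L1
penalty acts on `H` only, favouring codes that load on few marks. The
factorization is initialized with the deterministic NNDSVD construction
(variants: `nndsvdar`, `random`), so default runs are exactly reproducible.
The single main parameter is the rank `c`; `rank_scan()` reports
reconstruction error and Hoyer sparsity of `W` and `H` across ranks so a
knee can be located.

Three modes assemble the pipeline:

* **absolute** — reads are counted per locus and mark, columns are
  sigmoid-scaled to [0, 1), and `V` is factorized directly.
* **discriminatory** — `k` classes of loci are factorized independently;
  the per-class bases are concatenated and a single `W` over all loci is
  re-derived by non-negative least squares, exposing class-specific codes.
* **differential** — for two conditions, per-window counts inside each
  locus are depth-corrected with median-of-ratios size factors and
  subtracted; positive and negative window differences are integrated into
  per-mark "gain" and "loss" scores (2m columns), and the gain/loss matrix
  is factorized into patterns of coordinated change.

Downstream, `assign_codes()` labels each locus with its strongest code,
`match_codes()` pairs codes across factorizations by Hungarian-algorithm
minimum-cost matching, `correlation_matrix()` reports Spearman
multicollinearity (pairs above |rho| = 0.8 are flagged), and
`enrich_all()` tests each code's weights against gene-set collections with
the random-set z-test and Benjamini–Hochberg correction.

## Worked example

The package ships a generator of miniature indexed BAM/BED fixtures with
known truth, so the full pipeline can be run without any downloads:

```r
library(chromcode)
td <- tempfile()
fx <- make_toy_alignments("absolute", td)   # 24 loci x 3 marks, 2 planted patterns
fit <- absolute_mode(fx$bams, fx$bed, c = 2, seed = 1)
fit
#> chromcode NMF factorization (absolute mode)
#>   rank c: 2, loci: 24, columns: 3
#>   init: nndsvd, l1_H: 0.1, iterations: 500
#>   reconstruction error (Frobenius): 0.0300599
#>   mean Hoyer sparsity H rows: 0.7135
round(fit$H, 3)
#>        mark1 mark2 mark3
#> code_1 0.167 0.167 0.000
#> code_2 0.001 0.000 0.168
head(assign_codes(fit), 4)
#>   locus code code_label   weight   margin
#> 1   L01    1     code_1 2.364650 2.085789
#> 2   L02    1     code_1 2.626487 2.347784
#> 3   L03    1     code_1 2.929831 2.650991
#> 4   L04    1     code_1 3.164040 2.746350
```

The two recovered codes are exactly the planted co-occurrence patterns:
code 1 loads on marks 1+2 (which were planted together), code 2 on mark 3
alone, and the fixture's mark-1+2 loci are all assigned to code 1 with a
large margin. The same interface runs from a shell through the thin
`exec/chromcode` wrapper:

```sh
chromcode absolute --bams mark1.bam,mark2.bam,mark3.bam --bed loci.bed \
    --c 2 --seed 1 --out run1
# -> run1.H.tsv  run1.W.tsv  run1.assign.tsv  run1.config.json  run1.log
```

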