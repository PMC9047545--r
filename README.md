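# tmijoint

Joint quantification of the tumor microenvironment from bulk RNA-seq: immune
cell-type fractions by support-vector-regression deconvolution with
particle-swarm-tuned hyperparameters, and infiltrating bacterial abundance
from host-unmapped ("foreign") reads by an EM mixture over ambiguous
read-to-genome mappings — plus the downstream differential-abundance tests
and a joint elastic-net classifier of tumor vs. normal status.

## Who this is for

Computational biologists working with paired tumor/normal bulk RNA-seq who
want, from a single library, both layers of microenvironment signal:

1. **Immune infiltration.** Solve $X_{n\times L} = S_{n\times m} f_{m\times L}$
   for cell fractions $f$, given a gene × cell-type signature matrix $S$,
   per sample by linear $\epsilon$-insensitive SVR
   (loss ignores residuals inside an $\epsilon$-tube, penalty $C$ outside),
   with raw coefficients clamped and renormalized onto the probability
   simplex. The hyperparameters $(\epsilon, C, \phi)$ can be tuned by a
   canonical particle swarm ($c_1=c_2=2$, inertia 0.9 → 0.4, bounded search
   box, velocity clamping) against a cross-validated gene-holdout
   reconstruction RMSE.
2. **Bacterial infiltration.** Extract unmapped reads by SAM flag logic
   (`-f 4 -F 264` singles, `-f 12 -F 256` pairs), quality-filter them
   (length ≥ 36, ≤ 5 `N`, ≤ 40% of bases under Q15), pair singletons with
   reverse-complement mates, and resolve multi-mapping reads with an EM
   mixture: $p(r\,|\,j) \propto L_j^{-1}\varepsilon^{m}(1-\varepsilon)^{\ell-m}$,
   genome-length-corrected abundances, Shannon diversity.
3. **Joint analysis.** Per-feature Mann-Whitney U (exact for small untied
   samples, tie-corrected normal otherwise) with Benjamini-Hochberg FDR and
   direction/percent-difference annotation; elastic-net logistic regression
   (objective $-\tfrac1n\ell(\beta_0,\beta) + \mu[(1-\alpha)\tfrac12\lVert\beta\rVert_2^2 + \alpha\lVert\beta\rVert_1]$)
   comparing bacteria-only, cells-only and joint feature sets on repeated
   stratified 75/25 splits.

Everything is validated against deterministic synthetic generators
(`synth_spec()` and friends) with planted ground truth; see the methods
vignette (`vignettes/tmijoint-methods.Rmd`) for the models, assumptions and
limitations.

## Worked example

```r
library(tmijoint)

## -- immune fractions from a synthetic mixture with known truth ----------
spec <- synth_spec(seed = 42, noise_sd = 0.05)   # 200 genes, 5 types, 20 samples
S   <- make_signature(spec)
mix <- make_mixtures(S, spec)
fr  <- deconvolve(mix$X, S)                      # reference (eps, C, phi)
round(fr$fractions[1:3, ], 3)
#>          cell_1 cell_2 cell_3 cell_4 cell_5
#> sample_1  0.184  0.060  0.545  0.078  0.133
#> sample_2  0.146  0.237  0.092  0.006  0.519
#> sample_3  0.037  0.262  0.474  0.184  0.043
benchmark_metrics(as.vector(mix$fractions), as.vector(fr$fractions))
#> RMSE 0.0221  Pearson 0.9908  Spearman 0.9813
```

Each row is one sample's estimated cell-type composition (rows sum to 1);
at 5% mixture noise the estimates track the generator's true fractions with
RMSE 0.022 and correlation 0.99.

```r
## -- bacterial abundance from ambiguously mapped reads -------------------
rs   <- make_read_set(synth_spec(seed = 42, n_reads = 5000))
prof <- em_abundance(rs$cands)                   # truth: 0.5 / 0.3 / 0.2
prof
#> Abundance profile over 3 genomes, 5000 reads, 10 EM iterations
#> genome_1 genome_2 genome_3
#>   0.4949   0.3001   0.2050
shannon_diversity(prof)
#> [1] 1.0342

## -- differential abundance and the three-case classifier ----------------
cohort <- make_cohort(synth_spec(seed = 42))     # 49 tumor/normal pairs
tab <- differential_table(t(cohort$bacteria[cohort$labels == 0, ]),
                          t(cohort$bacteria[cohort$labels == 1, ]))
head(tab[order(tab$q), c("feature", "U", "p", "q", "direction", "pct_diff")], 1)
#>   feature   U        p        q direction pct_diff
#> 1  bact_1 263 2.78e-11 2.23e-10        up     88.6

res <- evaluate_three_cases(cohort$bacteria, cohort$cells, cohort$labels,
                            en_config(mu = 0.01, seed = 1), repeats = 25)
#> bacteria accuracy 0.763 +/- 0.083
#> cells    accuracy 0.768 +/- 0.103
#> joint    accuracy 0.833 +/- 0.069
```

The planted 2-fold feature is recovered at FDR ≪ 0.05, and the joint
feature set classifies held-out samples better than either block alone —
the qualitative pattern the method is designed to expose.

## Command line

A subcommand CLI wraps the same functions (see `?tmi_cli`):

```sh
Rscript inst/cli/tmijoint run --out-dir artifacts --seed 1
Rscript inst/cli/tmijoint deconv --mixture X.tsv --signature S.tsv --out F.tsv
Rscript inst/cli/tmijoint abundance --cands cands.tsv --lengths len.tsv --out A.tsv
```

`run` drives the full synthetic pipeline (simulate → abundance → deconvolve
→ differential tables → classifier) into an artifact directory with a
reproducibility manifest; stages are resumable.

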