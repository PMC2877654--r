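# tadfd

Dendrogram-based functional diversity (FD) analysis for stream tadpole
communities — and for any presence-based community data with mixed
binary/continuous traits.

Community ecologists ask two questions that species richness (SR) alone
cannot answer: do co-occurring species overlap in ecological function
(**functional redundancy**), and are communities assembled by
**environmental filtering** (co-occurring species more similar than
chance) or by competition (more different)?  `tadfd` implements the
classic dendrogram-based FD workflow to answer both, plus the habitat
ordination stage that links richness to stream gradients.

## The measure and the tests

1. **Functional space.** A species × trait matrix (binary state columns +
   continuous measurements) gives pairwise **Gower distances**
   d(i,j) = (1/T) Σₜ δₜ(i,j), with δₜ the range-normalised absolute
   difference for continuous traits and the mismatch indicator for binary
   ones.  An agglomerative dendrogram is built over the regional pool; the
   linkage (UPGMA, WPGMA, complete, single, Ward) is chosen automatically
   by minimising Σ_{i<j} (d(i,j) − c(i,j))², the discrepancy between input
   and cophenetic distances.
2. **FD.** A community's FD is the total branch length of the minimal
   subtree of the regional dendrogram spanning its species, truncated at
   their last common ancestor; FD(singleton) = 0.
3. **Redundancy.** Polynomial regression FD ~ SR + SR²: a significantly
   negative quadratic term means the curve flattens — added species are
   functionally redundant.
4. **Null model.** Predicted FD at richness S is the mean FD of 500 random
   S-subsets of the full pool.  Observed and predicted curves are compared
   by a grouped Michaelis–Menten fit
   FD(S) = (Fmax + δFmax·g)·S/((K + δK·g) + S), with one-sided t-tests
   (df = n − 4) on the offsets; a significantly negative δFmax is the
   **low FD** verdict, i.e. evidence of environmental filtering.
5. **Habitat ordination.** Box-Cox screening of skewed variables,
   correlation-matrix PCA, bootstrapped-eigenvector significance flags for
   loadings, broken-stick component retention, and backward-eliminated
   regression of SR on the retained components.

A synthetic-data module generates trait pools (guild-structured, so the
FD–SR curve saturates realistically), communities under neutral /
filtering / competition assembly, and habitat tables with one dominant
size–velocity gradient — so the whole chain is testable and calibrated
without any field download.

## Worked example

Simulate 29 stream sites under strong richness-dependent filtering and run
the full chain:

```r
library(tadfd)
cfg <- pipeline_config(simulation = list(rule = "filtering", strength = 40),
                       seed = 2026)
rep <- run_pipeline(cfg)
rep
#> == tadfd pipeline report ==
#> 29 sites, 36-species pool; seed 2026
#> PCA: PC1 48.0%, PC2 12.1%, PC3 8.8%; retained 1
#> SR ~ PCs: retained PC1; R^2 = 0.462
#> Clustering: UPGMA selected (criterion 1.731)
#> Redundancy: no evidence (SR^2 p = 0.0985); R^2 linear 0.782, quadratic 0.804
#> MM: Fmax obs 1.427 vs pred 2.285 (t = -4.043, df = 54, p = 8.43e-05)
#> Verdict: low FD
```

Reading the report: PC1 carries 48% of habitat variance and predicts SR
(the size–velocity gradient); UPGMA best preserves the Gower distances;
and the observed FD asymptote (Fmax = 1.43) sits significantly below the
null-model asymptote (2.29): the one-sided t-test on the offset gives

```r
rep$verdict
#> FD verdict: low FD (alpha = 0.05)
#>   Fmax contrast: -0.8577, t = -4.043, df = 54, p = 8.428e-05
#>   K contrast:    -6.3648, t = -2.709, df = 54, p = 0.00451
```

so co-occurring species in the rich sites are more similar than random
assembly allows — environmental filtering.  Under `rule = "neutral"` the
same chain returns "not low" in ~95% of seeds.

Every stage is also exposed directly (`gower_distance()`,
`build_dendrogram()`, `fd()`, `null_model_fd()`, `fit_mm_grouped()`,
`run_pca()`, `bootstrap_eigenvector_test()`, …), and a thin command-line
front end lives at `inst/cli/tadfd.R` with subcommands
`simulate | ordinate | fd | nullmodel | compare | run-all`.

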