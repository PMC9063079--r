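# covfold

Predicts an individual, possibly pseudoknotted, RNA secondary structure
for **every sequence** of a multiple sequence alignment, by combining the
family's covariation signal with restricted thermodynamic energy
minimization.

Homologous RNAs conserve structure through compensatory mutations, which
leave a statistical dependence between the alignment columns of conserved
base pairs. covfold measures that dependence with canonical-pair
mutual information corrected for background noise,

```
MI(a,b)  = Σ_{x·y canonical} f_ab(x,y) log2( f_ab(x,y) / (f_a(x) f_b(y)) )
MIp(a,b) = MI(a,b) − MI(a,z̄)·MI(b,z̄) / MI_avg        (average product correction)
```

selects non-conflicting column pairs with `MIp > 0.4` as forced
*intermediary base pairs*, marks columns whose maximum MI falls below the
alignment mean as forced-unpaired (`x`), and projects the resulting
*guide structure* onto each sequence. A restricted Zuker-style dynamic
program (O(n³) time / O(n²) space, C++ core) then minimizes free energy
around the guide along four relaxation paths, including a pseudoknotted
path that adds a disjoint pseudoknot-free layer so the union is a
density-2 structure (H-type pseudoknots, kissing hairpins). The
lowest-energy structure per sequence is reported.

The package also provides base-pair accuracy metrics (sensitivity, PPV,
F-measure, and a compatible-pair-adjusted variant), a resampling
significance test for comparing methods, a configurable nearest-neighbor
energy model with affine pseudoknot penalties, and synthetic-alignment
generators with planted structures for validation.

## Worked example

```r
library(covfold)

fx   <- trna_like_fixture(n_sequences = 20, seed = 42)   # 4-stem cloverleaf
pred <- predict_alignment(fx$alignment, threshold = 0.4)
pred[1:3, c("id", "structure", "energy", "method")]
#>   id      structure                                                                    energy method
#> 1 seq_001 (((((((..((((........)))).(((((.......))))).....(((((.......))))))))))))....   1.18 P5
#> 2 seq_002 (((((((..((((........)))).(((((.......))))).....(((((.......))))))))))))....   1.78 P5
#> 3 seq_003 (((((((..((((........)))).(((((.......))))).....(((((.......))))))))))))....  -1.32 P5
```

Each row is one input sequence: its ungapped sequence, projected guide,
predicted dot-bracket structure (bracket layers `[]{}<>` mark crossing
pairs), free energy in kcal/mol, and which relaxation path won. The
alignment-level guide shows the covariation evidence — here all four
planted stems were selected and loop columns restricted:

```r
guide_string(attr(pred, "alignment_guide"))
#> (((((((xx((((x_xxx__x))))_(((((_xxxx_x)))))x_xxx(((((xx___xx))))))))))))x_x_
```

Scoring against the planted truth:

```r
sc <- evaluate_predictions(pred, fx$structures)
mean(sc$f_measure)
#> [1] 1
```

A pseudoknot forms when a forced stem's loop can pair downstream:

```r
pk <- restricted_pk_mfe("AAAGGGGGUUACCCCC",
                        guide_structure(16, cbind(c(1, 2), c(10, 9))))
pk
#> <fold_result> [restricted_pk_guide_layer] 7 pairs, 2.05 kcal/mol
#> AAAGGGGGUUACCCCC
#> ((.[[[[[)).]]]]]
```

`tidy()`, `glance()` and `autoplot()` methods give per-pair tables,
one-row summaries, and arc diagrams of any fold result;
`autoplot()` on the covariation object draws the MIp heatmap.

A thin command-line front end is installed at
`system.file("cli", "covfold", package = "covfold")` with subcommands
`predict`, `covary`, `evaluate` and `sweep`.

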