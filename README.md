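# pssmdt

Identifying DNA-binding proteins from evolutionary sequence profiles.

DNA-binding proteins (transcription factors, histones, nucleases, repair
enzymes) are functionally central but hard to recognise from sequence
alone. `pssmdt` implements a profile-based classifier for this task: it
turns the PSI-BLAST position-specific scoring matrix (PSSM) of a protein
into a fixed-length *distance-transformation* feature vector, trains an
RBF-kernel support vector machine on those vectors, evaluates it under
jackknife / k-fold / independent-test protocols, and ranks amino-acid-pair
descriptors by discriminant weight to show *which residue pairings* drive
the decision.

## The encoding

A PSSM is an L × 20 matrix of log-odds scores `S[position, amino acid]`
(columns in PSI-BLAST order `A R N D C Q E G H I L K M F P S T W Y V`).
For an ordered amino-acid pair (a₁, a₂) and a sequence lag *lg*, the
descriptor value is

    DT(a1, a2, lg) = Σ_{j=1}^{L-lg} S[j, a1] · S[j+lg, a2] / (L − lg)

an evolutionary co-occurrence of a₁ and a₂ at separation *lg*. Same-pair
descriptors form the SDT block (20·LG values for a maximum lag LG),
ordered different-pair descriptors the DDT block (380·LG), and their
concatenation the full encoding with 400·LG coordinates — 2000 at the
default LG = 5. The SVM decision function is
`f(x) = Σ αᵢ yᵢ exp(−γ‖sᵢ − x‖²) + b`, with (C, γ) grid-searched by
stratified 5-fold cross-validation; the feature read-out `W = AᵀM`
(A = dual weights, M = training features) is collapsed per ordered pair as
the quadratic sum of its positively weighted lags.

Four comparison PSSM encoders (`avepscore20`, `avepscore400`, `pscore100`,
`acc_transform`), a seeded synthetic-profile generator with plantable
pair/lag signal, FASTA / ASCII-PSSM parsers, and a CLI round out the
package.

## Worked example

Everything below runs offline on seeded synthetic data (n = 60 balanced,
planted arginine-centred signal: pair (R,R) at lag 4, (A,R) at lag 5):

```r
library(pssmdt)

sim <- generate_dataset(seed = 11)                     # 30 pos + 30 neg
enc <- encode_profiles(sim$profiles, "dt", LG = 5, labels = sim$labels)
dim(enc)
#> [1]   60 2002                                        # id, label, 2000 descriptors

gs <- grid_search(enc, C_grid = 2^seq(-1, 7, 2),
                  gamma_grid = 2^seq(-15, -5, 2), folds = 5, seed = 11)
jk <- jackknife(enc, C = gs$C, gamma = gs$gamma)
jk
#> <evaluation_report> protocol: jackknife  (C = 0.5, gamma = 3.05176e-05)
#>  n = 60  TP 27  FP 0  TN 30  FN 3
#>  ACC 95.00%  SN 90.00%  SP 100.00%  MCC 0.905  AUC 100.00%

model <- svm_train(enc, C = gs$C, gamma = gs$gamma)
rep <- discriminant_report(model, enc)
rep$ranked_pairs[1:4]
#> [1] "R-R" "A-R" "R-A" "A-A"
```

Reading the output: 57 of 60 held-out samples are classified correctly
(ACC 95%), every negative is rejected (SP 100%), the Matthews correlation
0.905 is near-perfect agreement, and the pooled held-out decision values
rank all positives above all negatives (AUC 100%). The discriminant
ranking recovers the two planted pairs in the top ranks — the feature
analysis pointing back at exactly the residue pairings that carry the
signal. `autoplot(jk)` draws the ROC curve; `autoplot(rep)` the 20 × 20
pair-weight heatmap; `per_lag_weights(rep$weights, c("R","R"))` shows the
weight peaking at the planted lag 4.

The same workflows are scriptable from a shell:

```sh
Rscript inst/cli/pssmdt.R simulate --out sim --seed 11
Rscript inst/cli/pssmdt.R encode --pssm-dir sim --scheme dt --lg 5 --out bench
Rscript inst/cli/pssmdt.R evaluate --data bench --protocol jackknife \
    --grid --seed 11 --out report.json
```

## Limitations

Synthetic validation demonstrates pipeline correctness and recoverability
of planted signal, not real-data accuracy: benchmark-scale performance
depends on profiles computed against a large protein database (see
`run_psiblast()`), which this package deliberately does not bundle. The
methods vignette (`vignettes/pssm-dt-methods.Rmd`) documents the model,
parameter choices, generator design and numerical conventions in detail.
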