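# distsvm

Protein remote homology detection with distance-based residue and
Top-1-gram pair features (SVM-DR / SVM-DT).

## The problem

Remote homologs keep their fold while their sequences drift below the
identity range that alignment detects. Discriminative methods turn the
question into one-vs-rest classification: map each protein to a fixed-length
vector and train an SVM to separate family members from non-members.
Position-independent representations (composition, k-mer spectra) discard
sequence order; this package implements a position-dependent one.

## The representation

Over the fixed alphabet **Ӑ** = (A, R, D, C, Q, E, H, I, G, N, L, K, M, F,
P, S, T, W, Y, V) and a distance threshold *d*<sub>max</sub>, a symbol
sequence *S′* maps to the concatenation

&nbsp;&nbsp;*F*<sub>*d*max</sub>(*S′*) = [*D*<sub>0</sub>(*S′*), *D*<sub>1</sub>(*S′*), …, *D*<sub>*d*max</sub>(*S′*)]

where *D*<sub>0</sub> holds the 20 unigram counts *T*<sup>0</sup><sub>*i*</sub>(*S′*)
and each *D*<sub>*d*</sub> (*d* ≥ 1) holds the 20×20 counts
*T*<sup>*d*</sup><sub>*ij*</sub>(*S′*) of ordered pairs in which symbol
*t*<sub>*i*</sub> occurs exactly *d* positions before *t*<sub>*j*</sub>.
The dimension is 20 + 20·20·*d*<sub>max</sub> (60020 at the default
*d*<sub>max</sub> = 150).

Two methods share this code path:

* **SVM-DR** — symbols are the native residues (sequence-based, no profiles
  needed);
* **SVM-DT** — each residue is replaced by the **Top-1-gram** of its
  PSI-BLAST profile column (the most frequent amino acid in the alignment at
  that position), injecting evolutionary information.

A linear soft-margin SVM is trained per family on unit-normalised count
vectors; families are scored by ROC and ROC50 (area under the ROC curve up
to the 50th false positive). Because the feature space is explicit, the
discriminant weight vector **w** = *M*α (training matrix × label-signed dual
coefficients) is available for feature analysis: per-pair L2-norms over
distances and per-distance weight profiles.

## Worked example

The `KFFK` feature vector at *d*<sub>max</sub> = 2:

```r
library(distsvm)
v <- build_feature_vector("KFFK", d_max = 2)
c(length(v), sum(v != 0), sum(v))
#> [1] 820   7   9
```

820 = 20 + 400·2 components; 7 nonzero (K and F twice each at *d* = 0;
(K,F), (F,F), (F,K) at *d* = 1; (K,F), (F,K) at *d* = 2); the counts sum to
4 + 3 + 2 = 9 valid positions/pairs.

End to end on a synthetic family with pair (G,G) planted at distance 5:

```r
fam <- generate_family(synthetic_family_config(seed = 42))
tr <- c(fam$split$positive_train, fam$split$negative_train)
te <- c(fam$split$positive_test, fam$split$negative_test)
y_tr <- ifelse(tr %in% fam$split$positive_train, 1, -1)
y_te <- ifelse(te %in% fam$split$positive_test, 1, -1)

fit <- dsvm(fam$profiles[tr], y_tr, mode = "dt", d_max = 10)
fit
#> Distance-pair SVM (DT mode), d_max = 10, 4020 features
#> Training: 30 positive, 30 negative; training ROC 1.000

s <- predict(fit, fam$profiles[te])
roc_score(s, y_te)    # 0.965
roc50_score(s, y_te)  # 0.965

summary(fit)
#> Most discriminative ordered pairs (L2-norm over distances):
#>   (G, G)  1.897
#>   (G, H)  0.6764
#>   ...
which.max(abs(pair_distance_profile(coef(fit), "G", "G")))
#> [1] 5
```

The classifier separates held-out test proteins (ROC 0.965), the planted
pair (G,G) tops the importance ranking, and its weight profile peaks at the
planted distance 5. `plot(fit)` draws the 20×20 importance heatmap;
`plot(fit, type = "distance", pair = c("G","G"))` the per-distance weights.

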