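---
title: "Distance-pair features for protein remote homology detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-pair features for protein remote homology detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distsvm)
```

## The problem and the representation

Remote homologs — proteins that diverged long ago — keep their fold and
function while their sequences drift below the identity level that pairwise
alignment can detect. Discriminative classifiers sidestep alignment by
mapping every protein to a fixed-length vector and learning a decision
boundary between family members and non-members. The representation decides
what the classifier can see. Plain composition or k-mer spectra are
position-independent: they discard the order in which residues occur, which
is exactly where much of the conserved structural signal lives.

This package implements a position-dependent representation built from
ordered symbol pairs at bounded positional offsets. Fix the 20-letter
amino-acid alphabet in the order

```{r}
aa_alphabet()
```

and a distance threshold `d_max`. For a symbol sequence $S'$ of length $L$,
the feature vector concatenates one block per distance $d = 0, 1, \dots,
d_{\max}$:

* the $d = 0$ block holds the 20 unigram occurrence counts
  $T^0_i(S')$ (the composition);
* the block for $d \ge 1$ holds the $20 \times 20$ counts
  $T^d_{ij}(S')$ of ordered pairs $(t_i, t_j)$ in which $t_i$ occurs exactly
  $d$ positions before $t_j$ (adjacent symbols have $d = 1$).

The total dimension is $20 + 20 \cdot 20 \cdot d_{\max}$; at the standard
operating point `d_max = 150` that is 60020. The construction costs
$O(L \cdot d_{\max})$ — one vectorised pass per distance.

Two methods share this single code path and differ only in the symbols:

* **SVM-DR** (Distance-based Residue): the native residues themselves —
  alignment-free and profile-free;
* **SVM-DT** (Distance-based Top-1-gram): each residue is replaced by the
  *Top-1-gram* of its PSI-BLAST frequency-profile column — the amino acid
  that dominated the multiple alignment at that position — injecting
  evolutionary information into the same pair-count machinery.

A worked example: if the profile columns of the sequence `AGLP` have maxima
K, F, F, K, the Top-1-gram sequence is `KFFK`, and at `d_max = 2`:

```{r}
prof <- frequency_profile(diag(20)[match(c("K","F","F","K"), aa_alphabet()), ],
                          id = "AGLP")
v <- dt_features(prof, d_max = 2)
c(length = length(v), nonzero = sum(v != 0), total = sum(v))
```

Seven nonzero counts: K and F twice each at $d=0$; (K,F), (F,F), (F,K) at
$d=1$; (K,F), (F,K) at $d=2$.

## Conventions the data do not fix

Several choices are not forced by the construction itself; they are frozen
here and tested, because reproducible feature files require a fixed layout.

* **Index layout.** Unigram $a$ maps to position $a$ (1-based); pair
  $(a, b)$ at distance $d$ maps to $20 + 400(d-1) + 20(a-1) + b$. Blocks are
  ordered by increasing distance.
* **Ordered pairs.** $(a,b)$ and $(b,a)$ are distinct features; the first
  symbol is the earlier one.
* **Tie-breaking in profiles.** When a profile column has tied maxima, the
  Top-1-gram is the symbol earliest in the alphabet order above. All-zero
  percentage rows become uniform rows (hence encode to `A`) and are flagged.
* **Ambiguity codes.** B, Z, X, U, O carry no standard symbol. They are
  masked: the position contributes to no unigram count, and any pair
  spanning it is dropped rather than bridged. Masking keeps the alphabet at
  exactly 20 symbols (the dimension formula depends on it) and keeps the
  conservation identity exact: for a fully valid sequence the vector sums to
  $L + \sum_{d=1}^{d_{\max}} \max(0, L - d)$.
* **Distance convention.** $d$ is the positional offset $j - i$, so $d = 0$
  is the unigram block and adjacent pairs have $d = 1$; the two-case block
  structure forces this reading and the `KFFK` example above pins it down.

## The classifier

Each family is a one-vs-rest problem: positive training sequences from the
family's superfamily (minus the held-out family), negatives from outside.
Count vectors are scaled to unit Euclidean norm — raw counts grow linearly
with sequence length, and length is a nuisance variable here — and a
soft-margin SVM is trained. Defaults, all configurable through
`classifier_config()`:

* linear kernel (the representation is explicit and high-dimensional, so a
  linear boundary is both fast and interpretable);
* regularisation constant $C = 1$;
* class imbalance handled by weighting the positive class by
  $N_{neg}/N_{pos}$;
* dual solver (libsvm, via \pkg{e1071}) run at tolerance $10^{-7}$, tight
  enough that retraining and training-order permutations move test scores by
  far less than $10^{-6}$. There is no randomised initialisation: training
  is deterministic.

The fitted object stores the label-signed dual coefficients
$\alpha = [\alpha_1 y_1, \dots, \alpha_N y_N]$ and the training matrix, and
all scoring goes through the kernel expansion
$f(v) = \sum_i \alpha_i K(x_i, v) + b$.

## Evaluation: ROC and ROC50

Family classifiers are compared by the ROC score — the normalised area under
the true-positive/false-positive curve, equal to the probability that a
random positive outranks a random negative, with ties counting one half —
and by the ROC50 score, the area under the curve truncated at the 50th false
positive. The truncation reflects practice: a curator inspects a bounded
prefix of the ranked list, so early precision matters more than the tail.

The truncated area is normalised by $n_{pos} \times \min(50, n_{neg})$, the
standard convention of this benchmark literature (the alternative,
unnormalised truncated area, is not bounded by 1). Under it, ROC50 equals
ROC exactly whenever $n_{neg} \le 50$, a property the test suite asserts,
together with exact agreement ($<10^{-12}$) between the rank-statistic
implementation and an independent brute-force trapezoid construction, and a
null calibration (shuffled labels give mean ROC $0.5 \pm 0.02$). Averages
over a benchmark are unweighted across families.

## Discriminant weights and feature analysis

For the linear kernel the decision function has an explicit weight vector

$$ w = M\,\alpha, $$

with $M$ the matrix whose columns are the (normalised) training vectors and
$\alpha$ the label-signed dual coefficients. Label-signing is the only
reading under which $w^\top v + b$ reproduces the kernel-expansion score — a
consistency the tests verify to $10^{-9}$ — and the magnitude of each
component of $w$ measures the discriminative power of its feature.

Two summaries support family-level interpretation:

* `pair_l2_norms()`: the importance of ordered pair $(a,b)$ as
  $\sqrt{\sum_d w_{(a,b,d)}^2}$, a $20\times20$ heatmap. The unigram block is
  excluded from pair norms and reported separately (it is not a pair).
* `pair_distance_profile()`: the signed weight of one pair at each distance
  $1..d_{\max}$, the "ladder" plot that shows short distances carrying most
  of the discrimination.

These summaries partition the squared norm of $w$ exactly:
$\sum_{pairs}\|\cdot\|_2^2 + \sum_a w_a^2 = \|w\|_2^2$. Whether to rescale
$w$ (e.g. by $\|\alpha\|$) before plotting is cosmetic — rankings are
unaffected — and this package plots it unscaled.

## The synthetic benchmark

Real benchmark families require an external structural classification
database and PSI-BLAST profiles against a large sequence database, neither
of which belongs in a package test. Instead, the generator in
`generate_family()` builds two-class families with controlled structure:

* positives: i.i.d. background sequences carrying `insertions` copies of a
  planted ordered pair at a fixed offset (default: (G, G) at distance 5,
  3 insertions);
* negatives: pure background with the *same* residue composition, so
  discrimination must come from pair-distance structure, not composition —
  the planting does perturb composition slightly (each insertion adds two
  fixed symbols), which is why a narrow `d_max` retains some signal, but the
  distance blocks dominate;
* profiles: each column puts mass `profile_concentration` (default 0.8) on
  the native residue and spreads the rest randomly. This controls exactly
  the channel the DT method consumes: above 0.5 the Top-1-gram equals the
  native residue (so DT and DR coincide on synthetic data — by design, the
  generator stresses the pair-count machinery, not profile inference), and
  at 1.0 the profile is degenerate. A Dirichlet noise model would add
  realism the method never reads.

Default family sizes are 30 positive and 30 negative training sequences and
20 + 20 test sequences, lengths uniform on [80, 150], uniform background —
sizes at which a planted signal of 3 pairs per sequence is strong but not
trivial (mean test ROC around 0.97, not 1.0) and a full five-seed benchmark
runs in seconds. Passing tests on this generator show that the pipeline
recovers planted pair-distance structure end to end (mean ROC $\ge 0.95$,
planted pair recovered as the top importance in $\ge 4/5$ seeds, null
families at ROC $\approx 0.5$, and `d_max = 10` beating `d_max = 1` when the
signal sits at distance 5). They do not show performance on real proteins:
real families have phylogenetic correlation, composition bias, indel
structure and profile noise that the generator deliberately omits.

## Numerical and degenerate-input choices

* Counts are stored as exact integers; normalisation happens only inside the
  classifier, so all counting invariants are integer-exact.
* The all-zero feature vector (possible only when every position is masked)
  is left unchanged by unit normalisation.
* `roc_score`/`roc50_score` refuse single-class inputs rather than returning
  a conventional value.
* Training requires both classes and unique ids; single-class input is an
  argument error, not a degenerate fit.
* PSSM rows with fewer than 42 whitespace-separated fields, or non-numeric
  percentages, are format errors naming the row; the parser takes its column
  order from the file header when present and falls back to the standard
  PSI-BLAST order.

## Limitations

* Pair features are restricted to Top-1-grams; general Top-n-gram pairs for
  $n \ge 2$ would multiply the dimension by $20^{2(n-1)}$ and are out of
  scope.
* The SVM defaults here are a documented choice, not a reproduction of any
  particular legacy SVM package's defaults; absolute ROC values on a given
  dataset depend on them even when rankings are stable.
* Profiles are consumed from files; running PSI-BLAST, building alignments,
  or assessing profile quality is out of scope.
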