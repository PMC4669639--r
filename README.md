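# mechmatch

Tools for asking — and answering — a simple question about enzyme
function prediction: when a nearest-neighbour classifier over binary
protein-signature annotations predicts enzymatic reaction mechanisms
almost perfectly, *why* does it work? `mechmatch` implements the whole
analysis as a reusable R pipeline: the classifier, its evaluation, and the
matrix-structure analyses that explain its behaviour, exercised end-to-end
on synthetic data with known (planted) structure.

## The model

Each enzyme is a point `x` in the binary feature space `χ = {0,1}^L`,
where `x_i = 1` records the presence of the *i*-th protein signature
(e.g. an InterPro family/domain identifier; `L = 321` by default). Each
enzyme carries one or more mechanism labels `ω_j` from a label space of
`J = 71` mechanisms (`M0123`-style identifiers). Classification is a
dictionary search: a query is assigned the label set of its nearest
stored neighbour under squared Euclidean distance, which on binary
vectors is the Hamming distance

```
d²(a, b) = Σ_i (a_i − b_i)² = #{i : a_i ≠ b_i}.
```

Because annotation vectors are sparse, many dictionary points are often
tied at the minimum distance; the whole equidistant **ring** votes, and
the most common label *set* wins (ties broken deterministically: smallest
set, then lexicographic). Accuracy is measured by leave-one-out (LOO)
evaluation over all N enzymes.

The package also explains the classifier's success structurally:

* `blockify()` reorders rows and columns to expose the block-diagonal
  structure of the enzyme × signature matrix and scores its diagonality
  (fraction of presence cells inside their own label's block);
* `overlap_report()` extracts each mechanism's feature *region* (the
  union of its enzymes' signatures) and scores every label pair by
  Jaccard overlap, flagging completely overlapping (indistinguishable)
  pairs;
* `sub_subspaces()` detects composite regions — labels whose enzymes
  split into groups with mutually disjoint signatures;
* `build_templates()` / `match_templates()` turn the matrix into a
  look-up table for predicting whether a novel enzyme carries any known
  mechanism;
* `generate_annotation()` builds synthetic matrices with this exact
  anatomy planted: near-disjoint per-label blocks, one completely
  overlapping pair sharing a 4-signature block, one composite label,
  optional bit-flip noise.

## Worked example

```r
library(mechmatch)

sim  <- generate_annotation(generator_config())   # 247 x 321, noiseless
dict <- dictionary(sim$matrix, sim$labels)

loo <- loo_evaluate(dict)
loo
#> <loo_report> n=247 criterion=exact vote=set success_rate=0.9838
subset(loo$per_enzyme, !success)
#>     enzyme_id true_labels predicted_labels ring_distance ring_size success
#> 114   SYN0114       M0348            M0269             0         3   FALSE
#> 115   SYN0115       M0348            M0269             0         3   FALSE
#> 133   SYN0133       M0269            M0348             0         3   FALSE
#> 134   SYN0134       M0269            M0348             0         3   FALSE

ov <- overlap_report(sim$matrix, sim$labels)
ov$complete_pairs
#>      label_a label_b
#> [1,] "M0269" "M0348"
lengths(ov$shared_features)
#> M0269|M0348
#>           4

layout <- blockify(generate_annotation(
  generator_config(shuffle_columns = TRUE))$matrix, sim$labels)
layout$score
#> [1] 1
```

Read: LOO succeeds for 243 of 247 enzymes (98.38 %). The only failures
are the four enzymes of the two completely overlapping mechanisms —
their signature vectors are identical, so each enzyme's ring is
dominated by the *other* label and no annotation-based classifier could
separate them. The overlap report finds exactly that one pair, sharing
exactly 4 signatures, and `blockify` recovers the planted block
structure perfectly (diagonality 1.0) from shuffled columns.

A subcommand CLI (`simulate`, `loo`, `blockify`, `overlap`, `predict`)
wraps the same pipeline for TSV files:

```sh
Rscript inst/cli/mechmatch.R simulate --out matrix.tsv --seed 1
Rscript inst/cli/mechmatch.R loo --matrix matrix.tsv --out loo.tsv
# success_rate=0.983806
```

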