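# fsace

Filter feature selection for high-dimensional classification data —
gene expression matrices in particular — by **approximate conditional
entropy on fuzzy information granules**.

## The problem and the method

Expression datasets have tens–hundreds of samples and thousands of
genes, nearly all irrelevant to the class labels. `fsace` selects a
small attribute subset without training the downstream classifier:

1. **Fuzzy relation.** For attribute subset *B* and kernel width σ,
   sample similarity is the Laplacian kernel
   *r*<sub>ij</sub> = exp(−‖x<sub>i</sub> − x<sub>j</sub>‖<sub>B</sub>/σ) ∈ (0, 1].
2. **Granulation.** Two samples share a *fuzzy information granule*
   when their relation rows are approximately equal: at every position
   the values fall in the same of *k* equal-width bins of [0,1]. The
   granules partition the samples.
3. **Scoring.** The approximate conditional entropy of the decision *D*
   given *B*,

   H<sub>ace</sub>(D/B) = −Σ<sub>j</sub> log₂(2 − a(X<sub>j</sub>)) Σ<sub>i</sub> (|[x<sub>i</sub>]∩X<sub>j</sub>|/n) · log₂(|[x<sub>i</sub>]∩X<sub>j</sub>|/|[x<sub>i</sub>]|),

   blends the granule-based conditional entropy (information view) with
   each class's rough-set approximation accuracy
   a(X<sub>j</sub>) = |lower|/|upper| (algebra view). It is 0 exactly
   when every granule is class-pure and peaks at n·log₂n.
4. **Greedy search (FSACE).** Seed with the *core* (attributes whose
   removal raises the entropy), then repeatedly add the attribute with
   the largest entropy drop (external importance, IEA) until the
   subset's entropy matches the full set's.

## Worked example

```r
library(fsace)

syn <- generate_table(synthetic_spec(seed = 42))  # 60 samples, 3 classes,
print(syn$table)                                  # 2 informative + 20 noise
#> Decision table: 60 objects x 22 attributes, 3 class(es)
#> Classes: class1 (20), class2 (20), class3 (20)
syn$ground_truth
#> [1] 17 19

sigma <- choose_sigma(syn$table, seed = 42)  # coarse CV-driven sweep
sigma
#> [1] 2

res <- fsace_select(syn$table, sigma = sigma)
print(res)
#> FSACE selection: 2 attribute(s) [17, 19]
#> H_ace(D/C) = 0, H_ace(D/B) = 0
#> converged = TRUE (entropy-matched); core = {}
res$trace
#>   attribute       iea    h_ace
#> 1        17 92.847484 2.250266
#> 2        19  2.250266 0.000000

cross_validate(syn$table, res$selected, "knn3", folds = 5, seed = 42)
#> [1] 1
```

Reading the trace: with no attributes the entropy is the maximal
60·log₂3 ≈ 95 bits (one universal granule). Adding attribute 17 drops
it by ≈92.8 bits to 2.25 — attribute 17 separates one class boundary
but leaves two classes mixed. Adding attribute 19 removes the remaining
2.25 bits: every granule is now class-pure, the entropy matches the
full 22-attribute set's, and the run converges having recovered exactly
the two planted informative attributes. The selected pair
cross-validates at accuracy 1.0.

## Command line

```sh
exec/fsace synth  --samples 60 --noise 20 --seed 1 --out table.csv --truth truth.json
exec/fsace select --input table.csv --label-col class --sigma 2 --output sel.json
exec/fsace sweep  --input table.csv --label-col class --sigma-grid 0.05:1:0.05 --output sweep.csv
exec/fsace evaluate --input table.csv --label-col class --subset sel.json --folds 10
```

Matrices are CSV/TSV, samples in rows (use `--transpose` for gene-major
files), labels in a designated column (`--label-col`) or a separate
single-column file (`--label-file`). Every output embeds the full run
configuration and package version; re-running with the embedded
configuration reproduces the file byte-for-byte.

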