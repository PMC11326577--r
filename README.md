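# depolyscan

Phage depolymerases are virion-associated enzymes that degrade the
surface polysaccharides (capsule, exopolysaccharide) of their bacterial
hosts to expose the phage receptor. They are prime candidates for
antibiofilm and capsule-stripping therapeutics, but their sequences are
extremely divergent: what is conserved is the *fold* of the catalytic
region — most often a right-handed β-helix, sometimes an n-bladed
β-propeller or an intertwined triple helix.

`depolyscan` detects depolymerases from protein sequence alone, for
phage biologists and genome annotators. It implements a two-stage
(stacked) classifier:

1. **Token stage.** Every residue *i* of a protein is classified into
   one of four fold labels
   *y<sub>i</sub>* ∈ {none, β-helix, β-propeller, triple helix}
   by a softmax layer over per-residue embedding features
   *x<sub>i</sub>* ∈ ℝ<sup>d</sup> from a pluggable backbone
   (a deterministic k-mer-context mock backbone is bundled; the
   published protein-language-model configurations are recognised but
   their weights are not shipped).
2. **Binary stage.** The per-residue class-probability sequence
   *P* ∈ ℝ<sup>L×4</sup> is scanned by two 1-D convolutional layers,
   pooled (global max + mean), and passed through two dense layers to
   a single probability *p* that the protein is a depolymerase; the
   call is *p* ≥ 0.5. The two stages are trained sequentially, the
   token stage being frozen while the head is fitted.

Around the model, the package provides the full supporting workflow:

- the **curation decision rules** used to assemble fold-confirmed
  training sets: discard sequences under 200 aa; accept a
  profile-search hit iff bit score > 20 with ≥ 30 aligned positions;
  accept a structural hit iff its match probability exceeds 0.5
  (0.2 for the divergent β-helix); keep the longest sequence of each
  identity cluster; cap diversity at 5 proteins per
  (embedding-cluster, annotation) pair — with parsers for the
  external tools' output dialects (CD-HIT `.clstr`, tabular
  structure/homology hits);
- **domain delineation**: projection of a best structural match onto
  protein units by a ≥ 50 % overlap rule, and extraction of contiguous
  domain segments from per-residue labels (majority-vote smoothing,
  minimum segment length);
- cluster-atomic **group-shuffle splitting** (70/20/10) so that
  near-identical sequences never straddle training and evaluation;
- a **synthetic data generator** producing proteins ≥ 200 aa with one
  contiguous fold-specific repeat domain per positive, plus hard
  negatives carrying decoy repeats;
- a **benchmark suite**: precision, recall, specificity, accuracy, F1,
  Matthews correlation coefficient
  MCC = (TN·TP − FN·FP) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
  precision–recall AUC (average precision), multi-tool comparison
  tables, and a false-positive reassessment adjustment.

## Worked example

```r
library(depolyscan)

cfg <- synthetic_config(n_positive_per_fold = 20, n_negative = 40, seed = 1)
ds  <- generate_dataset(cfg)           # 100 labelled proteins
set.seed(2)
idx   <- sample(100)
test  <- ds$labeled[idx[1:30]]
model <- depo_train(ds$labeled[idx[31:100]])
print(model)
#> Stacked depolymerase classifier
#>   backbone: mock (esm2_t12_35M_UR50D, dim 280)
#>   token stage: 70 training sequences, final loss 0.0366
#>   binary head: 70 training sequences, final loss 0.0009, threshold 0.50

res <- predict(model, lapply(test, `[[`, "record"))
print(res[[4]])
#> <prediction_result> pos_B_006: p(depolymerase)=1.0000 -> depolymerase
seg <- labels_to_segments(res[[4]]$token_labels)[[1]]
```

For that held-out protein the delineated domain is `[163, 258)` with
fold `BETA_HELIX`; the domain actually injected by the generator was
`[161, 261) BETA_HELIX` — the catalytic region is recovered to within a
few residues of each edge. Across the 30 held-out proteins:

```r
truth <- setNames(vapply(test, function(x) any(x$labels != "NONE"), TRUE),
                  vapply(test, function(x) x$record$id, ""))
calls <- setNames(vapply(res, `[[`, TRUE, "is_depolymerase"),
                  vapply(res, `[[`, "", "record_id"))
binary_metrics(binary_confusion(truth, calls))
#> <metrics_report> P=1.0000 R=1.0000 Sp=1.0000 Acc=1.0000 F1=1.0000 MCC=1.0000
micro_token_metrics(token_confusion(lapply(test, `[[`, "labels"),
                                    lapply(res, `[[`, "token_labels")))
#> <metrics_report> P=0.9803 R=0.9803 Sp=NA Acc=0.9803 F1=0.9803 MCC=0.9287
```

All sequence-level calls are correct and 98 % of the roughly 8,000
held-out residues carry the right fold label (micro-averaging makes
precision, recall, F1 and accuracy coincide; the multi-class MCC is the
generalised R<sub>k</sub> statistic).

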