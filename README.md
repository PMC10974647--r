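# admetfusion

Multi-task prediction of ADMET endpoints (absorption, distribution,
metabolism, excretion, toxicity) for drug-like molecules, fusing two
views of a compound: a block of 13 physicochemical descriptors and the
SMILES string itself, read by a transformer encoder. The package is
aimed at computational chemists and ML practitioners who want a fully
inspectable, dependency-light R implementation of the
descriptor-vs-sequence modelling question — where does the predictive
signal live?

## What is inside

* **`chem_data`** — DrugBank-style JSON/CSV readers, exclusion of
  drug-likeness filter flags, completeness filtering, merging of
  redundant raw labels (24 → 21: HIA absorbs Caco-2, p-gp inhibitor
  I+II merge, hERG I+II merge), and train-split z-score normalization.
* **`smiles_tokenizer`** — byte-pair-encoding tokenizer trained on SMILES
  corpora, with deterministic lexicographic tie-breaking and exact
  encode/decode round trips.
* **`mlm_pretrain`** — a transformer encoder (multi-head self-attention,
  GELU feed-forward, layer norm; explicit hand-written backpropagation,
  finite-difference-verified) pretrained with a RoBERTa-style
  masked-language-model objective (15% masking, 80/10/10).
* **`fusion_models`** — the six architectures: `dnn` (descriptors →
  10+10+10 → fused 30 → 21 labels), `encoder` (pooled H = 768 hidden
  vector → 21), `concat` (30 + 768 = 798 → 21), `pipe` (hidden vector →
  13 predicted descriptors → DNN stage → 21), and the self-attention
  variants `dnn_a` / `pipe_a` (dot-product attention over the three
  descriptor group vectors, tanh activation).
* **`trainer`** — 7:1.5:1.5 splits, summed per-label binary
  cross-entropy (+ stage-1 MSE for pipe), AdamW, early stopping with
  patience 5, max 30 epochs, multi-seed replication reported as
  "mean (sd)".
* **`evaluator`** — per-label accuracy / AUROC (Mann–Whitney with ties
  at one half) / F1 / precision / recall, six-model majority voting
  with the 3:3 tie broken by mean probability, and three CYP450
  substrate aggregation methods including hepatic-abundance-weighted
  soft voting (2C9 = 0.12, 2D6 = 0.04, 3A4 = 0.30).
* **`synthetic_chem`** — a generator of grammar-valid SMILES with a
  planted structural motif (`N(=O)=O`) that is independent of all 13
  descriptors by construction, plus feature-driven or structure-driven
  binary labels with controllable flip noise. Every experiment in the
  package runs on these synthetic molecules; no external download is
  needed.

A thin command-line interface wraps the same functions
(`system.file("cli", "admetfusion.R", package = "admetfusion")`) with
subcommands `simulate`, `tokenize`, `pretrain`, `train`, `evaluate`,
`ensemble` and `cyp-aggregate`, each writing a run manifest and JSONL
log.

## Worked example

```r
library(admetfusion)

## 2000 synthetic molecules whose labels depend only on a planted motif
sim    <- simulateMolecules(GeneratorConfig(nMolecules = 2000, seed = 101,
                                            labelMode = "structure_driven",
                                            noiseRate = 0.05))
splits <- splitMolecules(sim$molecules, seed = 101)
stats  <- fitNormalization(splits$train)
splits <- lapply(splits, applyNormalization, stats = stats)

## tokenizer + small MLM-pretrained encoder (H = 64 desk-scale config)
vocab <- trainBPE(smilesStrings(splits$train), vocabSize = 96)
ecfg  <- EncoderConfig(vocabSize = vocabSize(vocab), nLayers = 2,
                       nHeads = 2, hiddenSize = 64, ffSize = 128,
                       maxLen = 64)
enc   <- pretrainEncoder(initEncoder(ecfg, vocab, seed = 1),
                         smilesStrings(splits$train), epochs = 2,
                         learningRate = 1e-3, seed = 1)$encoder

tcfg <- TrainConfig(learningRate = 1e-3, nSeeds = 3, seeds = 1:3)
for (arch in c("dnn", "encoder")) {
  msr <- multiSeedRun(ModelConfig(arch, hiddenSize = 64), splits, tcfg,
                      encoder = if (arch == "dnn") NULL else enc)
  cat(arch, "test AUROC:", msr$summary, "\n")
}
```

Output from this exact script:

```
dnn test AUROC: 47.7 (1.2)
encoder test AUROC: 93.6 (0.0)
```

The descriptor-only DNN sits at chance — the labels depend on a
structural motif that is independent of every descriptor — while the
SMILES encoder recovers the motif and approaches the noise ceiling
(≈ 0.93 at 30% prevalence under 5% label flips). On feature-driven
labels the ordering reverses in the DNN's favour (it reaches ≈ 0.89).
See the vignette for the model details and the design rationale.

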