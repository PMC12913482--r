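# PhageHostNet

Dual-tower deep learning for predicting bacteriophage–bacterial host
interactions from whole genome sequences, in pure R (with C++ kernels).

## The problem

Choosing a phage that infects a given bacterial strain is the central
screening step of phage therapy against antibiotic-resistant infections,
and host assignment for uncultivated phages is a recurring task in viral
metagenomics. Alignment-based searches are insensitive for fast-evolving
phage genomes; alignment-free methods instead exploit the tendency of
phages to share k-mer compositional statistics with their hosts.
PhageHostNet implements a neural version of this idea for users who want
to train and evaluate such a model end to end, entirely offline: a
synthetic genome generator plants a controllable host-mimicry signal, so
every stage of the pipeline is testable without downloading a genome
database.

## The model

For a genome of length $N$:

* segmentation into $c = \lceil N/2000 \rceil$ windows of 2,000 bp
  (terminal padding; padded/ambiguous k-mer windows map to a zero-embedded
  `UNK` token);
* tokenization into overlapping k-mers ($k = 3$) embedded by a skip-gram
  model ($d = 64$), giving $X \in \mathbb{R}^{(2000-k+1) \times d}$ per
  window;
* a CNN tower per side (conv 3×3 → batch norm → ReLU, three blocks, max
  pooling after the first two, global average pooling) mapping each window
  to a 256-vector $Y_i$ (phage) or $Z_i$ (host); the towers share one
  architecture with independent parameters (pseudo-Siamese);
* a Transformer encoder per side (6 layers, 4 heads,
  $d_k = d_v = d_{model}/4 = 64$, residual connections + layer norm) over
  $[Y_{CLS}; Y_1; \dots; Y_c]$, whose final CLS row is the genome
  representation $C_{phage}$ or $C_{host}$;
* a fused classifier: $z = [C_{phage}; C_{host}] \in \mathbb{R}^{512}$
  through an MLP $512 \to 4096 \to 2$ and softmax; $p[2]$ is the match
  probability.

Training follows the stated protocol: cross-entropy + L2 (1e-3) inside
the loss, Adam (lr 1e-4, β₁ 0.9, β₂ 0.999), batch size 32, gradient
clipping at global norm 5.0, batch-norm moving statistics with decay
0.999, 200 epochs. Evaluation ranks every candidate host per phage by
$p_{match}$ (host representations cached) and scores accuracy at five
taxonomic ranks: genus, family, order, class, phylum.

The network and its backpropagation are hand-implemented (no deep-learning
framework); gradients are validated against finite differences and an
explicit-loop attention oracle in the test suite.

## Worked example

A complete desk-scale run — simulate a 4-phylum synthetic dataset with
20 kb genomes and strong (0.9) host mimicry, pretrain skip-gram
embeddings, train the reduced dual-tower model on 40 labeled pairs, and
evaluate 10 held-out phages — takes a few minutes on one CPU:

```r
library(PhageHostNet)
ex <- deskScaleExperiment(seed = 1)

ex$binary$accuracy
#> [1] 0.95                 # held-out binary accuracy over 20 pairs

rankAccuracies(ex$report)
#>  genus family  order  class phylum
#>    0.6    0.6    0.6    0.6    0.6  # top-1 host ranking, 10 phages x 8 hosts

ex$baseline_phylum
#> [1] 1                    # alignment-free cosine baseline sanity check
```

The held-out binary accuracy (19/20) shows the planted compositional
signal was learned (one-sided binomial p ≈ 2e-5 against chance); the
ranking accuracies are identical across ranks here because this synthetic
taxonomy has one lineage per phylum. The composition baseline confirms
the signal existed in the data independently of the network.

Individual stages are exposed directly (`simulateDataset()`,
`trainSkipgram()`, `initModel()`, `trainModel()`, `rankHosts()`,
`hierarchicalAccuracy()`, ...), and a YAML-driven workflow
(`runSimulate()`, `runEmbed()`, `runTrain()`, `runEvaluate()`, plus the
CLI wrapper `inst/scripts/phagehost.R`) ties them into reproducible run
directories with manifests.

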