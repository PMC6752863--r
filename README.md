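# thermonet

Protein-RNA binding intensity prediction that treats RNA structure as what
it thermodynamically is: an ensemble, not a single conformation.

RNA-binding proteins (RBPs) recognize short sequence motifs *and* the
structural context those motifs sit in — a motif presented in an accessible
hairpin loop is not the same binding site as the same motif buried in a
helix. `thermonet` predicts the binding intensity of an RBP to short RNAs
(RNAcompete-style 41-nt probes, CLIP-seq-style 101-nt windows) by
combining:

- **learned multi-length k-mer embeddings**: every k-mer (k = 1..k_m)
  starting at each position is embedded into a d-dimensional vector learned
  jointly with the predictor, giving an l x k_m·d sequence representation
  instead of an exponential 4^k one-hot encoding;
- **a Boltzmann ensemble of secondary structures**: N structures are
  sampled per sequence (bundled exact partition-function sampler, or any
  `RNAsubopt`-compatible executable), annotated per position into paired /
  hairpin / internal-loop / multiloop / external contexts, and the top T
  unique structures each drive their own rank-specific convolutional
  network, with the low-frequency remainder collapsed into an average
  structure profile for one extra network;
- **frequency-weighted combination**: the final prediction is
  `f(s) = Σ_{i≤min(T,U)} (m_i/N)·f_i + (1 − Σ m_i/N)·f_avg`,
  the Boltzmann-frequency-weighted average of the structure-specific
  predictions.

Each base network is five 1-D same-length convolution → batch-norm → ReLU
blocks plus a fully-connected head, trained individually with Huber loss,
L2 weight decay and Adam (learning rate dropped to one tenth after the 5th
epoch by default). A synthetic-benchmark module plants sequence-only and
hairpin-context binding signals so the whole pipeline — including the
ablation between sequence-only and structure-aware variants — is testable
at desk scale with no external data or executables.

## Worked example

```r
library(thermonet)

# a 2,000-record planted-signal dataset in the RNAcompete-style format
task <- plantedTask(mode = "sequence_only", n = 2500, seed = 11)
d <- generateDataset(task)
head(d, 3)
#>            id                                       seq  intensity
#> 1 synth_00001 CCUAUAAUCUACCCGCAGAGGACAGUGGCCGGGCUACGCUC  0.1409314
#> 2 synth_00002 GCAUUGUUAUGUAACAACAAGAUCUCACGAAUGUCCAUCCC  2.3580194
#> 3 synth_00003 ACAGUGUGUCGGGUGGGUGUUGUACUAAAUCUGGCUAGAAU -0.1011895

# sample and tally a structure ensemble for one probe
tal <- tallyUnique(sampleEnsemble(d$seq[1], n = 100, seed = 1))
tal
#> EnsembleTally: N=100 samples, U=100 unique, l=41 nt
#>   m_1=  1  (((((..((..(.(...).))).).))...))((...)..)
#>   m_2=  1  (((((....(.(...(...))).).)))..)(((...)).)
#>   ...

# train the full model (T rank-specific networks + average-profile network)
fit <- trainThermoNet(
    data.frame(seq = d$seq[1:2000], y = d$intensity[1:2000]),
    networkConfig(l = 41),
    trainConfig(learningRate = 3e-3, l2 = 1e-3, epochs = 40,
                batchSize = 16, lrDropEpoch = 30, patience = 8, seed = 11))

# held-out evaluation
pred <- predictIntensity(fit, d$seq[2001:2500], seed = 99)
pearson(pred, d$intensity[2001:2500])
#> [1] 0.9340042
```

The held-out Pearson correlation of 0.93 means the model recovers the
planted motif signal (the noise floor of the task caps attainable
correlation near 0.96). For a structure-dependent task, generate with
`mode = "hairpin_context"` — there the target is proportional to the
probability that the motif sits entirely in a hairpin loop, and
`runAblation()` compares the model variants: over three seeded
replicates the full model beats the sequence-only (`k-no-struc`) variant
in every replicate and is non-inferior on the mean to the
average-profile-only (`k-struc`) variant.

A thin CLI wraps the same functions:

```sh
exec/thermonet sample --seq GGGCGCAAGCCUAAGGCGCCC --n 10 --seed 1
exec/thermonet benchmark --mode hairpin_context --n 2000 --seed 1 --out bench/
exec/thermonet evaluate --metric pearson --pred pred.tsv --truth bench/data.tsv
```

## Package layout

- `R/`, `src/` — structure ensemble machinery (Rcpp partition
  function/sampler), k-mer embeddings, the fused RcppArmadillo CNN kernel,
  training/grid search, datasets and metrics, synthetic benchmark, ablation.
- `tests/testthat/` — unit, property and acceptance tests with independent
  brute-force oracles (exhaustive structure enumeration, pairwise AUROC,
  finite differences).
- `vignettes/thermonet-methods.Rmd` — the model, its assumptions, parameter
  meanings, and the design decisions behind the bundled sampler and the
  synthetic benchmark.
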