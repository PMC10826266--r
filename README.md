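# panMHCII

Pan-specific prediction of peptide binding affinity to MHC class II
molecules, with calibrated sinusoidal positional encoding and 9-mer
binding-core calling.

MHC-II molecules present 9–22-residue peptides to CD4 T cells through an
open-ended groove: a 9-residue **binding core** occupies the groove
(specificity dominated by pockets 1, 4, 6, 9) while flanking residues
modulate affinity. Instead of one model per allelic variant, a
*pan-specific* model conditions a single regressor on the allele's
34-residue pseudo-sequence `Q`. The predictor is a **binding-interaction
convolutional layer** (BICL): convolution kernels are *generated* from
the MHC representation,

    C_Emb = f( f(W^k Y) X + b^k ),   f = ReLU,

with kernel sizes s^k ∈ {9, 11, 13, 15} (h^k ∈ {256, 128, 64, 64}
kernels), embedding width d = 16, so every allele convolves the peptide
embedding `X` with its own filters. Peptides are zero-padded into a
26-position frame; sinusoidal positional encodings

    PE(pos, 2k)   = sin(pos / 1000^(2k/d))
    PE(pos, 2k+1) = cos(pos / 1000^((2k+1)/d))

can be injected **pre** (added to the embeddings) or **post** (a separate
learned convolution added to the BICL output), on the peptide alone (O)
or on peptide and MHC together (T), using either **direct** encodings
(numbering the padded frame, so a residue's code depends on where the
padding fell) or **calibrated** encodings (numbering true residues
1..L', all pads sharing the position-0 code) — eight strategies plus the
PE-free baseline, all selectable per model. Affinity (ẑ ∈ [0,1], the
conventional `1 − log(IC50)/log(50000)` scale) and the binding core are
predicted by one mechanism: every candidate 9-mer register gets a logit
from the kernels centred on it, registers are pooled log-sum-exp
(a Boltzmann ensemble), and the top register is the core. Training uses
MSE, Adadelta (lr 0.9, weight decay 1e-4), batches of 128, ensembles of
T = 20, and motif-grouped 5-fold cross-validation. A synthetic-data
generator with implanted anchor-pocket motifs makes the whole pipeline
testable without external benchmark downloads.

## Worked example

```r
library(panMHCII)

sim <- simulateDataset(nAlleles = 2, nPerAllele = 500, seed = 1)
recs   <- bindingRecords(sim)
train  <- recs[recs$split == "train", ]
test   <- recs[recs$split == "test", ]
pseudo <- pseudoMap(sim)

cfg <- trainConfig(epochs = 30, ensembleSize = 1)
fit <- trainModel(train, pseudo, cfg, seed = 1)
fit

pred  <- predictAffinity(fit, test, pseudo)
perAlleleReport(test, pred)

cores <- predictBindingCore(fit, test, pseudo)
coreAccuracy(cores$coreStart[test$binder], test$coreStart[test$binder])
```

```
BiclModel: baseline (no PE) | d=16 Lmax=26 | kernels 9/11/13/15 x 256/128/64/64 | 188834 parameters
   allele   n       auc       pcc      srcc        mse
1  SYN-01 100 0.9203869 0.7540045 0.7471587 0.02071487
2  SYN-02 100 0.9061772 0.6428665 0.5568677 0.03530926
3 Average 200 0.9132820 0.6984355 0.6520132 0.02801207
$exactMatchRate
[1] 0.5145631

$meanOverlap
[1] 0.8360302
```

Training takes about half a minute on one CPU.

The report gives per-allele AUC (binder cutoff 0.426 ≙ 500 nM), Pearson
and Spearman correlations and MSE on the held-out split, plus their
unweighted average; `coreAccuracy` scores predicted against true core
registers over the held-out binder complexes (exact register match and
mean 9-mer overlap). A PE strategy is chosen with
`trainConfig(strategy = peStrategy("calibrated", "pre", "T"))`.

A thin command-line wrapper (`inst/scripts/panmhc2`) exposes
`simulate`, `train`, `cv`, `predict`, `evaluate`, `core`, `logo` and a
`sweep` command that trains all eight PE strategies plus the baseline
and writes a per-allele AUC comparison table.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch — simulates
the two-allele benchmark, trains the baseline model, and reports
held-out affinity metrics and binder-core accuracy to stderr — then
writes the JSON report to `--out`.
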