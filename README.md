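# m6arec

Sequence-only recognition of N6-methyladenosine (m6A) modification sites
in RNA, for researchers who have fixed-length candidate windows (a
101-nt window centered on an adenosine, in the usual deposition format)
and want a site classifier that uses nothing but the sequences and the
relationships among them — no physicochemical descriptors, conservation
tracks or pretrained language models.

## The model

For a set of $m$ windows, each window $X$ is encoded as its normalized
3-mer frequency vector $R_X \in \mathbb{R}^{64}$ (columns in
lexicographic A<C<G<U order, $\sum_j R_X^j = 1$). Pairwise Manhattan
distances $d_{ij} = \sum_j |R_i^j - R_j^j|$ give a dataset-level
similarity structure $S \in [0,1]^{m \times m}$ (order-reversing rbf
transform, median bandwidth). A small Transformer encoder over the 3-mer
token streams yields per-sequence embeddings whose thresholded,
normalized pairwise distances define a binary structure graph
$G_{st} \in \{0,1\}^{m \times m}$.

Both graphs are embedded by a **self-correlation graph convolutional
autoencoder**: a learnable initial node matrix $Er \in \mathbb{R}^{m
\times m}$ (no prior node features exist for sequence windows) passes
through three symmetric-normalized graph convolutions
$H_i = \mathrm{ReLU}(\tilde D^{-1/2}(\tfrac12(A+A^\top)+I)\tilde
D^{-1/2} H_{i-1} W_i)$ accumulated in a scaled residual stream
($\alpha_i = i/(I+1)$), trained end-to-end with the dual
adjacency-reconstruction loss

$$\mathcal{L} = \mathrm{BCE}(\sigma(E_{sm}E_{sm}^\top), S)
             + \mathrm{BCE}(\sigma(E_{st}E_{st}^\top), G_{st}),$$

with the structure graph periodically refreshed from the (co-trained)
Transformer. Branch embeddings and the raw 3-mer vector are combined by
gated local-global fusion, $e^{fi} = w' e^{ss} + (1-w') e^{km}$, and the
fused features are classified by random forest under stratified 10-fold
cross-validation (metrics: MCC, Acc, Sn, Sp, Prec, F1, AUC, AUPR).

All neural components (Transformer encoder, graph convolutions, fusion
blocks, Adam) are implemented in plain R matrix algebra with
hand-derived gradients, each verified against finite differences in the
test suite. See `vignettes/m6arec-methods.Rmd` for the full method
description and design rationale.

## Worked example

```r
library(m6arec)

# a labelled benchmark dataset: 101-nt windows, central A, positives
# carry a noised GGACU context (eps = difficulty knob)
d <- synth_generate(synth_config(m = 400, eps = 0.1, seed = 1))
d$sequences
#> rna_set: 400 windows of length 101 (400 labelled, 200 positive)

# full pipeline at a reduced profile (see the methods vignette)
cfg <- m6a_config(epochs = 100, lr = 5e-3, refresh_every = 20,
                  fusion_epochs = 100, fusion_lr = 1e-2,
                  tf = transformer_config(d_model = 16, heads = 2,
                                          ff_dim = 64, blocks = 2,
                                          seed = 1),
                  seed = 1)
res <- m6a_run(d$sequences, cfg, classifier = "rf")
res$report[res$report$Fold == "Mean", ]
#>    Fold       MCC    Acc    Sn   Sp      Prec        F1      AUC      AUPR
#> 11 Mean 0.6825035 0.8375 0.845 0.83 0.8418539 0.8390446 0.903625 0.9000376
```

The mean row reads like a standard fold-wise evaluation table: at
difficulty 0.1 the recognizer recovers the planted signal with a mean
cross-validated AUC of about 0.90; at `eps = 0` the benchmark is nearly
noiseless and the AUC exceeds 0.95, and by `eps = 0.4` it decays toward
chance — the graded-difficulty sweep in the test suite checks exactly
this ordering. Individual stages are exposed as plain functions
(`kmer_encode()`, `kmer_distance_matrix()`, `build_structure_graph()`,
`train_embeddings()`, `fused_features()`, `cross_validate()`, ...) and a
command-line wrapper lives at `inst/cli/m6arec.R`:

```sh
Rscript inst/cli/m6arec.R synth --m 1000 --eps 0.1 --out bench
Rscript inst/cli/m6arec.R run --fasta bench/synthetic.fa --out bench
```

Real data drop in the same way: `read_rna_windows("windows.fa")` accepts
FASTA with `label=0|1` header tags or a two-column TSV of labels.

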