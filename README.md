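# priorquant

Prior-enhanced transcript quantification from RNA-seq, guided by ChIP-seq
evidence of transcription.

## The problem

Short RNA-seq fragments often align to several isoforms of a gene, to
overlapping genes, or to homologous loci.  Allocation of these
multimapping fragments normally leans on uniquely mapping reads — but an
*indistinguishable* isoform (one whose every possible fragment also
aligns to another isoform) has none, and its abundance cannot be pinned
down by the RNA-seq likelihood alone.  The practical consequence is
false-positive expressed calls: silent isoforms that absorb shared reads
and end up above the usual 1-TPM cutoff.

`priorquant` is for transcriptomics analysts who also have ChIP-seq of
RNA polymerase II (or histone modifications) for the same cells.  Peaks
near transcription start sites predict which isoforms are transcribed,
and that knowledge can be turned into a quantitative prior.

## The method

1. **Process external data.** Isoform TSSs are grouped (single linkage,
   500 nt); a TSS group *has a peak* when a ChIP-seq peak overlaps the
   500-nt flank of its TSS.
2. **Learn prior parameters.** From a training set of isoforms whose
   peaks and reads are uniquely assignable, partitioned by peak status
   (with-peak / no-peak by default), a Dirichlet–multinomial model

   $$P(n) = \frac{\Gamma(N+1)}{\prod_i \Gamma(n_i+1)}
            \frac{\Gamma(A)}{\Gamma(N+A)}
            \prod_i \frac{\Gamma(n_i+\alpha_{g(i)})}{\Gamma(\alpha_{g(i)})},
     \qquad A = \sum_i \alpha_{g(i)},$$

   is fitted to the maximum-likelihood fragment counts $n_i$ of the
   training isoforms, yielding one pseudocount $\alpha_g$ per partition.
3. **Apply the prior.** A collapsed Gibbs sampler reallocates fragments
   with $P(z_r = (i,p) \mid z_{-r}) \propto (\alpha_i + n_i^{-r}) /
   \tilde\ell_i$; the pseudocounts act as prior fragment counts, and
   posterior-mean abundances are reported in TPM alongside the ML
   estimates.

A structural read simulator and an FPR/FNR benchmark harness are
included, so the whole workflow runs end-to-end on synthetic data with
known truth.  See the methods vignette (`vignettes/methods.Rmd`) for the
model, conventions and design decisions.

## Worked example

Generate a synthetic bundle (annotation, peaks, simulated alignments),
learn the prior and quantify:

```r
library(priorquant)
fx <- make_fixtures("demo", seed = 42, scale = 2, n_fragments = 30000)
cfg <- run_config(annotation = fx$gtf, peaks = fx$peaks,
                  alignments = fx$sam, out_dir = "demo/out", seed = 42)
trained <- cmd_train_prior(cfg)
#> train-prior: 18 training units; alpha = 0.4487, 0.03135; logLik = -83.721523
quant <- cmd_quantify(cfg, trained$prior)
#> quantify: 28400 aligned reads over 24 transcripts
```

The learned pseudocounts say: an isoform with a Pol II TSS peak is worth
about 0.45 prior fragments, one without a peak about 0.03 — the external
data strongly separates expressed from silent isoforms.  The effect is
visible on the fixture's "mixed" gene, whose no-peak isoform `A2` is
structurally indistinguishable (every `A2` fragment also aligns to `A1`):

```r
tab <- read.delim(quant$quantification)
tab[tab$gene_id == "geneA", c("transcript_id", "TPM",
                              "posterior_mean_TPM", "alpha")]
#>   transcript_id    TPM posterior_mean_TPM   alpha
#> 1            A1 112593             118526 0.44874
#> 2            A2   9617               1216 0.03135
```

Maximum likelihood hands `A2` nearly 10,000 TPM of shared reads; under
the learned prior those reads move to the with-peak isoform `A1`, and
`A2` falls by a factor of eight.  In simulations with known truth this
read-shifting behaviour translates into a much lower false-positive
rate at a small false-negative cost.

The same pipeline is available from a shell via the thin wrapper
`inst/scripts/priorquant`:

```sh
Rscript inst/scripts/priorquant make-fixtures out_dir=demo seed=42
Rscript inst/scripts/priorquant train-prior annotation=demo/annotation.gtf \
    peaks=demo/peaks.narrowPeak alignments=demo/alignments.sam \
    out_dir=demo/out seed=42
```

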