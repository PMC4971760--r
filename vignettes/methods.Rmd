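---
title: "Prior-enhanced transcript quantification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-enhanced transcript quantification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorquant)
```

## The problem

Short RNA-seq fragments are frequently compatible with several
alternatively spliced isoforms of a gene, with overlapping genes, or with
homologous loci.  Estimators that allocate such multimapping fragments
purely from the RNA-seq likelihood must lean on uniquely mapping reads,
and an *indistinguishable* isoform — one for which every possible fragment
also aligns to some other isoform — has none.  For these isoforms the
likelihood is flat (or nearly flat) along the direction that moves
abundance between the isoform and its sibling, and point estimates or
uninformative-prior posterior means place substantial mass on isoforms
that may not be transcribed at all.

`priorquant` addresses this by bringing in a complementary signal that is
informative about *transcription* rather than about read compatibility:
ChIP-seq peaks of RNA polymerase II (or histone modifications) near
transcription start sites.  Isoforms are partitioned by that external
evidence, a Dirichlet prior with one pseudocount per partition is learned
from the RNA-seq data itself, and posterior-mean abundances are computed
under that prior.

## Model

### Quantification core

Each aligned fragment $r$ carries a set of candidate alignments
$A_r = \{(i, p)\}$ (transcript, start position).  Positions are uniform
over the $\tilde\ell_i$ valid starts of transcript $i$ (the *effective
length*), so the likelihood of the fragment-generating probabilities
$\theta$ is

$$ L(\theta) = \prod_r \sum_{(i,p) \in A_r} \theta_i / \tilde\ell_i . $$

The maximum-likelihood estimator is the standard EM with
responsibilities $\gamma_{ri} \propto \theta_i/\tilde\ell_i$ and update
$\theta_i = \sum_r \gamma_{ri} / N$.  Abundances are reported as TPM,
$\mathrm{tpm}_i = 10^6 (\theta_i/\tilde\ell_i) / \sum_j
(\theta_j/\tilde\ell_j)$.

In the Bayesian formulation $\theta \sim
\mathrm{Dirichlet}(\alpha_1, \dots, \alpha_M)$ and the sampler is a
collapsed Gibbs chain over fragment assignments $z_r$:

$$ P(z_r = (i,p) \mid z_{-r}) \propto (\alpha_i + n_i^{-r}) /
   \tilde\ell_i, $$

where $n_i^{-r}$ counts fragments currently assigned to $i$ excluding
$r$.  The pseudocounts $\alpha_i$ act exactly like prior fragment
counts.  After burn-in the posterior-mean count is the average of $n_i$
and the posterior-mean probability is $(\alpha_i + \bar n_i)/(A + N)$
with $A = \sum_i \alpha_i$; with only uniquely mapping reads this
reduces to the conjugate closed form $(n_i + \alpha_i)/(N + A)$, which
the test suite checks exactly.

This read model is deliberately simpler than a full aligner-aware model:
there are no base qualities, no sequencing-error model, no positional or
orientation bias, and no noise transcript in the inference model.
Compatibility is *structural*: a fragment of one isoform aligns to
another isoform exactly when its genomic exonic footprint is a contiguous
sub-path of the other's exon chain.  Cross-locus multimapping is declared
through explicit homology groups rather than discovered from sequence.
The package's contribution is the prior, not the read model, and the
structural model keeps every component deterministic and testable without
an aligner.

### Chain initialisation

The sampler starts from one draw of the read responsibilities at the
*posterior mode* under its own prior, obtained by a MAP variant of the EM
(M-step adds $\alpha_i - 1$ to the expected counts and truncates at
zero).  For a uniform pseudocount of 1 the MAP solution coincides with
maximum likelihood, so the classic uninformative-prior baseline is
initialised at the ML solution.  Initialising at the mode matters in
practice: single-read Gibbs updates mix slowly along the flat direction
created by a contained isoform, so a chain started far from the mode
retains a visible bias at any affordable chain length.  Starting at the
mode makes finite chains well-behaved for exactly the isoforms the prior
is meant to regularise.

### Learning the prior

A training set is built from isoforms whose external evidence is
unambiguous: (a) their isoform-TSS-group window overlaps no other group's
window, and (b) their gene's exonic span overlaps no other gene.  These
two conservative rules are configurable; they are this package's own
construction for "uniquely assignable" evidence.  Training counts are the
ML expected counts (fractional values are used as-is; all likelihood
computations go through `lgamma`).

With partition labels $g(i)$ and per-partition pseudocounts
$\alpha_g$, the training counts follow a Dirichlet-multinomial:

$$ \log P(n) = \log\frac{\Gamma(N+1)}{\prod_i \Gamma(n_i+1)}
   + \log\frac{\Gamma(A)}{\Gamma(N+A)}
   + \sum_i \log\frac{\Gamma(n_i + \alpha_{g(i)})}{\Gamma(\alpha_{g(i)})},
   \qquad A = \sum_i \alpha_{g(i)} . $$

The multinomial coefficient is constant in $\alpha$ but retained so that
reported log-likelihoods are true log-probabilities for integer counts.
`fit_prior()` maximises this over $\log\alpha$ with L-BFGS-B, bounds
$[10^{-4}, 10^{4}]$, initial value $\alpha = 1$ and a log-likelihood
tolerance of $10^{-6}$; none of these constants is data-dependent, and
degenerate inputs legitimately end on a bound (under-dispersed counts
drive $\alpha$ to the upper bound, an all-or-nothing count vector to the
lower).  After the optimiser stops, each coordinate is compared against
its bounds and moved there when the bound is at least as good, which
protects the monotone-likelihood cases from premature termination.

### Partition models

* `two_partition_peak` (default): with-peak vs. without-peak, where an
  isoform has a peak when a ChIP-seq peak overlaps the 500-nt flank of
  its TSS (inclusive on both sides).
* `signal_quantile(k)`: $k$ signal-quantile groups.
* `peak_plus_signal`: no-peak units in one partition; with-peak units
  split at their median signal.
* `logistic_combined`: logistic regression of an expressed flag
  (ML TPM $\ge$ 1 on the training units) on `log1p` signals of all
  marks, thresholded at fitted probability 0.5.
* `no_partition`: a single pseudocount, the "uniform small prior"
  variant.

The quantile split, the median split and the permutation-based
informativeness test below are this package's own constructions standing
in for procedures whose published descriptions are brief; they are
labelled as such here deliberately.

Candidate prior sources are compared by their maximised training-set
log-likelihood (ties broken lexicographically by name), and a
permutation test measures whether a two-level labelling is informative at
all: the statistic is the log-likelihood gain of the two-partition fit
over the single-partition fit (non-negative by nesting), the null is
obtained by permuting labels, and the p-value uses the add-one
convention.  Under the null the p-value is approximately uniform; at a
15:1 pseudocount ratio the test essentially always rejects — both
properties are exercised in the test suite.

## Synthetic data

`make_fixtures()` writes a small genome that contains every structure
the workflow must handle: a gene with a structurally indistinguishable
isoform, genes with "mixed" TSS-peak status, an overlapping gene pair
(training-ineligible), a cross-chromosome homology group, and a panel of
clean single-isoform training genes with peak-correlated expression.
Truth is drawn from a partitioned Dirichlet with pseudocounts 0.60
(with peak) and 0.04 (no peak) — the scale a Pol II-derived prior takes
on real data — and fragments are generated with a fixed fragment length
(default 100 nt) and a 5% unaligned noise fraction that counts toward
library depth.

The benchmark annotation (`sim_annotation()`) uses 25 two-isoform genes
in which the no-peak isoform is a 3'-exon of its with-peak sibling —
every one of its fragments is shared — plus 50 short single-isoform
context genes.  The context genes matter: TPM is a per-million measure,
so the per-transcript pseudocount floor of an estimator depends on the
transcriptome-wide density $\sum_j \theta_j/\tilde\ell_j$.  With short
expressed context transcripts setting a realistic density, a pseudocount
of 1 keeps every truly-silent isoform above the 1-TPM expressed cutoff
while a learned pseudocount of 0.04 does not — which is precisely the
regime in which an informative prior can demonstrate its value.  Default
benchmark settings are 50,000 fragments per replicate and Gibbs chains
of 150 burn-in plus 250 retained sweeps; these sizes were chosen so a
50-replicate benchmark completes on a laptop-class machine while leaving
the false-positive contrast far from its decision thresholds.

What the generator does *not* emulate: sequence content and mappability,
fragment-length variability (the simulator is fixed-length;
`effective_lengths()` itself accepts a distribution), positional bias,
and sequencing error.  Passing benchmarks therefore demonstrate the
statistical behaviour of the allocation machinery, not robustness to
alignment artefacts on real data.

## Numerical choices and conventions

* Coordinates are 0-based half-open internally; GTF input (1-based
  closed) is converted on read.  The TSS is the first exon start on
  `+`, the last exon end minus one on `-`.
* TSS groups: single-linkage clustering of same-gene TSSs at an
  inclusive 500-nt threshold; the representative TSS is the minimum
  member coordinate.
* Window signal is the *sum* of overlapping peak signals; the
  5'-end signal helper uses a 100-nt flank and reads-per-million, with a
  read counted once per group.
* Expressed calls are inclusive (TPM $\ge$ cutoff, default 1).
* EM: uniform initialisation, relative log-likelihood tolerance
  $10^{-8}$, cap $10^4$ iterations; the log-likelihood trace is
  monotone and asserted as such.
* Gibbs: defaults 1000 retained samples after 500 burn-in, single
  chain, thinning 1; identical seeds give bit-identical output.
  Posterior-mean TPM is computed from the posterior-mean $\theta$, not
  as a mean of per-sample TPMs.
* MAP truncation can zero every candidate of a read during
  initialisation; such reads fall back to flat positional weights.
* FPR/FNR use the empty-denominator-is-zero convention.

## Parameter-recovery behaviour

`fit_prior()` is consistent but the small-pseudocount coordinate is
noisy at moderate training sizes: with 500 units per partition and
$N = 5\times10^4$ total counts, the with-peak pseudocount is recovered
within a few percent in every seed while individual-seed estimates of
the 0.04 pseudocount can deviate by ~25%.  The acceptance test therefore
checks the seed-averaged estimate (both coordinates within ±20% of
truth) alongside per-seed bounds for the well-identified coordinate, and
the unit tests check that the median error shrinks as the training set
grows.

## Known limitations

* No paired-end insert modelling, bias correction, credibility
  intervals, or multi-chain convergence diagnostics.
* Peak calling and ChIP-seq quality control are out of scope; peaks are
  taken as given (narrowPeak/BED6).
* The structural compatibility model cannot represent partial-homology
  multimapping; homology groups are all-or-nothing at equal offsets.
* Training-set eligibility is conservative; on sparse annotations it can
  empty the training set, which is reported as an error rather than
  silently relaxed.
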