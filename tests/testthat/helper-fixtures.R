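# Shared toy objects and independent oracles used across the suite.

# two-exon / contained-isoform gene: A = [0,300)+[500,800), B = [0,300)
toy_gene <- function() {
  transcript_set(rbind(
    data.frame(transcript_id = "A", gene_id = "g", chrom = "c",
               strand = "+", start = c(0, 500), end = c(300, 800)),
    data.frame(transcript_id = "B", gene_id = "g", chrom = "c",
               strand = "+", start = 0, end = 300)))
}

# exonic base vector of a transcript, in genomic order
tx_bases <- function(ts, id) {
  ex <- ts$exons[[id]]
  unlist(lapply(seq_len(nrow(ex)), function(k) ex[k, 1]:(ex[k, 2] - 1L)))
}

# brute-force distinguishability oracle: a fragment (contiguous slice of
# the origin's base vector) aligns to j iff its bases occur as a contiguous
# run of j's base vector
oracle_distinguishability <- function(ts, L) {
  tx <- ts$tx
  out <- lapply(seq_len(nrow(tx)), function(i) {
    id <- tx$transcript_id[i]
    bases <- tx_bases(ts, id)
    sib_ids <- tx$transcript_id[tx$gene_id == tx$gene_id[i] &
                                tx$transcript_id != id &
                                tx$chrom == tx$chrom[i] &
                                tx$strand == tx$strand[i]]
    sib_bases <- lapply(sib_ids, tx_bases, ts = ts)
    n_start <- length(bases) - L + 1L
    witness <- 0L
    if (n_start >= 1L) {
      for (s in seq_len(n_start)) {
        frag <- bases[s:(s + L - 1L)]
        hit <- any(vapply(sib_bases, function(bj) {
          k <- match(frag[1L], bj)
          !is.na(k) && k + L - 1L <= length(bj) &&
            all(bj[k:(k + L - 1L)] == frag)
        }, logical(1L)))
        if (!hit) witness <- witness + 1L
      }
    }
    data.frame(transcript_id = id, indistinguishable = witness == 0L,
               witness_fragments = witness, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# exact posterior mean of theta for small compatibility matrices by
# enumerating every assignment vector: P(z) ~ prod_r 1/eff[z_r] *
# prod_i Gamma(alpha_i + n_i) / Gamma(alpha_i)
oracle_posterior_mean <- function(read_candidates, eff, alpha) {
  M <- length(eff)
  grids <- expand.grid(read_candidates, KEEP.OUT.ATTRS = FALSE)
  wsum <- 0
  mean_theta <- numeric(M)
  N <- length(read_candidates)
  A <- sum(alpha)
  for (row in seq_len(nrow(grids))) {
    z <- as.integer(grids[row, ])
    n <- tabulate(z, M)
    logw <- -sum(log(eff[z])) + sum(lgamma(alpha + n) - lgamma(alpha))
    w <- exp(logw)
    wsum <- wsum + w
    mean_theta <- mean_theta + w * (alpha + n) / (A + N)
  }
  mean_theta / wsum
}

# direct likelihood of a 2-transcript compatibility matrix at theta_A = x,
# used by the grid-search EM oracle
grid_search_2tx <- function(reads, eff, step = 1e-3) {
  # reads: list of integer vectors over {1, 2} (candidate transcripts)
  xs <- seq(step, 1 - step, by = step)
  ll <- vapply(xs, function(x) {
    theta <- c(x, 1 - x)
    sum(vapply(reads, function(cand)
      log(sum(theta[cand] / eff[cand])), numeric(1L)))
  }, numeric(1L))
  xs[which.max(ll)]
}

# simulate a training set from the Dirichlet-multinomial model
simulate_dm_counts <- function(alpha_per_unit, N, seed) {
  set.seed(seed)
  p <- rgamma(length(alpha_per_unit), shape = alpha_per_unit)
  p <- p / sum(p)
  as.numeric(stats::rmultinom(1, N, p))
}

# write a minimal GTF for a transcript table (1-based closed coordinates)
write_toy_gtf <- function(path, lines) writeLines(lines, path)
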