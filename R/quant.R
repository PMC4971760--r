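#' Read-to-transcript compatibility matrix
#'
#' The sole read evidence used by the EM and Gibbs estimators: for each
#' read, the set of (transcript, position) alignments.  Positions are
#' 0-based offsets into the transcript and must lie in `[0, eff_length)`.
#'
#' @param alignments data.frame with `read_id`, `transcript_id`, `pos`.
#' @param depth Total library depth including unaligned (noise) reads;
#'   defaults to the number of aligned reads.
#' @return Object of class `compat_matrix`: `aln` (alignment table with an
#'   integer `read` index), `read_ids`, `N` (aligned reads), `depth`.
#' @export
compat_matrix <- function(alignments, depth = NULL) {
  stopifnot(all(c("read_id", "transcript_id", "pos") %in% names(alignments)))
  if (anyDuplicated(alignments[, c("read_id", "transcript_id", "pos")]))
    stop("duplicate (read, transcript, pos) alignment")
  if (nrow(alignments) > 0L && any(alignments$pos < 0))
    stop("alignment positions must be non-negative")
  read_ids <- unique(alignments$read_id)
  aln <- data.frame(read = match(alignments$read_id, read_ids),
                    transcript_id = as.character(alignments$transcript_id),
                    pos = as.integer(alignments$pos),
                    stringsAsFactors = FALSE)
  aln <- aln[order(aln$read), , drop = FALSE]
  N <- length(read_ids)
  structure(list(aln = aln, read_ids = as.character(read_ids), N = N,
                 depth = if (is.null(depth)) N else depth),
            class = "compat_matrix")
}

#' @export
print.compat_matrix <- function(x, ...) {
  cat("compat_matrix:", x$N, "aligned reads,", nrow(x$aln),
      "alignments, depth", x$depth, "\n")
  invisible(x)
}

#' Read transcriptome alignments (minimal SAM dialect or TSV)
#'
#' The SAM dialect uses the mandatory columns QNAME, FLAG, RNAME
#' (transcript id) and POS (1-based); multiple records per QNAME encode
#' multimapping, FLAG bit 0x4 marks an unaligned (noise) read which is
#' excluded from the matrix but counted in the library depth.  The TSV
#' format has columns `read_id`, `transcript_id`, `pos` (0-based) with a
#' header.
#'
#' @param path Alignment file.
#' @param format `"sam"` or `"tsv"`.
#' @return A [compat_matrix()].
#' @export
read_alignments <- function(path, format = c("sam", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    return(compat_matrix(dt))
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L) stop("no alignment records in ", path)
  dt <- data.table::fread(text = body, sep = "\t", header = FALSE,
                          fill = TRUE, data.table = FALSE)
  qname <- as.character(dt[[1L]])
  flag <- as.integer(dt[[2L]])
  unaligned <- bitwAnd(flag, 4L) != 0L
  aln <- data.frame(read_id = qname[!unaligned],
                    transcript_id = as.character(dt[[3L]][!unaligned]),
                    pos = as.integer(dt[[4L]][!unaligned]) - 1L,
                    stringsAsFactors = FALSE)
  depth <- length(unique(qname))
  compat_matrix(aln, depth = depth)
}

# validate the compat matrix against an effective-length universe and
# return an environment of indexed structures shared by EM and Gibbs
.index_compat <- function(compat, eff) {
  stopifnot(inherits(compat, "compat_matrix"))
  if (compat$N < 1L) stop("no aligned reads to quantify")
  tx_ids <- names(eff)
  idx <- match(compat$aln$transcript_id, tx_ids)
  if (anyNA(idx)) {
    miss <- unique(compat$aln$transcript_id[is.na(idx)])
    stop("read aligned to unknown transcript: ",
         paste(utils::head(miss, 3L), collapse = ", "))
  }
  if (any(compat$aln$pos >= eff[idx]))
    stop("alignment position beyond the transcript's effective length")
  ord <- order(compat$aln$read)
  list(tx_ids = tx_ids, M = length(tx_ids),
       read = compat$aln$read[ord], tx = idx[ord], N = compat$N)
}

.tpm_from_theta <- function(theta, eff) {
  dens <- theta / eff
  1e6 * dens / sum(dens)
}

# Shared EM core.  With `alpha = NULL` this is plain maximum likelihood;
# with pseudocounts it maximises the Dirichlet posterior (MAP), whose
# M-step adds alpha_i - 1 to the expected counts and truncates at zero —
# for alpha = 1 the two coincide.  Returns theta, expected counts and the
# objective trace.
.em_core <- function(ix, inv_eff, alpha = NULL, tol = 1e-8,
                     max_iter = 1e4) {
  M <- length(inv_eff)
  theta <- rep(1 / M, M)
  ll_old <- -Inf
  ll_trace <- numeric(0L)
  cnt <- numeric(M)
  for (iter in seq_len(max_iter)) {
    w <- theta[ix$tx] * inv_eff[ix$tx]
    den <- as.numeric(rowsum(w, ix$read))  # reads are 1..N, already sorted
    if (!is.null(alpha) && any(den == 0)) {
      # MAP truncation can zero out every candidate of a read; give such
      # reads flat positional weights so responsibilities stay defined
      zero <- den[ix$read] == 0
      w[zero] <- inv_eff[ix$tx][zero]
      den <- as.numeric(rowsum(w, ix$read))
    }
    ll <- sum(log(den))
    if (is.null(alpha) && ll < ll_old - 1e-9 * (abs(ll_old) + 1))
      stop("EM log-likelihood decreased; this indicates a bug")
    ll_trace <- c(ll_trace, ll)
    gamma <- w / den[ix$read]
    rs <- rowsum(gamma, ix$tx)
    cnt <- numeric(M)
    cnt[as.integer(rownames(rs))] <- rs[, 1L]
    if (is.null(alpha)) {
      theta_new <- cnt / ix$N
    } else {
      map_cnt <- pmax(cnt + alpha - 1, 0)
      if (sum(map_cnt) == 0) map_cnt <- cnt  # all mass truncated: fall back
      theta_new <- map_cnt / sum(map_cnt)
    }
    done <- is.finite(ll_old) && (ll - ll_old) < tol * (abs(ll) + 1)
    theta <- theta_new
    if (done) break
    ll_old <- ll
  }
  list(theta = theta, count = cnt, ll_trace = ll_trace)
}

#' Maximum-likelihood abundance estimation (EM)
#'
#' Maximises `L(theta) = prod_r sum_{(i,p) in A_r} theta_i / eff_i` by
#' expectation-maximisation: responsibilities `gamma_ri` proportional to
#' `theta_i / eff_i`, update `theta_i = sum_r gamma_ri / N`.  The
#' log-likelihood is non-decreasing across iterations; convergence is
#' declared at a relative change below `tol`.
#'
#' @param compat A [compat_matrix()].
#' @param eff_lengths Effective lengths ([effective_lengths()] output or a
#'   named numeric vector) covering every aligned transcript; transcripts
#'   without alignments get zero abundance.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @return data.frame of class `abundance_estimate`: `transcript_id`,
#'   `expected_count`, `theta`, `tpm`, `estimator = "ML"`, with the
#'   log-likelihood trace in attribute `log_likelihood`.
#' @export
em_quantify <- function(compat, eff_lengths, tol = 1e-8, max_iter = 1e4) {
  eff <- .eff_vec(eff_lengths)
  ix <- .index_compat(compat, eff)
  inv_eff <- 1 / unname(eff)
  core <- .em_core(ix, inv_eff, alpha = NULL, tol = tol,
                   max_iter = max_iter)
  res <- data.frame(transcript_id = ix$tx_ids,
                    expected_count = core$count, theta = core$theta,
                    tpm = .tpm_from_theta(core$theta, unname(eff)),
                    estimator = "ML", stringsAsFactors = FALSE)
  attr(res, "log_likelihood") <- core$ll_trace
  class(res) <- c("abundance_estimate", class(res))
  res
}

#' Posterior-mean abundance estimation by collapsed Gibbs sampling
#'
#' Read assignments `z_r` are sampled from their full conditional
#' `P(z_r = (i,p) | z_-r) ~ (alpha_i + n_i^{-r}) / eff_i` over the read's
#' alignments.  After burn-in, the posterior-mean count of transcript i is
#' the average of `n_i` over the retained samples and the posterior-mean
#' fragment-generating probability is `(alpha_i + mean n_i) / (A + N)` with
#' `A = sum_i alpha_i`.  TPM is computed from the posterior-mean theta with
#' the same effective-length adjustment as the ML estimator.  Output is
#' reproducible bit-for-bit given `seed`.
#'
#' @param compat A [compat_matrix()].
#' @param eff_lengths Effective lengths covering every transcript.
#' @param prior A [prior_spec()] assigning a pseudocount to every
#'   transcript in the effective-length universe.
#' @param n_samples Posterior samples retained (>= 1).
#' @param burn_in Discarded initial sweeps (>= 0).
#' @param seed Optional integer seed.
#' @param init_em_iter Iteration cap for the posterior-mode EM used to form
#'   the initial assignment distribution: the chain starts from one draw of
#'   the read responsibilities at the MAP solution under the same prior
#'   (for a uniform pseudocount of 1 this is exactly the ML solution).
#' @return data.frame of class `abundance_estimate`: `transcript_id`,
#'   `expected_count` (posterior-mean count), `theta` (posterior mean),
#'   `tpm`, `estimator = "posterior_mean"`, `alpha`.
#' @export
gibbs_quantify <- function(compat, eff_lengths, prior, n_samples = 1000L,
                           burn_in = 500L, seed = NULL,
                           init_em_iter = 2000L) {
  eff <- .eff_vec(eff_lengths)
  alpha <- prior_alphas(prior, names(eff))
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (burn_in < 0L) stop("burn_in must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (compat$N == 0L) {
    # no data: the posterior is the prior, whose mean is alpha / sum(alpha)
    theta <- unname(alpha) / sum(alpha)
    res <- data.frame(transcript_id = names(eff),
                      expected_count = 0, theta = theta,
                      tpm = .tpm_from_theta(theta, unname(eff)),
                      estimator = "posterior_mean", alpha = unname(alpha),
                      stringsAsFactors = FALSE)
    class(res) <- c("abundance_estimate", class(res))
    return(res)
  }
  ix <- .index_compat(compat, eff)
  inv_eff <- 1 / unname(eff)

  core <- .em_core(ix, inv_eff, alpha = unname(alpha),
                   max_iter = init_em_iter)
  init_w <- core$theta[ix$tx] * inv_eff[ix$tx]
  # guard against reads whose every candidate has zero MAP weight
  den0 <- as.numeric(rowsum(init_w, ix$read))
  if (any(den0 == 0)) {
    flat <- inv_eff[ix$tx]
    zero <- den0[ix$read] == 0
    init_w[zero] <- flat[zero]
  }

  offsets <- c(0L, cumsum(tabulate(ix$read, ix$N)))
  draw <- .gibbs_sample(ix$tx - 1L, offsets, inv_eff, unname(alpha),
                        init_w, as.integer(burn_in),
                        as.integer(n_samples))
  mean_count <- draw$mean_count
  A <- sum(alpha)
  theta <- (unname(alpha) + mean_count) / (A + ix$N)
  res <- data.frame(transcript_id = ix$tx_ids,
                    expected_count = mean_count, theta = theta,
                    tpm = .tpm_from_theta(theta, unname(eff)),
                    estimator = "posterior_mean", alpha = unname(alpha),
                    stringsAsFactors = FALSE)
  class(res) <- c("abundance_estimate", class(res))
  res
}

#' Uniform-prior Gibbs variants
#'
#' [gibbs_quantify()] with the same pseudocount for every transcript:
#' pseudocount 1 reproduces the classic uninformative-prior posterior-mean
#' baseline; a small single-partition maximum-likelihood pseudocount gives
#' the "no partition" variant.
#'
#' @inheritParams gibbs_quantify
#' @param pseudocount Positive pseudocount shared by all transcripts.
#' @param ... Passed to [gibbs_quantify()].
#' @export
uniform_prior_variant <- function(compat, eff_lengths, pseudocount = 1,
                                  ...) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  eff <- .eff_vec(eff_lengths)
  prior <- prior_spec(pseudocount,
                      stats::setNames(rep(1L, length(eff)), names(eff)))
  gibbs_quantify(compat, eff, prior, ...)
}

#' Aggregate isoform estimates to gene level
#'
#' Gene expected counts and TPM are sums over member isoforms.
#'
#' @param estimates An `abundance_estimate` data.frame.
#' @param tx2gene Named character vector: gene id per transcript id.
#' @return data.frame `gene_id`, `expected_count`, `tpm`.
#' @export
aggregate_genes <- function(estimates, tx2gene) {
  g <- tx2gene[estimates$transcript_id]
  if (anyNA(g))
    stop("transcript(s) not mapped to a gene: ",
         paste(utils::head(
           estimates$transcript_id[is.na(g)], 3L), collapse = ", "))
  cnt <- rowsum(estimates$expected_count, g)
  tpm <- rowsum(estimates$tpm, g)
  res <- data.frame(gene_id = rownames(cnt), expected_count = cnt[, 1L],
                    tpm = tpm[, 1L], stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$gene_id), , drop = FALSE]
}

#' Expressed calls at a TPM cutoff
#'
#' A unit is called expressed when its TPM is at or above the cutoff
#' (inclusive).
#'
#' @param estimates An `abundance_estimate` / gene-level data.frame with a
#'   `tpm` column, or a named numeric vector of TPM.
#' @param cutoff_tpm Positive cutoff (default 1 TPM).
#' @return Named logical vector.
#' @export
call_expressed <- function(estimates, cutoff_tpm = 1) {
  if (cutoff_tpm <= 0) stop("cutoff_tpm must be positive")
  if (is.data.frame(estimates)) {
    id_col <- intersect(c("transcript_id", "gene_id", "unit_id"),
                        names(estimates))[1L]
    tpm <- stats::setNames(estimates$tpm, estimates[[id_col]])
  } else tpm <- estimates
  tpm >= cutoff_tpm
}

#' Write the quantification table
#'
#' Fixed columns: transcript_id, gene_id, length, effective_length,
#' expected_count, TPM, posterior_mean_count, posterior_mean_TPM,
#' partition_id, alpha.
#'
#' @param ml ML estimates from [em_quantify()].
#' @param posterior Posterior-mean estimates from [gibbs_quantify()].
#' @param ts A [transcript_set].
#' @param eff Effective lengths.
#' @param prior The [prior_spec()] used.
#' @param path Output TSV.
#' @export
write_quantification <- function(ml, posterior, ts, eff, prior, path) {
  effv <- .eff_vec(eff)
  ids <- ml$transcript_id
  tab <- data.frame(
    transcript_id = ids,
    gene_id = ts$tx$gene_id[match(ids, ts$tx$transcript_id)],
    length = ts$tx$length[match(ids, ts$tx$transcript_id)],
    effective_length = unname(effv[ids]),
    expected_count = ml$expected_count,
    TPM = ml$tpm,
    posterior_mean_count =
      posterior$expected_count[match(ids, posterior$transcript_id)],
    posterior_mean_TPM = posterior$tpm[match(ids, posterior$transcript_id)],
    partition_id = unname(prior$assignment[ids]),
    alpha = unname(prior$alpha[prior$assignment[ids]]),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}
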