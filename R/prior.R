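#' Training set of uniquely attributable isoforms
#'
#' @param unit_ids Character vector of transcript (or unit) ids.
#' @param counts Non-negative real fragment counts, one per unit.
#'   Fractional expected counts from a maximum-likelihood quantification are
#'   accepted as-is; all likelihood computations go through `lgamma`.
#' @param labels Integer partition labels in `1..G`; every label must occur.
#' @return An object of class `training_set`.
#' @export
training_set <- function(unit_ids, counts, labels) {
  if (length(unit_ids) != length(counts) ||
      length(counts) != length(labels))
    stop("unit_ids, counts and labels must have equal length")
  if (length(counts) == 0L)
    stop("empty training set; provide a larger input")
  if (any(counts < 0)) stop("counts must be non-negative")
  labels <- as.integer(labels)
  G <- max(labels)
  if (any(labels < 1L) || !all(seq_len(G) %in% labels))
    stop("labels must cover 1..G with every partition non-empty")
  structure(list(unit_ids = as.character(unit_ids),
                 counts = as.numeric(counts), labels = labels,
                 N = sum(counts), G = G),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("training_set:", length(x$counts), "units,", x$G,
      "partition(s), N =", format(x$N), "\n")
  invisible(x)
}

#' Dirichlet-multinomial log-likelihood of partitioned counts
#'
#' Each unit i carries the pseudocount `alpha[g(i)]` of its partition.  The
#' log-likelihood is
#' \deqn{\ln\Big[\frac{\Gamma(N+1)}{\prod_i\Gamma(n_i+1)}
#'   \frac{\Gamma(A)}{\Gamma(N+A)}
#'   \prod_i\frac{\Gamma(n_i+\alpha_{g(i)})}{\Gamma(\alpha_{g(i)})}\Big]}
#' with \eqn{A=\sum_i \alpha_{g(i)}}.  The multinomial coefficient is
#' constant in alpha but retained so that, for integer counts, the value is
#' a true log-probability.  Real-valued counts are handled directly through
#' `lgamma`.
#'
#' @param training A [training_set], or a numeric vector of counts.
#' @param alphas Positive pseudocounts, one per partition.
#' @param labels Partition labels when `training` is a plain vector.
#' @return Log-likelihood (scalar).
#' @export
dm_log_likelihood <- function(training, alphas, labels = NULL) {
  if (inherits(training, "training_set")) {
    counts <- training$counts
    labels <- training$labels
  } else {
    counts <- as.numeric(training)
    if (is.null(labels)) labels <- rep(1L, length(counts))
  }
  if (length(alphas) < max(labels))
    stop("need one alpha per partition")
  if (any(alphas <= 0)) stop("all alphas must be positive")
  a_i <- alphas[labels]
  N <- sum(counts)
  A <- sum(a_i)
  lgamma(N + 1) - sum(lgamma(counts + 1)) +
    lgamma(A) - lgamma(N + A) +
    sum(lgamma(counts + a_i) - lgamma(a_i))
}

#' Fit per-partition Dirichlet pseudocounts by maximum likelihood
#'
#' Maximises [dm_log_likelihood()] over `log(alpha)` with box constraints
#' `[alpha_min, alpha_max]` (L-BFGS-B, initialised at alpha = 1).  For
#' under/over-dispersed degenerate inputs the optimum sits on a bound and is
#' returned as such.
#'
#' @param training A [training_set].
#' @param alpha_min,alpha_max Bounds on each pseudocount.
#' @param tol Convergence tolerance on the log-likelihood.
#' @return List of class `prior_fit`: `alpha` (one per partition),
#'   `log_likelihood`, `n_units` per partition, `counts_total` per
#'   partition.
#' @export
fit_prior <- function(training, alpha_min = 1e-4, alpha_max = 1e4,
                      tol = 1e-6) {
  stopifnot(inherits(training, "training_set"))
  G <- training$G
  tab <- tabulate(training$labels, G)
  if (any(tab < 2L))
    warning("some partition has fewer than 2 training units")
  negll <- function(log_alpha)
    -dm_log_likelihood(training, exp(log_alpha))
  fit <- stats::optim(
    par = rep(0, G), fn = negll, method = "L-BFGS-B",
    lower = rep(log(alpha_min), G), upper = rep(log(alpha_max), G),
    control = list(factr = max(tol, 1e-10) / .Machine$double.eps,
                   maxit = 500L))
  if (fit$convergence != 0L && fit$convergence != 52L)
    stop("prior optimisation did not converge (code ", fit$convergence,
         "; last iterate alpha = ",
         paste(signif(exp(fit$par), 6), collapse = ", "), ")")
  alpha <- exp(fit$par)
  # a monotone likelihood can stall short of a bound; accept the bound when
  # it is at least as good
  for (g in seq_len(G)) {
    for (b in c(alpha_min, alpha_max)) {
      cand <- alpha
      cand[g] <- b
      if (dm_log_likelihood(training, cand) >= -fit$value) {
        alpha <- cand
        fit$value <- -dm_log_likelihood(training, cand)
      }
    }
  }
  structure(list(alpha = alpha,
                 log_likelihood = dm_log_likelihood(training, alpha),
                 n_units = tab,
                 counts_total = as.numeric(
                   rowsum(training$counts, training$labels)[, 1L]),
                 alpha_min = alpha_min, alpha_max = alpha_max),
            class = "prior_fit")
}

#' @export
print.prior_fit <- function(x, ...) {
  cat("prior_fit: alpha =", paste(signif(x$alpha, 4), collapse = ", "),
      " logLik =", format(x$log_likelihood), "\n")
  invisible(x)
}

#' Partition model specifications
#'
#' @param type One of `"two_partition_peak"` (default: with-peak
#'   vs. without-peak), `"signal_quantile"` (k groups by signal quantile),
#'   `"peak_plus_signal"` (no-peak, then with-peak split at the median
#'   signal), `"logistic_combined"` (logistic regression of an expressed
#'   flag on `log1p` signals of all marks, thresholded at probability 0.5),
#'   `"no_partition"`.
#' @param k Number of quantile groups for `"signal_quantile"`.
#' @export
partition_model <- function(type = c("two_partition_peak", "signal_quantile",
                                     "peak_plus_signal", "logistic_combined",
                                     "no_partition"), k = 2L) {
  type <- match.arg(type)
  if (type == "signal_quantile" && k < 2L)
    stop("signal_quantile needs k >= 2")
  structure(list(type = type, k = as.integer(k)), class = "partition_model")
}

#' Assign units to prior partitions
#'
#' @param features data.frame with `unit_id`, `has_peak` and one or more
#'   signal columns (any column whose name starts with `signal`).
#' @param model A [partition_model()].
#' @param response Logical expressed flags per unit, required for
#'   `"logistic_combined"` (typically TPM >= 1 from a maximum-likelihood
#'   quantification of the training units).
#' @return Named integer vector: partition label per `unit_id`.
#' @export
partition_units <- function(features, model = partition_model(),
                            response = NULL) {
  stopifnot(inherits(model, "partition_model"),
            "unit_id" %in% names(features))
  n <- nrow(features)
  sig_cols <- grep("^signal", names(features), value = TRUE)
  lab <- switch(model$type,
    no_partition = rep(1L, n),
    two_partition_peak = {
      stopifnot("has_peak" %in% names(features))
      ifelse(features$has_peak, 1L, 2L)
    },
    signal_quantile = {
      s <- features[[sig_cols[1L]]]
      br <- stats::quantile(s, probs = seq(0, 1, length.out = model$k + 1L))
      if (anyDuplicated(br))
        stop("signal has too few distinct values for ", model$k,
             " quantile groups")
      as.integer(cut(s, breaks = br, include.lowest = TRUE))
    },
    peak_plus_signal = {
      stopifnot("has_peak" %in% names(features))
      s <- features[[sig_cols[1L]]]
      lab <- integer(n)
      lab[!features$has_peak] <- 3L
      wp <- which(features$has_peak)
      if (length(wp) == 0L) stop("no with-peak units to split by signal")
      med <- stats::median(s[wp])
      if (all(s[wp] <= med) && all(s[wp] >= med) &&
          length(unique(s[wp])) == 1L)
        stop("with-peak signals are constant; no valid signal split")
      lab[wp] <- ifelse(s[wp] > med, 1L, 2L)
      lab
    },
    logistic_combined = {
      if (is.null(response))
        stop("logistic_combined requires training responses")
      x <- as.data.frame(lapply(features[sig_cols], log1p))
      dat <- cbind(y = as.numeric(response), x)
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = dat, family = stats::binomial()))
      p <- stats::predict(fit, type = "response")
      ifelse(p >= 0.5, 1L, 2L)
    })
  # compress to consecutive labels so every partition 1..G is populated
  lab <- match(lab, sort(unique(lab)))
  stats::setNames(as.integer(lab), features$unit_id)
}

#' Build the prior training set
#'
#' Training units are transcripts that can be attributed unambiguously to
#' their own ChIP-seq evidence: (a) their isoform TSS group's window
#' intersects no other group's window (unique peak assignment) and (b)
#' their gene's exonic span overlaps no other gene's span (unique ChIP read
#' assignment).  Fragment counts come from a maximum-likelihood
#' quantification; partition labels follow the chosen model applied to each
#' transcript's TSS-group features.
#'
#' @param ts A [transcript_set].
#' @param membership Output of [cluster_tss_groups()].
#' @param peaks Output of [read_peaks()].
#' @param quantified_counts Named numeric: expected count per transcript.
#' @param flank TSS window half-width in nt (default 500).
#' @param model A [partition_model()].
#' @param response Optional expressed flags (named by transcript) for
#'   `"logistic_combined"`.
#' @return A [training_set] with attributes `features` (the TSS-group
#'   feature table) and `group_of` (transcript to group map).
#' @export
build_training_set <- function(ts, membership, peaks, quantified_counts,
                               flank = 500, model = partition_model(),
                               response = NULL) {
  stopifnot(inherits(ts, "transcript_set"))
  groups <- tss_group_table(membership)
  feats <- tss_peak_status(groups, peaks, flank = flank)

  # (a) unique peak assignment: group window disjoint from all other windows
  wgr <- GenomicRanges::GRanges(feats$chrom,
           IRanges::IRanges(start = feats$window_start + 1L,
                            end = feats$window_end))
  self_hits <- GenomicRanges::countOverlaps(wgr, wgr)
  group_ok <- stats::setNames(self_hits == 1L, feats$unit_id)

  # (b) unique read assignment: gene exonic span overlaps no other gene
  tx <- ts$tx
  gene_span <- do.call(rbind, lapply(split(tx, tx$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1L], chrom = d$chrom[1L],
               start = min(d$span_start), end = max(d$span_end),
               stringsAsFactors = FALSE)))
  ggr <- GenomicRanges::GRanges(gene_span$chrom,
           IRanges::IRanges(start = gene_span$start + 1L,
                            end = gene_span$end))
  gene_ok <- stats::setNames(
    GenomicRanges::countOverlaps(ggr, ggr) == 1L, gene_span$gene_id)

  keep <- group_ok[membership$group_id] & gene_ok[membership$gene_id]
  units <- membership$transcript_id[keep]
  if (length(units) == 0L)
    stop("empty training set: no transcript has uniquely assignable ",
         "peaks and reads; provide a larger or less overlapping input")
  missing_counts <- setdiff(units, names(quantified_counts))
  if (length(missing_counts) > 0L)
    stop("no quantified count for training unit(s): ",
         paste(utils::head(missing_counts, 3L), collapse = ", "))

  group_of <- stats::setNames(membership$group_id, membership$transcript_id)
  unit_feats <- feats[match(group_of[units], feats$unit_id), , drop = FALSE]
  unit_feats$unit_id <- units
  labels <- partition_units(unit_feats, model,
                            response = if (is.null(response)) NULL
                                       else response[units])
  tr <- training_set(units, quantified_counts[units], labels[units])
  attr(tr, "features") <- feats
  attr(tr, "group_of") <- group_of
  tr
}

#' Full prior specification over quantified isoforms
#'
#' Combines fitted per-partition pseudocounts with a partition assignment
#' covering every isoform to be quantified.
#'
#' @param alpha Numeric vector, one pseudocount per partition.
#' @param assignment Named integer vector: partition label per unit id.
#' @param model Optional description of the partition model used.
#' @export
prior_spec <- function(alpha, assignment, model = NULL) {
  if (any(alpha <= 0)) stop("all alphas must be positive")
  assignment <- stats::setNames(as.integer(assignment), names(assignment))
  if (any(is.na(assignment)) || any(assignment < 1L) ||
      any(assignment > length(alpha)))
    stop("assignment labels must index into alpha")
  structure(list(alpha = as.numeric(alpha), assignment = assignment,
                 model = model), class = "prior_spec")
}

#' Per-transcript pseudocounts from a prior specification
#'
#' @param prior A [prior_spec()].
#' @param transcript_ids Units that need a pseudocount.
#' @return Named numeric vector of alphas.
#' @export
prior_alphas <- function(prior, transcript_ids) {
  stopifnot(inherits(prior, "prior_spec"))
  miss <- setdiff(transcript_ids, names(prior$assignment))
  if (length(miss) > 0L)
    stop("no prior pseudocount for transcript(s): ",
         paste(utils::head(miss, 3L), collapse = ", "))
  stats::setNames(prior$alpha[prior$assignment[transcript_ids]],
                  transcript_ids)
}

#' Compare candidate prior sources by training-set log-likelihood
#'
#' Each candidate is a partition labelling of the same training counts; for
#' each one the Dirichlet-multinomial model is fitted and the maximised
#' log-likelihood reported.  Larger is better; ties break lexicographically
#' by source name.
#'
#' @param counts Numeric training counts.
#' @param candidates Named list of integer label vectors.
#' @param ... Passed to [fit_prior()].
#' @return data.frame `source`, `log_likelihood`, ranked descending, with
#'   the fits in attribute `fits`.
#' @export
compare_prior_sources <- function(counts, candidates, ...) {
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    stop("candidates must be a named list")
  fits <- lapply(names(candidates), function(nm)
    fit_prior(training_set(paste0("u", seq_along(counts)), counts,
                           candidates[[nm]]), ...))
  names(fits) <- names(candidates)
  ll <- vapply(fits, `[[`, numeric(1L), "log_likelihood")
  ord <- order(-ll, names(candidates))
  res <- data.frame(source = names(candidates)[ord],
                    log_likelihood = unname(ll[ord]),
                    stringsAsFactors = FALSE)
  attr(res, "fits") <- fits[ord]
  res
}

#' Permutation test for informativeness of a partition labelling
#'
#' Test statistic: maximised log-likelihood of the two-partition model
#' minus that of the single-partition model (always >= 0 by nesting).  The
#' null distribution is obtained by refitting on permuted labels; the
#' p-value uses the add-one convention.
#'
#' @param counts Numeric training counts.
#' @param labels Two-level partition labels.
#' @param n_permutations Number of label permutations (>= 99).
#' @param seed Optional integer seed for the permutations.
#' @return List: `p_value`, `statistic`, `null_statistics`.
#' @export
informativeness_test <- function(counts, labels, n_permutations = 999L,
                                 seed = NULL) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) != 2L)
    stop("labels must define exactly two non-constant partitions")
  if (n_permutations < 99L) stop("use at least 99 permutations")
  if (!is.null(seed)) set.seed(seed)
  ids <- paste0("u", seq_along(counts))
  ll2 <- fit_prior(training_set(ids, counts, labels))$log_likelihood
  ll1 <- fit_prior(training_set(ids, counts,
                                rep(1L, length(counts))))$log_likelihood
  stat <- ll2 - ll1
  null_stats <- vapply(seq_len(n_permutations), function(b) {
    perm <- sample(labels)
    fit_prior(training_set(ids, counts, perm))$log_likelihood - ll1
  }, numeric(1L))
  p <- (1 + sum(null_stats >= stat)) / (n_permutations + 1)
  list(p_value = p, statistic = stat, null_statistics = null_stats)
}

#' Write / read a prior file
#'
#' One TSV with two sections: the partition table (`partition_id`, `alpha`,
#' `n_training_units`) followed by a blank line and the unit assignment
#' table (`unit_id`, `partition_id`).
#'
#' @param prior A [prior_spec()] (optionally carrying `n_units` from the
#'   fit in its `model` field).
#' @param path Output file.
#' @param n_training_units Optional integer per partition.
#' @export
write_prior <- function(prior, path, n_training_units = NA_integer_) {
  stopifnot(inherits(prior, "prior_spec"))
  part <- data.frame(partition_id = seq_along(prior$alpha),
                     alpha = prior$alpha,
                     n_training_units = n_training_units)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(part, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("", con)
  assign_tab <- data.frame(unit_id = names(prior$assignment),
                           partition_id = unname(prior$assignment))
  utils::write.table(assign_tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  lines <- readLines(path)
  blank <- which(lines == "")[1L]
  if (is.na(blank)) stop("malformed prior file: ", path)
  part <- utils::read.table(text = lines[seq_len(blank - 1L)], sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  assign_tab <- utils::read.table(text = lines[-seq_len(blank)], sep = "\t",
                                  header = TRUE, stringsAsFactors = FALSE)
  prior_spec(part$alpha[order(part$partition_id)],
             stats::setNames(assign_tab$partition_id, assign_tab$unit_id))
}
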