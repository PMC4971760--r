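#' Draw fragment-generating probabilities from a partitioned Dirichlet
#'
#' Each isoform's fragment-generating probability theta is drawn from a
#' Dirichlet distribution whose per-isoform pseudocounts come from the
#' prior specification (e.g. one value for with-peak, one for no-peak
#' isoforms).  True TPM follows from theta and the effective lengths.
#'
#' @param prior A [prior_spec()] covering every transcript.
#' @param eff_lengths Effective lengths (named vector or
#'   [effective_lengths()] output).
#' @param seed Optional integer seed.
#' @return Object of class `simulation_truth`: `theta`, `true_tpm` (both
#'   named), `alpha`.
#' @export
draw_theta <- function(prior, eff_lengths, seed = NULL) {
  eff <- .eff_vec(eff_lengths)
  alpha <- prior_alphas(prior, names(eff))
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # all-underflow guard
  theta <- g / sum(g)
  structure(list(theta = stats::setNames(theta, names(eff)),
                 true_tpm = stats::setNames(
                   .tpm_from_theta(theta, unname(eff)), names(eff)),
                 alpha = alpha),
            class = "simulation_truth")
}

# Precompute, for every (origin transcript, fragment start) pair, the full
# structural alignment set.  Same-gene targets come from exon-chain
# containment of the fragment's genomic footprint; cross-locus targets from
# user-declared homology groups (mutually alignable transcripts, aligned at
# equal offsets).  Returns a data.table keyed by (otx, s).
.build_compat_map <- function(ts, fragment_length, homology_groups = NULL) {
  L <- as.integer(fragment_length)
  tx <- ts$tx
  homo_of <- list()
  if (!is.null(homology_groups)) {
    for (grp in homology_groups)
      for (id in grp) homo_of[[id]] <- setdiff(grp, id)
  }
  rows <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    n_start <- tx$length[i] - L + 1L
    if (n_start < 1L) next
    sibs <- tx$transcript_id[tx$gene_id == tx$gene_id[i] &
                             tx$transcript_id != id &
                             tx$chrom == tx$chrom[i] &
                             tx$strand == tx$strand[i]]
    starts <- 0:(n_start - 1L)
    tgt_tx <- rep(id, n_start)
    tgt_pos <- starts
    res_s <- starts
    for (j in sibs) {
      ex_j <- ts$exons[[j]]
      offs <- vapply(starts, function(s)
        .footprint_offset(.footprint(ts$exons[[id]], s, L), ex_j),
        numeric(1L))
      hit <- which(!is.na(offs))
      tgt_tx <- c(tgt_tx, rep(j, length(hit)))
      tgt_pos <- c(tgt_pos, as.integer(offs[hit]))
      res_s <- c(res_s, starts[hit])
    }
    for (j in homo_of[[id]]) {
      lj <- tx$length[tx$transcript_id == j]
      if (length(lj) == 0L) next
      ok <- which(starts + L <= lj)
      tgt_tx <- c(tgt_tx, rep(j, length(ok)))
      tgt_pos <- c(tgt_pos, starts[ok])
      res_s <- c(res_s, starts[ok])
    }
    rows[[i]] <- data.table::data.table(otx = id, s = res_s,
                                        ttx = tgt_tx, tpos = tgt_pos)
  }
  map <- data.table::rbindlist(rows)
  data.table::setkeyv(map, c("otx", "s"))
  map
}

#' Generate structurally multimapping fragments
#'
#' Each fragment is a noise read with probability `noise_fraction`
#' (unaligned, counted in the library depth but absent from the
#' compatibility matrix); otherwise its origin transcript is drawn from
#' `truth$theta` and its start uniformly over the transcript's valid start
#' positions.  The alignment set of a fragment is every transcript whose
#' exon chain contains the fragment's genomic footprint as a contiguous
#' sub-path (same gene) plus any declared homologs (cross-locus).  Start
#' positions are reported as offsets in genomic orientation.
#'
#' @param truth A [draw_theta()] result, or a named theta vector.
#' @param ts A [transcript_set].
#' @param fragment_length Fixed fragment length in nt.
#' @param n_fragments Total fragments to generate (>= 1).
#' @param noise_fraction Probability of an unaligned noise fragment
#'   (default 0.05).
#' @param homology_groups Optional list of character vectors of mutually
#'   alignable transcript ids (cross-locus multimapping).
#' @param seed Optional integer seed.
#' @param compat_map Optional precomputed map from a previous call (via
#'   attribute `compat_map` of a result) to skip the structural
#'   enumeration.
#' @return List of class `sim_fragments`: `compat` (a [compat_matrix()]
#'   with `depth = n_fragments`), `origins` (data.frame `read_id`,
#'   `transcript_id`, `pos`; noise reads have `NA`), and the map in
#'   attribute `compat_map`.
#' @export
generate_fragments <- function(truth, ts, fragment_length, n_fragments,
                               noise_fraction = 0.05,
                               homology_groups = NULL, seed = NULL,
                               compat_map = NULL) {
  theta <- if (inherits(truth, "simulation_truth")) truth$theta else truth
  stopifnot(inherits(ts, "transcript_set"))
  if (n_fragments < 1L) stop("n_fragments must be >= 1")
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop("noise_fraction must be in [0, 1)")
  L <- as.integer(fragment_length)
  tx <- ts$tx
  n_start <- stats::setNames(pmax(tx$length - L + 1L, 0L),
                             tx$transcript_id)
  if (all(n_start == 0L))
    stop("fragment length ", L, " exceeds every transcript length")
  active <- names(theta)[theta > 0]
  if (any(n_start[active] == 0L))
    stop("transcript(s) with positive theta are shorter than the fragment ",
         "length: ", paste(utils::head(
           active[n_start[active] == 0L], 3L), collapse = ", "))
  if (is.null(compat_map))
    compat_map <- .build_compat_map(ts, L, homology_groups)
  if (!is.null(seed)) set.seed(seed)

  is_noise <- stats::runif(n_fragments) < noise_fraction
  n_real <- sum(!is_noise)
  read_id <- sprintf("frag%07d", seq_len(n_fragments))
  origins <- data.frame(read_id = read_id,
                        transcript_id = NA_character_, pos = NA_integer_,
                        stringsAsFactors = FALSE)
  compat <- NULL
  if (n_real > 0L) {
    otx <- sample(names(theta), n_real, replace = TRUE, prob = theta)
    s <- floor(stats::runif(n_real) * n_start[otx])
    origins$transcript_id[!is_noise] <- otx
    origins$pos[!is_noise] <- as.integer(s)
    frag <- data.table::data.table(read_id = read_id[!is_noise],
                                   otx = otx, s = as.integer(s))
    aln <- compat_map[frag, on = c("otx", "s"), allow.cartesian = TRUE]
    compat <- compat_matrix(
      data.frame(read_id = aln$read_id, transcript_id = aln$ttx,
                 pos = aln$tpos, stringsAsFactors = FALSE),
      depth = n_fragments)
  } else {
    compat <- structure(list(
      aln = data.frame(read = integer(), transcript_id = character(),
                       pos = integer(), stringsAsFactors = FALSE),
      read_ids = character(), N = 0L, depth = n_fragments),
      class = "compat_matrix")
  }
  res <- structure(list(compat = compat, origins = origins,
                        fragment_length = L,
                        noise_fraction = noise_fraction),
                   class = "sim_fragments")
  attr(res, "compat_map") <- compat_map
  res
}

#' Write simulated fragments as a minimal SAM file plus a truth TSV
#'
#' @param frags A [generate_fragments()] result.
#' @param truth The [draw_theta()] truth used to generate them.
#' @param ts The [transcript_set].
#' @param sam_path,truth_path Output files.
#' @export
write_fragments <- function(frags, truth, ts, sam_path, truth_path) {
  stopifnot(inherits(frags, "sim_fragments"))
  con <- file(sam_path, "w")
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ts$tx$transcript_id,
                     ts$tx$length), con)
  aln <- frags$compat$aln
  if (nrow(aln) > 0L)
    writeLines(sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                       frags$compat$read_ids[aln$read], aln$transcript_id,
                       aln$pos + 1L, frags$fragment_length), con)
  noise <- frags$origins$read_id[is.na(frags$origins$transcript_id)]
  if (length(noise) > 0L)
    writeLines(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", noise), con)
  close(con)

  origin_count <- table(frags$origins$transcript_id)
  tab <- data.frame(transcript_id = names(truth$theta),
                    theta = unname(truth$theta),
                    true_tpm = unname(truth$true_tpm),
                    origin_count = as.integer(
                      ifelse(is.na(match(names(truth$theta),
                                         names(origin_count))), 0L,
                             origin_count[names(truth$theta)])),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(sam = sam_path, truth = truth_path))
}

#' Subsample reads without replacement
#'
#' Draws `floor(fraction * N)` aligned reads; alignment sets are preserved
#' and the recorded library depth is scaled by the same fraction.
#'
#' @param compat A [compat_matrix()].
#' @param fraction Fraction in (0, 1].
#' @param seed Optional integer seed.
#' @export
subsample_reads <- function(compat, fraction, seed = NULL) {
  stopifnot(inherits(compat, "compat_matrix"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_keep <- floor(fraction * compat$N)
  if (n_keep < 1L) stop("subsample would contain no reads")
  keep <- sort(sample.int(compat$N, n_keep))
  aln <- compat$aln[compat$aln$read %in% keep, , drop = FALSE]
  compat_matrix(
    data.frame(read_id = compat$read_ids[aln$read],
               transcript_id = aln$transcript_id, pos = aln$pos,
               stringsAsFactors = FALSE),
    depth = floor(fraction * compat$depth))
}

#' False-positive and false-negative rates of expressed calls
#'
#' A false positive is a unit with true abundance below the cutoff but
#' estimated at or above it; a false negative is a unit with true abundance
#' at or above the cutoff but estimated below it.  FPR is the percentage of
#' truly unexpressed units called expressed, FNR the percentage of truly
#' expressed units called unexpressed; an empty denominator yields 0.
#'
#' @param true_tpm,est_tpm Named numeric vectors over the same units.
#' @param cutoff Expressed cutoff in TPM (default 1).
#' @return List of class `classification_result`: `fpr`, `fnr`
#'   (percentages), `n_fp`, `n_fn`, `n_true_expressed`,
#'   `n_true_unexpressed`, `cutoff_tpm`.
#' @export
classify_fpr_fnr <- function(true_tpm, est_tpm, cutoff = 1) {
  if (is.null(names(true_tpm)) || is.null(names(est_tpm)) ||
      !setequal(names(true_tpm), names(est_tpm)))
    stop("true and estimated TPM must cover the same named units")
  est_tpm <- est_tpm[names(true_tpm)]
  true_exp <- true_tpm >= cutoff
  est_exp <- est_tpm >= cutoff
  n_fp <- sum(!true_exp & est_exp)
  n_fn <- sum(true_exp & !est_exp)
  n_unexp <- sum(!true_exp)
  n_exp <- sum(true_exp)
  structure(list(
    fpr = if (n_unexp == 0L) 0 else 100 * n_fp / n_unexp,
    fnr = if (n_exp == 0L) 0 else 100 * n_fn / n_exp,
    n_fp = n_fp, n_fn = n_fn, n_true_expressed = n_exp,
    n_true_unexpressed = n_unexp, cutoff_tpm = cutoff),
    class = "classification_result")
}

#' Log2 fold change with optional pseudocount
#'
#' @param est_a,est_b Abundances (scalars or vectors).
#' @param pseudocount_tpm Added to both before the ratio (default 0).
#' @export
fold_change <- function(est_a, est_b, pseudocount_tpm = 0) {
  if (any(est_b + pseudocount_tpm <= 0))
    stop("denominator is zero; supply a positive pseudocount_tpm")
  log2((est_a + pseudocount_tpm) / (est_b + pseudocount_tpm))
}

#' Benchmark estimators by FPR/FNR on simulated data
#'
#' For each replicate: draw theta from the truth prior, generate
#' structurally multimapping fragments, quantify with every estimator
#' configuration, and classify expressed calls against the simulation
#' truth at both isoform and gene level.  Fully seeded end to end.
#'
#' @param ts A [transcript_set].
#' @param truth_prior [prior_spec()] the simulation draws theta from.
#' @param configs Named list of estimator configurations: each a list with
#'   `type` one of `"gibbs"` (field `prior`), `"uniform"` (field
#'   `pseudocount`), `"ml"`.
#' @param n_replicates Number of simulation replicates.
#' @param fragment_length,n_fragments,noise_fraction Simulation settings.
#' @param homology_groups Optional cross-locus homology groups.
#' @param cutoff Expressed cutoff in TPM.
#' @param n_samples,burn_in Gibbs settings used for all sampling
#'   estimators.
#' @param seed Base integer seed; replicate r uses `seed + r`.
#' @return Tidy data.frame: `replicate`, `estimator`, `level`, `cutoff`,
#'   `fpr`, `fnr`, `n_fp`, `n_fn`.
#' @export
benchmark_estimators <- function(ts, truth_prior, configs,
                                 n_replicates = 50L, fragment_length = 100L,
                                 n_fragments = 5e4, noise_fraction = 0.05,
                                 homology_groups = NULL, cutoff = 1,
                                 n_samples = 250L, burn_in = 150L,
                                 seed = 1L) {
  stopifnot(length(names(configs)) == length(configs))
  eff <- effective_lengths(ts, frag_length_fixed(fragment_length))
  effv <- .eff_vec(eff)
  tx2gene <- stats::setNames(ts$tx$gene_id, ts$tx$transcript_id)
  compat_map <- .build_compat_map(ts, fragment_length, homology_groups)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    truth <- draw_theta(truth_prior, effv, seed = seed + r)
    frags <- generate_fragments(truth, ts, fragment_length, n_fragments,
                                noise_fraction = noise_fraction,
                                homology_groups = homology_groups,
                                seed = seed + r,
                                compat_map = compat_map)
    true_gene <- stats::setNames(
      rowsum(unname(truth$true_tpm), tx2gene[names(truth$true_tpm)])[, 1L],
      sort(unique(unname(tx2gene))))
    for (nm in names(configs)) {
      cfg <- configs[[nm]]
      est <- switch(cfg$type,
        ml = em_quantify(frags$compat, effv),
        gibbs = gibbs_quantify(frags$compat, effv, cfg$prior,
                               n_samples = n_samples, burn_in = burn_in,
                               seed = seed + r),
        uniform = uniform_prior_variant(frags$compat, effv,
                                        pseudocount = cfg$pseudocount,
                                        n_samples = n_samples,
                                        burn_in = burn_in, seed = seed + r),
        stop("unknown estimator type: ", cfg$type))
      est_tpm <- stats::setNames(est$tpm, est$transcript_id)
      gene_est <- aggregate_genes(est, tx2gene)
      est_gene <- stats::setNames(gene_est$tpm, gene_est$gene_id)
      for (lv in c("isoform", "gene")) {
        cl <- if (lv == "isoform")
          classify_fpr_fnr(truth$true_tpm, est_tpm, cutoff)
        else classify_fpr_fnr(true_gene, est_gene, cutoff)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, estimator = nm, level = lv, cutoff = cutoff,
          fpr = cl$fpr, fnr = cl$fnr, n_fp = cl$n_fp, n_fn = cl$n_fn,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
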