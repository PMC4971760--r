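#' Synthetic benchmark annotation: peak-linked two-isoform genes
#'
#' Every gene has a with-peak isoform (two exons, TSS at the gene start)
#' and a no-peak isoform whose single exon is the with-peak isoform's 3'
#' exon, so every fragment of the no-peak isoform also aligns to its
#' sibling (it is structurally indistinguishable) while the sibling keeps
#' unique 5'-exon and junction fragments.  The two TSSs are 1 kb apart and
#' therefore fall in different isoform TSS groups.
#'
#' In addition to the two-isoform genes, a panel of short single-isoform
#' "context" genes (all with peaks) fills out the transcriptome; their
#' short effective lengths set a realistic per-million TPM scale so that
#' pseudocount floors of the estimators straddle the usual 1-TPM expressed
#' cutoff.
#'
#' @param n_genes Number of two-isoform genes.
#' @param n_context Number of short single-isoform context genes.
#' @param context_length Context gene length in nt.
#' @param chrom Chromosome name.
#' @return List: `ts` (a [transcript_set]), `peaks` (peak table for the
#'   with-peak TSSs), `assignment` (partition label per transcript: 1 =
#'   with peak, 2 = no peak).
#' @export
sim_annotation <- function(n_genes = 25L, n_context = 50L,
                           context_length = 150L, chrom = "chrS") {
  rows <- list()
  peak_rows <- list()
  add_peak <- function(tss) {
    peak_rows[[length(peak_rows) + 1L]] <<- data.frame(
      chrom = chrom, start = max(tss - 50L, 0L), end = tss + 50L,
      signal = 10, stringsAsFactors = FALSE)
  }
  for (g in seq_len(n_genes)) {
    off <- (g - 1L) * 10000L
    gid <- sprintf("gene%03d", g)
    a <- sprintf("%s.A", gid)
    b <- sprintf("%s.B", gid)
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = c(a, a, b), gene_id = gid, chrom = chrom,
      strand = "+",
      start = off + c(0L, 1000L, 1000L),
      end = off + c(400L, 1800L, 1800L), stringsAsFactors = FALSE)
    add_peak(off)
  }
  for (k in seq_len(n_context)) {
    off <- n_genes * 10000L + (k - 1L) * 5000L
    gid <- sprintf("ctx%03d", k)
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = paste0(gid, ".A"), gene_id = gid, chrom = chrom,
      strand = "+", start = off, end = off + as.integer(context_length),
      stringsAsFactors = FALSE)
    add_peak(off)
  }
  ts <- transcript_set(do.call(rbind, rows))
  assignment <- stats::setNames(
    ifelse(grepl("\\.A$", ts$tx$transcript_id), 1L, 2L),
    ts$tx$transcript_id)
  list(ts = ts, peaks = do.call(rbind, peak_rows),
       assignment = assignment)
}

#' Generate the full synthetic fixture bundle on disk
#'
#' Builds a small synthetic genome exercising every structure the workflow
#' must handle — a gene with a structurally indistinguishable isoform, a
#' gene with "mixed" TSS-peak status, an overlapping gene pair (excluded
#' from prior training), a cross-chromosome homology group, and a panel of
#' clean single-isoform training genes with peak-correlated expression —
#' then simulates fragments from a partitioned Dirichlet truth and writes
#' GTF, narrowPeak, SAM, truth and homology files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving theta and fragment generation.
#' @param scale Multiplies the number of training genes.
#' @param n_fragments Fragments to simulate.
#' @param fragment_length Fragment length in nt.
#' @param alpha Pseudocounts (with-peak, no-peak) of the simulation truth.
#' @return Named list of file paths plus the in-memory `ts`, `truth` and
#'   `homology_groups`.
#' @export
make_fixtures <- function(dir, seed = 1L, scale = 1L, n_fragments = 20000L,
                          fragment_length = 100L, alpha = c(0.60, 0.04)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  peaks <- list()
  add_tx <- function(tid, gid, chrom, strand, starts, ends) {
    rows[[length(rows) + 1L]] <<- data.frame(
      transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
      start = as.integer(starts), end = as.integer(ends),
      stringsAsFactors = FALSE)
  }
  add_peak <- function(chrom, tss, signal) {
    peaks[[length(peaks) + 1L]] <<- data.frame(
      chrom = chrom, start = as.integer(max(tss - 100L, 0L)),
      end = as.integer(tss + 100L), signal = signal,
      stringsAsFactors = FALSE)
  }

  # geneA: indistinguishable isoform A2 inside A1's 3' exon; mixed status
  add_tx("A1", "geneA", "chrF", "+", c(100L, 1000L), c(400L, 1700L))
  add_tx("A2", "geneA", "chrF", "+", 1000L, 1700L)
  add_peak("chrF", 100L, 12)
  # geneB: second mixed-status gene, same shape
  add_tx("B1", "geneB", "chrF", "+", c(20000L, 21000L), c(20400L, 21800L))
  add_tx("B2", "geneB", "chrF", "+", 21000L, 21800L)
  add_peak("chrF", 20000L, 9)
  # overlapping gene pair (training-ineligible)
  add_tx("C1", "geneC", "chrF", "+", 40000L, 41000L)
  add_tx("D1", "geneD", "chrF", "+", 40500L, 41500L)
  add_peak("chrF", 40000L, 7)
  # homology group across chromosomes
  add_tx("E1", "geneE", "chrF", "+", 60000L, 61000L)
  add_tx("F1", "geneF", "chrG", "+", 5000L, 6000L)
  add_peak("chrF", 60000L, 8)
  homology_groups <- list(c("E1", "F1"))
  # clean single-isoform training genes, half with a peak, one on "-"
  n_train <- 8L * scale
  for (k in seq_len(n_train)) {
    gid <- sprintf("geneT%02d", k)
    tid <- sprintf("T%02d", k)
    off <- 100000L + (k - 1L) * 10000L
    strand <- if (k == n_train) "-" else "+"
    add_tx(tid, gid, "chrF", strand, off, off + 1200L)
    if (k %% 2L == 1L)
      add_peak("chrF", if (strand == "+") off else off + 1199L, 5 + k)
  }
  ts <- transcript_set(do.call(rbind, rows))
  peak_tab <- do.call(rbind, peaks)

  # truth prior: partition by designed peak status of each isoform's group
  membership <- cluster_tss_groups(ts)
  feats <- tss_peak_status(tss_group_table(membership),
                           structure(peak_tab, class = "data.frame"))
  group_of <- stats::setNames(membership$group_id,
                              membership$transcript_id)
  has_peak <- stats::setNames(feats$has_peak, feats$unit_id)
  assignment <- stats::setNames(
    ifelse(has_peak[group_of[ts$tx$transcript_id]], 1L, 2L),
    ts$tx$transcript_id)
  truth_prior <- prior_spec(alpha, assignment)

  eff <- effective_lengths(ts, frag_length_fixed(fragment_length))
  truth <- draw_theta(truth_prior, eff, seed = seed)
  frags <- generate_fragments(truth, ts, fragment_length, n_fragments,
                              noise_fraction = 0.05,
                              homology_groups = homology_groups,
                              seed = seed)

  paths <- list(gtf = file.path(dir, "annotation.gtf"),
                peaks = file.path(dir, "peaks.narrowPeak"),
                sam = file.path(dir, "alignments.sam"),
                truth = file.path(dir, "truth.tsv"),
                homology = file.path(dir, "homology_groups.tsv"))
  write_gtf(ts, paths$gtf)
  write_narrowpeak(peak_tab, paths$peaks)
  write_fragments(frags, truth, ts, paths$sam, paths$truth)
  utils::write.table(
    data.frame(group = rep(seq_along(homology_groups),
                           lengths(homology_groups)),
               transcript_id = unlist(homology_groups)),
    paths$homology, sep = "\t", quote = FALSE, row.names = FALSE)
  c(paths, list(ts = ts, truth = truth, truth_prior = truth_prior,
                homology_groups = homology_groups))
}

#' Write a transcript set as GENCODE-style GTF
#'
#' @param ts A [transcript_set].
#' @param path Output file.
#' @export
write_gtf <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##description: synthetic annotation", con)
  for (i in seq_len(nrow(ts$tx))) {
    id <- ts$tx$transcript_id[i]
    ex <- ts$exons[[id]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     ts$tx$gene_id[i], id)
    writeLines(sprintf("%s\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       ts$tx$chrom[i], ex[1L, "start"] + 1L,
                       ex[nrow(ex), "end"], ts$tx$strand[i], attrs), con)
    writeLines(sprintf("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s",
                       ts$tx$chrom[i], ex[, "start"] + 1L, ex[, "end"],
                       ts$tx$strand[i], attrs), con)
  }
  invisible(path)
}

#' Write peaks in narrowPeak format
#'
#' @param peaks data.frame `chrom`, `start`, `end`, `signal`.
#' @param path Output file.
#' @export
write_narrowpeak <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\tpeak%d\t0\t.\t%g\t-1\t-1\t-1",
                   peaks$chrom, peaks$start, peaks$end,
                   seq_len(nrow(peaks)), peaks$signal)
  writeLines(lines, path)
  invisible(path)
}
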