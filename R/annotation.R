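#' Transcript models from exon structure
#'
#' A `transcript_set` holds one record per transcript: its gene, chromosome,
#' strand, spliced length and strand-aware transcription start site (TSS),
#' together with the underlying exon intervals.  All coordinates are 0-based
#' half-open genomic intervals; GTF input (1-based, closed) is converted on
#' read.  The TSS is the 5'-most transcribed base: the start of the first
#' exon on the plus strand, `end - 1` of the last exon on the minus strand.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), one row per exon.
#' @return An object of class `transcript_set`: a list with `tx` (per
#'   transcript summary data.frame ordered by chrom, span start, id) and
#'   `exons` (named list of 2-column matrices `start`,`end`, sorted,
#'   disjoint).
#' @export
transcript_set <- function(exons) {
  required <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0L)
    stop("exon table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(exons) == 0L)
    stop("exon table is empty; a transcript needs at least one exon")
  if (!all(exons$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(exons$end <= exons$start))
    stop("exon with end <= start (0-based half-open intervals required)")

  ids <- unique(exons$transcript_id)
  exon_list <- vector("list", length(ids))
  names(exon_list) <- ids
  tx_rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    e <- exons[exons$transcript_id == id, , drop = FALSE]
    if (length(unique(e$gene_id)) != 1L || length(unique(e$chrom)) != 1L ||
        length(unique(e$strand)) != 1L)
      stop("transcript ", id, " has inconsistent gene/chrom/strand")
    ord <- order(e$start)
    m <- cbind(start = e$start[ord], end = e$end[ord])
    if (nrow(m) > 1L && any(m[-1L, "start"] < m[-nrow(m), "end"]))
      stop("transcript ", id, " has overlapping exons")
    exon_list[[k]] <- m
    strand <- e$strand[1L]
    tss <- if (strand == "+") m[1L, "start"] else m[nrow(m), "end"] - 1L
    tx_rows[[k]] <- data.frame(
      transcript_id = id, gene_id = e$gene_id[1L], chrom = e$chrom[1L],
      strand = strand, tss = as.integer(tss),
      length = as.integer(sum(m[, "end"] - m[, "start"])),
      span_start = as.integer(m[1L, "start"]),
      span_end = as.integer(m[nrow(m), "end"]),
      stringsAsFactors = FALSE)
  }
  tx <- do.call(rbind, tx_rows)
  ord <- order(tx$chrom, tx$span_start, tx$transcript_id)
  tx <- tx[ord, , drop = FALSE]
  rownames(tx) <- NULL
  structure(list(tx = tx, exons = exon_list[tx$transcript_id]),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$tx), "transcripts,",
      length(unique(x$tx$gene_id)), "genes\n")
  invisible(x)
}

#' Parse a GENCODE-style GTF annotation
#'
#' Reads exon features and assembles one transcript model per
#' `transcript_id`.  Exon lines may appear in any order; they are sorted and
#' validated per transcript.  GTF 1-based closed coordinates are converted
#' to 0-based half-open.
#'
#' @param path Path to a GTF file carrying `gene_id` and `transcript_id`
#'   attributes on its exon features.
#' @return A [transcript_set].
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  gene_id <- if (is.null(gr$gene_id)) rep(NA_character_, length(gr))
             else as.character(gr$gene_id)
  tx_id <- if (is.null(gr$transcript_id)) rep(NA_character_, length(gr))
           else as.character(gr$transcript_id)
  bad <- which(is.na(gene_id) | is.na(tx_id))
  if (length(bad) > 0L) {
    # recover the offending line number for the error message
    lines <- readLines(path)
    data_lines <- which(!startsWith(lines, "#"))
    exon_lines <- data_lines[grepl("\t(exon)\t", lines[data_lines])]
    ln <- if (bad[1L] <= length(exon_lines)) exon_lines[bad[1L]] else NA_integer_
    stop("exon record missing gene_id/transcript_id attribute (line ",
         ln, " of ", path, ")")
  }
  exons <- data.frame(
    transcript_id = tx_id,
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  if (any(exons$strand == "*"))
    stop("exon feature without strand in ", path)
  transcript_set(exons)
}

#' Cluster isoform transcription start sites into TSS groups
#'
#' Isoforms of the same gene whose TSSs lie within `distance` nt of each
#' other (single linkage, inclusive threshold) form one isoform TSS group.
#' Groups of different genes never merge.  The representative TSS of a group
#' is the minimum member TSS coordinate.
#'
#' @param ts A [transcript_set].
#' @param distance Linkage threshold in nucleotides (default 500).
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `tss`, `group_id`, `representative_tss`.
#' @export
cluster_tss_groups <- function(ts, distance = 500) {
  stopifnot(inherits(ts, "transcript_set"))
  if (distance < 0) stop("distance must be non-negative")
  tx <- ts$tx
  if (nrow(tx) == 0L) return(tx[0, ])
  out <- vector("list", 0L)
  for (g in unique(tx$gene_id)) {
    sub <- tx[tx$gene_id == g, , drop = FALSE]
    ord <- order(sub$tss, sub$transcript_id)
    sub <- sub[ord, , drop = FALSE]
    # single linkage in 1-D: break the sorted chain at gaps > distance
    gap <- c(FALSE, diff(sub$tss) > distance)
    comp <- cumsum(gap) + 1L
    sub$group_id <- paste0(g, ".tss", comp)
    sub$representative_tss <- stats::ave(sub$tss, comp, FUN = min)
    out[[length(out) + 1L]] <- sub
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$span_start, res$transcript_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, c("transcript_id", "gene_id", "chrom", "strand", "tss",
          "group_id", "representative_tss")]
}

#' Summarise TSS groups to one row per group
#'
#' @param membership Output of [cluster_tss_groups()].
#' @return data.frame `group_id`, `gene_id`, `chrom`, `representative_tss`,
#'   `n_members`.
#' @export
tss_group_table <- function(membership) {
  sp <- split(membership, membership$group_id)
  rows <- lapply(sp, function(d) data.frame(
    group_id = d$group_id[1L], gene_id = d$gene_id[1L], chrom = d$chrom[1L],
    representative_tss = d$representative_tss[1L], n_members = nrow(d),
    stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res <- res[order(res$chrom, res$representative_tss, res$group_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fragment length models
#'
#' Either a fixed fragment length or a discrete length distribution.
#'
#' @param length Fixed fragment length in nt (positive integer).
#' @rdname fragment_length
#' @export
frag_length_fixed <- function(length) {
  if (length(length) != 1L || length <= 0)
    stop("fragment length must be a single positive value")
  structure(list(type = "fixed", length = as.numeric(length)),
            class = "frag_length_model")
}

#' @param lengths,probs Support and probabilities of a discrete fragment
#'   length distribution; `probs` must sum to 1.
#' @rdname fragment_length
#' @export
frag_length_dist <- function(lengths, probs) {
  if (length(lengths) != length(probs) || length(lengths) == 0L)
    stop("lengths and probs must be non-empty and of equal length")
  if (any(lengths <= 0)) stop("fragment lengths must be positive")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("probs must be non-negative and sum to 1")
  structure(list(type = "dist", lengths = as.numeric(lengths),
                 probs = as.numeric(probs)),
            class = "frag_length_model")
}

.as_frag_model <- function(x) {
  if (inherits(x, "frag_length_model")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(frag_length_fixed(x))
  stop("fragment_length_model must be a frag_length_model or a single number")
}

#' Effective lengths under a fragment length model
#'
#' The effective length of a transcript is its number of valid fragment
#' start positions: `max(l - L + 1, 1)` for a fixed fragment length `L`, or
#' the expectation `max(sum_l P(l) * max(l_i - l + 1, 0), 1)` under a
#' discrete length distribution.
#'
#' @param ts A [transcript_set].
#' @param fragment_length_model A [frag_length_fixed()] /
#'   [frag_length_dist()] object, or a single number (treated as fixed).
#' @return data.frame `transcript_id`, `length`, `eff_length`.
#' @export
effective_lengths <- function(ts, fragment_length_model) {
  stopifnot(inherits(ts, "transcript_set"))
  fm <- .as_frag_model(fragment_length_model)
  l <- ts$tx$length
  eff <- if (fm$type == "fixed") {
    pmax(l - fm$length + 1, 1)
  } else {
    vapply(l, function(li)
      max(sum(fm$probs * pmax(li - fm$lengths + 1, 0)), 1), numeric(1L))
  }
  data.frame(transcript_id = ts$tx$transcript_id, length = l,
             eff_length = eff, stringsAsFactors = FALSE)
}

# named numeric vector of effective lengths from the various accepted forms
.eff_vec <- function(eff_lengths) {
  if (is.numeric(eff_lengths)) {
    if (is.null(names(eff_lengths))) stop("effective lengths must be named")
    return(eff_lengths)
  }
  stopifnot(is.data.frame(eff_lengths),
            all(c("transcript_id", "eff_length") %in% names(eff_lengths)))
  stats::setNames(eff_lengths$eff_length, eff_lengths$transcript_id)
}

# ---- structural fragment compatibility ------------------------------------

# genomic footprint of the fragment [s, s+L) in transcript coordinates of
# `exons` (matrix start/end, genomic order).  Returns a matrix of genomic
# intervals or NULL when the fragment does not fit.
.footprint <- function(exons, s, L) {
  widths <- exons[, "end"] - exons[, "start"]
  total <- sum(widths)
  if (s < 0 || s + L > total) return(NULL)
  cum <- cumsum(c(0, widths))
  out <- NULL
  remaining <- L
  pos <- s
  for (k in seq_len(nrow(exons))) {
    if (pos >= cum[k + 1L]) next
    off <- pos - cum[k]
    take <- min(remaining, widths[k] - off)
    out <- rbind(out, c(exons[k, "start"] + off,
                        exons[k, "start"] + off + take))
    remaining <- remaining - take
    pos <- pos + take
    if (remaining == 0) break
  }
  colnames(out) <- c("start", "end")
  out
}

# Is the genomic footprint a contiguous sub-path of the exon chain `exons`?
# Returns the transcript coordinate (genomic-order offset) of the footprint
# start in that chain, or NA when incompatible.
.footprint_offset <- function(fp, exons) {
  nf <- nrow(fp)
  ne <- nrow(exons)
  k <- which(exons[, "start"] <= fp[1L, "start"] &
             exons[, "end"] >= fp[1L, "end"])
  if (length(k) != 1L) {
    # the first block must start inside one exon; containment can only fail
    # or hold in one exon because exons are disjoint
    k <- which(exons[, "start"] <= fp[1L, "start"] &
               exons[, "end"] > fp[1L, "start"])
    if (length(k) != 1L) return(NA_real_)
    if (fp[1L, "end"] > exons[k, "end"]) return(NA_real_)
  }
  if (nf > 1L) {
    if (fp[1L, "end"] != exons[k, "end"]) return(NA_real_)  # must be a suffix
    if (k + nf - 1L > ne) return(NA_real_)
    if (nf > 2L) {
      for (m in 2:(nf - 1L)) {
        if (fp[m, "start"] != exons[k + m - 1L, "start"] ||
            fp[m, "end"] != exons[k + m - 1L, "end"]) return(NA_real_)
      }
    }
    if (fp[nf, "start"] != exons[k + nf - 1L, "start"] ||
        fp[nf, "end"] > exons[k + nf - 1L, "end"]) return(NA_real_)
  }
  widths <- exons[, "end"] - exons[, "start"]
  sum(widths[seq_len(k - 1L)]) + (fp[1L, "start"] - exons[k, "start"])
}

#' Structural isoform distinguishability
#'
#' A fragment of length `fragment_length` from transcript i, identified by
#' its genomic exonic footprint, aligns to transcript j when that footprint
#' is a contiguous sub-path of j's exon chain (same chromosome and strand).
#' An isoform is indistinguishable when every one of its possible fragments
#' aligns to at least one other isoform of the same gene.
#'
#' @param ts A [transcript_set] (any number of genes; compatibility is
#'   evaluated within each gene).
#' @param fragment_length Fragment length in nt (>= 1).
#' @return data.frame `transcript_id`, `gene_id`, `indistinguishable`,
#'   `fragment_length`, `witness_fragments` (count of fragments unique to
#'   the transcript; 0 iff indistinguishable).
#' @export
distinguishability <- function(ts, fragment_length) {
  stopifnot(inherits(ts, "transcript_set"))
  if (fragment_length < 1) stop("fragment_length must be >= 1")
  L <- as.integer(fragment_length)
  tx <- ts$tx
  rows <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    sibs <- tx[tx$gene_id == tx$gene_id[i] & tx$transcript_id != id &
               tx$chrom == tx$chrom[i] & tx$strand == tx$strand[i], ,
               drop = FALSE]
    exons_i <- ts$exons[[id]]
    n_start <- tx$length[i] - L + 1L
    witness <- 0L
    if (n_start >= 1L) {
      for (s in 0:(n_start - 1L)) {
        fp <- .footprint(exons_i, s, L)
        hit <- FALSE
        for (j in sibs$transcript_id) {
          if (!is.na(.footprint_offset(fp, ts$exons[[j]]))) { hit <- TRUE; break }
        }
        if (!hit) witness <- witness + 1L
      }
    }
    rows[[i]] <- data.frame(
      transcript_id = id, gene_id = tx$gene_id[i],
      indistinguishable = witness == 0L, fragment_length = L,
      witness_fragments = witness, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write the transcript table TSV
#'
#' Fixed column order: transcript_id, gene_id, chrom, strand, tss, length,
#' effective_length, tss_group_id.
#'
#' @param ts A [transcript_set].
#' @param membership Output of [cluster_tss_groups()].
#' @param eff Output of [effective_lengths()].
#' @param path Output file.
#' @export
write_transcript_table <- function(ts, membership, eff, path) {
  tab <- ts$tx[, c("transcript_id", "gene_id", "chrom", "strand", "tss",
                   "length")]
  tab$effective_length <-
    .eff_vec(eff)[tab$transcript_id]
  tab$tss_group_id <-
    membership$group_id[match(tab$transcript_id, membership$transcript_id)]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
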