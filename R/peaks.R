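#' Read ChIP-seq peaks (narrowPeak or BED6)
#'
#' narrowPeak is the 10-column ENCODE BED extension; its `signalValue`
#' (column 7) becomes the peak signal.  For plain BED6 the `score` column
#' is used.  Coordinates stay 0-based half-open as in BED.
#'
#' @param path Peak file.
#' @param format `"narrowPeak"` or `"bed6"`.
#' @return data.frame `chrom`, `start`, `end`, `signal`, ordered by
#'   (chrom, start, end).
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed6")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak file not found: ", path)
  ncol_needed <- if (format == "narrowPeak") 10L else 6L
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), signal = numeric()))
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE),
    error = function(e) stop("cannot read ", path, ": ", conditionMessage(e)))
  if (nrow(dt) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), signal = numeric()))
  if (ncol(dt) < ncol_needed)
    stop("line 1 of ", path, ": expected ", ncol_needed,
         " columns for ", format)
  start <- suppressWarnings(as.integer(dt[[2L]]))
  end <- suppressWarnings(as.integer(dt[[3L]]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad) > 0L)
    stop("line ", bad[1L], " of ", path,
         ": malformed interval (need numeric start < end)")
  signal <- if (format == "narrowPeak") {
    suppressWarnings(as.numeric(dt[[7L]]))
  } else {
    suppressWarnings(as.numeric(dt[[5L]]))
  }
  bad <- which(is.na(signal) | signal < 0)
  if (length(bad) > 0L)
    stop("line ", bad[1L], " of ", path, ": malformed signal value")
  res <- data.frame(chrom = as.character(dt[[1L]]), start = start,
                    end = end, signal = signal, stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# units: data.frame with unit_id, chrom, tss columns
.check_units <- function(units) {
  if (inherits(units, "transcript_set")) {
    units <- data.frame(unit_id = units$tx$transcript_id,
                        chrom = units$tx$chrom, tss = units$tx$tss,
                        stringsAsFactors = FALSE)
  } else if (all(c("group_id", "representative_tss") %in% names(units))) {
    units <- data.frame(unit_id = units$group_id, chrom = units$chrom,
                        tss = units$representative_tss,
                        stringsAsFactors = FALSE)
    units <- units[!duplicated(units$unit_id), , drop = FALSE]
  }
  stopifnot(all(c("unit_id", "chrom", "tss") %in% names(units)))
  units
}

#' Peak status and aggregate signal in TSS windows
#'
#' A unit (transcript or isoform TSS group) has a peak when some peak
#' interval intersects the window `[tss - flank, tss + flank]` (inclusive,
#' i.e. the half-open interval `[tss - flank, tss + flank + 1)`) on the same
#' chromosome.  The window signal is the sum of the signals of all
#' intersecting peaks.
#'
#' @param units A [transcript_set], the output of [cluster_tss_groups()] /
#'   [tss_group_table()], or any data.frame with `unit_id`, `chrom`, `tss`.
#' @param peaks Output of [read_peaks()].
#' @param flank Window half-width in nt (default 500).
#' @return data.frame `unit_id`, `chrom`, `window_start`, `window_end`,
#'   `has_peak`, `signal`.
#' @export
tss_peak_status <- function(units, peaks, flank = 500) {
  if (flank < 0) stop("flank must be non-negative")
  units <- .check_units(units)
  win_start <- units$tss - flank
  win_end <- units$tss + flank + 1  # half-open end, covers +flank inclusive
  has_peak <- logical(nrow(units))
  signal <- numeric(nrow(units))
  if (nrow(peaks) > 0L && nrow(units) > 0L) {
    chroms <- union(units$chrom, peaks$chrom)
    qgr <- GenomicRanges::GRanges(factor(units$chrom, chroms),
             IRanges::IRanges(start = win_start + 1L, end = win_end))
    sgr <- GenomicRanges::GRanges(factor(peaks$chrom, chroms),
             IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
    hits <- GenomicRanges::findOverlaps(qgr, sgr)
    if (length(hits) > 0L) {
      agg <- rowsum(peaks$signal[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
      idx <- as.integer(rownames(agg))
      has_peak[idx] <- TRUE
      signal[idx] <- agg[, 1L]
    }
  }
  data.frame(unit_id = units$unit_id, chrom = units$chrom,
             window_start = win_start, window_end = win_end,
             has_peak = has_peak, signal = signal, stringsAsFactors = FALSE)
}

#' Depth-normalised 5'-end signal in TSS windows (RPM)
#'
#' Counts reads whose 5' end falls within the `flank`-nt window of the TSS
#' of any member of a unit (a read is counted once per unit even when it
#' hits several member windows), normalised to reads per million.
#'
#' @param read_positions data.frame with `chrom` and `pos` (0-based 5'-end
#'   coordinate), e.g. from a BED file of read 5' ends.
#' @param members data.frame with `unit_id`, `chrom`, `tss`, one row per
#'   member TSS of each unit (a transcript-level table may be passed
#'   directly with `unit_id` set to the group id).
#' @param flank Window half-width in nt (default 100).
#' @param library_depth Total reads in the library (> 0).
#' @return Named numeric vector of RPM per `unit_id`.
#' @export
tss_signal_rpm <- function(read_positions, members, flank = 100,
                           library_depth) {
  if (missing(library_depth) || library_depth <= 0)
    stop("library_depth must be positive")
  stopifnot(all(c("chrom", "pos") %in% names(read_positions)),
            all(c("unit_id", "chrom", "tss") %in% names(members)))
  counts <- stats::setNames(numeric(length(unique(members$unit_id))),
                            unique(members$unit_id))
  if (nrow(read_positions) > 0L && nrow(members) > 0L) {
    chroms <- union(members$chrom, read_positions$chrom)
    qgr <- GenomicRanges::GRanges(factor(members$chrom, chroms),
             IRanges::IRanges(start = members$tss - flank + 1L,
                              end = members$tss + flank + 1L))
    rgr <- GenomicRanges::GRanges(factor(read_positions$chrom, chroms),
             IRanges::IRanges(start = read_positions$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(qgr, rgr)
    if (length(hits) > 0L) {
      pair <- unique(data.frame(
        unit = members$unit_id[S4Vectors::queryHits(hits)],
        read = S4Vectors::subjectHits(hits)))
      tab <- table(pair$unit)
      counts[names(tab)] <- as.numeric(tab)
    }
  }
  1e6 * counts / library_depth
}

#' Gene-level peak status categories
#'
#' A gene is `"all"` when every one of its isoform TSS groups has a peak,
#' `"mixed"` when only some do, `"none"` when none does.
#'
#' @param group_features data.frame with `gene_id`, `unit_id` (group id) and
#'   `has_peak` — e.g. [tss_peak_status()] on TSS groups joined with their
#'   gene ids.
#' @return data.frame `gene_id`, `category`.
#' @export
gene_peak_status <- function(group_features) {
  stopifnot(all(c("gene_id", "has_peak") %in% names(group_features)))
  sp <- split(group_features$has_peak, group_features$gene_id)
  category <- vapply(sp, function(fl) {
    if (all(fl)) "all" else if (any(fl)) "mixed" else "none"
  }, character(1L))
  res <- data.frame(gene_id = names(sp), category = unname(category),
                    stringsAsFactors = FALSE)
  res[order(res$gene_id), , drop = FALSE]
}
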