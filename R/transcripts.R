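# Transcript processing: isolate 3' terminal exons, extend them downstream,
# trim neighbor overlaps, refine ends by read coverage, merge (for training)
# and cut into masked fixed-length bin sequences.

#' Construct a terminal region
#'
#' A (possibly merged) modified 3' terminal exon interval, carrying its
#' source transcripts and their original stop positions.
#' @param chrom,strand,start,end Strand-specific 1-based inclusive interval.
#' @param source_transcript_ids Character vector of source transcript ids.
#' @param original_stops 1-based 3' stop positions, one per source transcript.
#' @param merged Was this region produced by merging overlapping regions?
#' @return An `apa_region` object.
#' @export
apa_region <- function(chrom, strand, start, end, source_transcript_ids,
                       original_stops, merged = FALSE) {
  if (end < start) stop_fmt("region end < start")
  if (any(original_stops < start | original_stops > end))
    stop_fmt("region [%d,%d] does not contain all original stops",
             as.integer(start), as.integer(end))
  structure(list(chrom = chrom, strand = strand, start = as.numeric(start),
                 end = as.numeric(end),
                 source_transcript_ids = source_transcript_ids,
                 original_stops = as.numeric(original_stops),
                 merged = merged),
            class = "apa_region")
}

#' @export
print.apa_region <- function(x, ...) {
  cat(sprintf("apa_region %s:%s [%d,%d] (%d bases, %d source(s)%s)\n",
              x$chrom, x$strand, as.integer(x$start), as.integer(x$end),
              as.integer(x$end - x$start + 1),
              length(x$source_transcript_ids),
              if (x$merged) ", merged" else ""))
  invisible(x)
}

#' Isolate a transcript's 3' terminal exon
#'
#' @param t An [apa_transcript()].
#' @return An [apa_region()] covering the last exon in transcription order,
#'   with the transcript's 3' stop as its single original stop.
#' @export
extract_terminal_exon <- function(t) {
  ex <- if (t$strand == "+") t$exons[nrow(t$exons), ] else t$exons[1, ]
  apa_region(t$chrom, t$strand, ex[["start"]], ex[["end"]],
             t$transcript_id, transcript_stop3p(t))
}

#' Extend a terminal region downstream
#'
#' Moves the region's 3' boundary downstream by `10000 + 2 * bin_size` bases
#' (10,200 for the default 100-base bin), clipped at the chromosome end, then
#' shortens the extension so it does not overlap the exon span of any
#' neighboring same-strand transcript. The region is never shortened past the
#' original stop.
#'
#' @param r An [apa_region()].
#' @param bin_size Bin width in bases.
#' @param neighbors Transcripts on the same chromosome/strand other than the
#'   region's sources (others are ignored).
#' @param chrom_length Chromosome length in bases.
#' @return The extended `apa_region`.
#' @export
extend_region <- function(r, bin_size = 100, neighbors = list(),
                          chrom_length = Inf) {
  ext <- 10000 + 2 * bin_size
  spans <- lapply(neighbors, function(t) {
    if (t$chrom != r$chrom || t$strand != r$strand) return(NULL)
    if (t$transcript_id %in% r$source_transcript_ids) return(NULL)
    c(min(t$exons[, 1]), max(t$exons[, 2]))
  })
  spans <- Filter(Negate(is.null), spans)
  if (r$strand == "+") {
    stop0 <- max(r$original_stops)
    new_end <- min(r$end + ext, chrom_length)
    for (sp in spans) {   # clip extension [r$end+1, new_end] at neighbor spans
      if (sp[1] <= new_end && sp[2] > r$end)
        new_end <- min(new_end, max(r$end, sp[1] - 1))
    }
    new_end <- max(new_end, stop0)
    apa_region(r$chrom, r$strand, r$start, new_end,
               r$source_transcript_ids, r$original_stops, r$merged)
  } else {
    stop0 <- min(r$original_stops)
    new_start <- max(r$start - ext, 1)
    for (sp in spans) {
      if (sp[2] >= new_start && sp[1] < r$start)
        new_start <- max(new_start, min(r$start, sp[2] + 1))
    }
    new_start <- min(new_start, stop0)
    apa_region(r$chrom, r$strand, new_start, r$end,
               r$source_transcript_ids, r$original_stops, r$merged)
  }
}

#' Refine an extended region by read coverage
#'
#' Walks 5' to 3' from the original stop in windows of `bin_size` bases and
#' truncates the extension at the first window whose mean depth falls below
#' `max(min_abs_cov, frac * D0)`, where `D0` is the mean depth over the
#' window ending at the original stop. Either shortens the extended region or
#' keeps it the same length; never shortens past the original terminal exon.
#'
#' @param r An extended [apa_region()].
#' @param cov An `apa_coverage` from [load_coverage()].
#' @param bin_size Window width in bases.
#' @param min_abs_cov Absolute depth floor for the truncation threshold.
#' @param frac Fraction of `D0` for the truncation threshold.
#' @return The refined `apa_region`.
#' @export
refine_region <- function(r, cov, bin_size = 100, min_abs_cov = 5,
                          frac = 0.05) {
  if (r$strand == "+") {
    s <- max(r$original_stops)
    d0 <- mean(cov_depth(cov, r$chrom, r$strand,
                         max(r$start, s - bin_size + 1):s))
    thr <- max(min_abs_cov, frac * d0)
    new_end <- r$end
    k <- 0
    repeat {
      w_lo <- s + 1 + k * bin_size
      if (w_lo > r$end) break
      w_hi <- min(w_lo + bin_size - 1, r$end)
      if (mean(cov_depth(cov, r$chrom, r$strand, w_lo:w_hi)) < thr) {
        new_end <- w_lo - 1
        break
      }
      k <- k + 1
    }
    apa_region(r$chrom, r$strand, r$start, new_end,
               r$source_transcript_ids, r$original_stops, r$merged)
  } else {
    s <- min(r$original_stops)
    d0 <- mean(cov_depth(cov, r$chrom, r$strand,
                         s:min(r$end, s + bin_size - 1)))
    thr <- max(min_abs_cov, frac * d0)
    new_start <- r$start
    k <- 0
    repeat {
      w_hi <- s - 1 - k * bin_size
      if (w_hi < r$start) break
      w_lo <- max(w_hi - bin_size + 1, r$start)
      if (mean(cov_depth(cov, r$chrom, r$strand, w_lo:w_hi)) < thr) {
        new_start <- w_hi + 1
        break
      }
      k <- k + 1
    }
    apa_region(r$chrom, r$strand, new_start, r$end,
               r$source_transcript_ids, r$original_stops, r$merged)
  }
}

#' Merge overlapping terminal regions
#'
#' Same-chromosome, same-strand overlapping intervals are unioned, with
#' source ids and original stops concatenated. Used before training so no
#' genomic bin is duplicated; prediction keeps per-transcript regions.
#'
#' @param regions List of [apa_region()] objects.
#' @return List of merged `apa_region` objects.
#' @export
merge_regions <- function(regions) {
  if (length(regions) == 0) return(list())
  keys <- vapply(regions, function(r) paste(r$chrom, r$strand), "")
  out <- list()
  for (key in unique(keys)) {
    grp <- regions[keys == key]
    grp <- grp[order(vapply(grp, `[[`, 0, "start"))]
    cur <- grp[[1]]
    flush <- function(r) {
      r$merged <- length(r$source_transcript_ids) > 1
      out[[length(out) + 1]] <<- r
    }
    for (r in grp[-1]) {
      if (r$start <= cur$end) {      # overlap (1-based inclusive)
        cur$end <- max(cur$end, r$end)
        cur$source_transcript_ids <- c(cur$source_transcript_ids,
                                       r$source_transcript_ids)
        cur$original_stops <- c(cur$original_stops, r$original_stops)
      } else {
        flush(cur)
        cur <- r
      }
    }
    flush(cur)
  }
  out
}

#' Cut a region into masked fixed-length bin sequences
#'
#' Tiles the region with `bin_size`-base bins 5' to 3' in transcription
#' order, starting at the region's 5' boundary; a trailing remnant shorter
#' than one bin is dropped. Regions longer than `max_len` bins are split into
#' consecutive chunks; the final chunk is padded at its 3' tail with masked
#' bins (zero features, excluded from loss, standardization and metrics).
#'
#' @param r A refined or merged [apa_region()].
#' @param bin_size Bin width in bases.
#' @param max_len Sequence length in bins.
#' @param labels Optional `apa_sites`; a bin is labelled 1 iff at least one
#'   site lies within its interval on the matching strand, else 0. Without
#'   labels bins are unlabelled (`NA`).
#' @return List of `apa_bins` sequences (possibly empty, with a warning, if
#'   the region is shorter than one bin).
#' @export
bin_region <- function(r, bin_size = 100, max_len = 300, labels = NULL) {
  n <- floor((r$end - r$start + 1) / bin_size)
  if (n == 0) {
    warning(sprintf("region %s:%s [%d,%d] shorter than one bin; skipped",
                    r$chrom, r$strand, as.integer(r$start), as.integer(r$end)))
    return(list())
  }
  if (r$strand == "+") {
    starts <- r$start + (seq_len(n) - 1) * bin_size
    ends <- starts + bin_size - 1
  } else {
    ends <- r$end - (seq_len(n) - 1) * bin_size
    starts <- ends - bin_size + 1
  }
  lab <- if (is.null(labels)) rep(NA_integer_, n) else {
    vapply(seq_len(n), function(i) {
      as.integer(nrow(sites_in_interval(labels, r$chrom, r$strand,
                                        starts[i], ends[i])) > 0)
    }, 0L)
  }
  n_chunks <- ceiling(n / max_len)
  lapply(seq_len(n_chunks), function(ci) {
    idx <- ((ci - 1) * max_len + 1):min(ci * max_len, n)
    k <- length(idx)
    pad <- max_len - k
    structure(list(
      seq_id = sprintf("%s:%s:%d-%d|%d", r$chrom, r$strand,
                       as.integer(r$start), as.integer(r$end), ci),
      chrom = r$chrom, strand = r$strand, region = r,
      bin_size = bin_size, max_len = max_len, chunk = ci,
      start = c(starts[idx], rep(NA_real_, pad)),
      end = c(ends[idx], rep(NA_real_, pad)),
      label = c(lab[idx], rep(NA_integer_, pad)),
      mask = c(rep(TRUE, k), rep(FALSE, pad)),
      n_real = k, features = NULL), class = "apa_bins")
  })
}

#' @export
print.apa_bins <- function(x, ...) {
  cat(sprintf("apa_bins %s: %d real / %d total bins of %d bases%s%s\n",
              x$seq_id, x$n_real, length(x$mask), x$bin_size,
              if (is.null(x$features)) "" else ", featurized",
              if (all(is.na(x$label))) "" else
                sprintf(", %d positive", sum(x$label == 1, na.rm = TRUE))))
  invisible(x)
}

#' Build bin sequences for a set of transcripts
#'
#' Runs the full transcript-processing chain: terminal-exon isolation,
#' downstream extension with neighbor trimming, coverage-based refinement,
#' optional merging of overlapping regions (training), and binning into
#' masked fixed-length sequences.
#'
#' @param transcripts Named list of [apa_transcript()] objects.
#' @param genome An `apa_genome` (for chromosome lengths).
#' @param cov An `apa_coverage`.
#' @param labels Optional `apa_sites` used to label bins.
#' @param merge Merge overlapping refined regions (use `TRUE` for training,
#'   `FALSE` for per-transcript prediction).
#' @param bin_size,max_len See [bin_region()].
#' @param min_abs_cov,frac See [refine_region()].
#' @return List of `apa_bins` sequences; the refined (pre-merge) regions are
#'   attached as attribute `"regions"` (named by transcript id).
#' @export
prepare_bin_sequences <- function(transcripts, genome, cov, labels = NULL,
                                  merge = FALSE, bin_size = 100,
                                  max_len = 300, min_abs_cov = 5,
                                  frac = 0.05) {
  regions <- lapply(transcripts, function(t) {
    r <- extract_terminal_exon(t)
    r <- extend_region(r, bin_size, neighbors = transcripts,
                       chrom_length = chrom_length(genome, t$chrom))
    refine_region(r, cov, bin_size, min_abs_cov, frac)
  })
  names(regions) <- vapply(transcripts, `[[`, "", "transcript_id")
  binned <- if (merge) merge_regions(regions) else regions
  out <- list()
  for (r in binned)
    out <- c(out, bin_region(r, bin_size, max_len, labels))
  attr(out, "regions") <- regions
  out
}
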