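# Bin-level precision/recall/F/average-precision metrics for imbalanced
# labels, and transcriptome-level 3'-terminus benchmarking against a true
# polyA-site set.

#' Confusion counts over real bins
#'
#' @param calls 0/1 calls, a vector or `N x T` matrix.
#' @param labels 0/1 labels of the same shape.
#' @param masks Optional mask of the same shape (1/TRUE = real bin); padded
#'   bins are excluded from all counts.
#' @return Named vector `c(Tp, Fp, Fn, Tn)`.
#' @export
confusion <- function(calls, labels, masks = NULL) {
  if (length(calls) != length(labels))
    stop_fmt("calls and labels have different lengths")
  keep <- if (is.null(masks)) rep(TRUE, length(calls)) else {
    if (length(masks) != length(calls))
      stop_fmt("masks length mismatch")
    as.logical(masks)
  }
  y <- as.integer(labels)[keep]
  p <- as.integer(calls)[keep]
  c(Tp = sum(p == 1 & y == 1), Fp = sum(p == 1 & y == 0),
    Fn = sum(p == 0 & y == 1), Tn = sum(p == 0 & y == 0))
}

#' F-measure from precision and recall
#'
#' Harmonic mean `2PR/(P+R)`, with the `0/0 -> 0` convention.
#' @param p,r Precision and recall in `[0, 1]`.
#' @return The F-measure.
#' @export
f_measure <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

#' Precision, recall and F-measure from confusion counts
#'
#' `P = Tp/(Tp+Fp)`, `R = Tp/(Tp+Fn)`, `F = 2PR/(P+R)`; any `0/0` is 0.
#' @param counts Named vector with `Tp`, `Fp`, `Fn` (as from [confusion()]).
#' @return Named vector `c(P, R, F)`.
#' @export
prf <- function(counts) {
  tp <- counts[["Tp"]]; fp <- counts[["Fp"]]; fn <- counts[["Fn"]]
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(P = p, R = r, F = f_measure(p, r))
}

#' Average precision
#'
#' The threshold-sweep summary of the precision-recall curve,
#' `AP = sum_n (R_n - R_{n-1}) P_n` with `R_0 = 0`, thresholding at each
#' distinct predicted probability in descending order (no interpolation).
#' Preferred over ROC area for the highly imbalanced bin labels.
#'
#' @param probs Predicted probabilities (vector or matrix).
#' @param labels 0/1 labels of the same shape.
#' @param masks Optional mask; padded bins are excluded.
#' @return AP in `[0, 1]`. At least one positive label is required.
#' @export
average_precision <- function(probs, labels, masks = NULL) {
  keep <- if (is.null(masks)) rep(TRUE, length(probs)) else as.logical(masks)
  p <- as.numeric(probs)[keep]
  y <- as.integer(labels)[keep]
  n_pos <- sum(y == 1)
  if (n_pos == 0) stop_fmt("average_precision: no positive labels")
  ord <- order(p, decreasing = TRUE)
  p <- p[ord]; y <- y[ord]
  # at each distinct probability threshold, cumulative Tp and predicted-pos
  cum_tp <- cumsum(y)
  cum_pp <- seq_along(y)
  last_of_tie <- c(p[-1] != p[-length(p)], TRUE)
  tp <- cum_tp[last_of_tie]
  pp <- cum_pp[last_of_tie]
  prec <- tp / pp
  rec <- tp / n_pos
  sum((rec - c(0, rec[-length(rec)])) * prec)
}

#' Bin-level evaluation report
#'
#' Confusion counts, precision/recall/F at the probability threshold, and
#' average precision, over real bins only.
#' @param probs,labels,masks As in [average_precision()].
#' @param threshold Probability call threshold.
#' @return An `apa_eval` list: `counts`, `P`, `R`, `F`, `AP`, `threshold`,
#'   `n_bins`, `prevalence`.
#' @export
eval_report <- function(probs, labels, masks = NULL, threshold = 0.5) {
  counts <- confusion(as.integer(as.numeric(probs) >= threshold), labels,
                      masks)
  m <- prf(counts)
  keep <- if (is.null(masks)) rep(TRUE, length(probs)) else as.logical(masks)
  structure(list(counts = counts, P = m[["P"]], R = m[["R"]], F = m[["F"]],
                 AP = average_precision(probs, labels, masks),
                 threshold = threshold, n_bins = sum(keep),
                 prevalence = mean(as.integer(labels)[keep])),
            class = "apa_eval")
}

#' @export
print.apa_eval <- function(x, ...) {
  cat(sprintf(paste0("apa_eval: %d bins (prevalence %.3f)\n",
                     "  Tp %d  Fp %d  Fn %d  Tn %d\n",
                     "  P %.3f  R %.3f  F %.3f  AP %.3f (threshold %.2f)\n"),
              x$n_bins, x$prevalence, x$counts[["Tp"]], x$counts[["Fp"]],
              x$counts[["Fn"]], x$counts[["Tn"]], x$P, x$R, x$F, x$AP,
              x$threshold))
  invisible(x)
}

#' Benchmark transcript 3' termini against true polyA sites
#'
#' A transcript counts as a true positive iff some truth site on the same
#' chromosome and strand lies within `cutoff` bases (inclusive) of its 3'
#' stop; otherwise a false positive. Also reports how many distinct truth
#' sites are captured by at least one transcript, and the per-unique-terminus
#' tally (multiple transcripts can share a terminus).
#'
#' @param transcripts List of [apa_transcript()] objects.
#' @param truth An `apa_sites` data frame.
#' @param cutoff Maximum |distance| in bases (default 100).
#' @return An `apa_terminus_benchmark` list with `tp_transcripts`,
#'   `fp_transcripts`, `ppv`, `unique_true_sites_captured`,
#'   `unique_termini`, `tp_unique_termini` and `cutoff`.
#' @export
benchmark_termini <- function(transcripts, truth, cutoff = 100) {
  stops <- data.frame(
    chrom = vapply(transcripts, `[[`, "", "chrom"),
    strand = vapply(transcripts, `[[`, "", "strand"),
    pos = vapply(transcripts, transcript_stop3p, 0),
    stringsAsFactors = FALSE)
  tp <- logical(nrow(stops))
  captured <- character(0)
  for (i in seq_len(nrow(stops))) {
    near <- truth[truth$chrom == stops$chrom[i] &
                  truth$strand == stops$strand[i] &
                  abs(truth$pos - stops$pos[i]) <= cutoff, , drop = FALSE]
    if (nrow(near) > 0) {
      tp[i] <- TRUE
      captured <- c(captured, paste(near$chrom, near$strand, near$pos))
    }
  }
  term_key <- paste(stops$chrom, stops$strand, stops$pos)
  uniq <- !duplicated(term_key)
  n_tp <- sum(tp)
  structure(list(cutoff = cutoff, tp_transcripts = n_tp,
                 fp_transcripts = sum(!tp),
                 ppv = if (nrow(stops) == 0) 0 else n_tp / nrow(stops),
                 unique_true_sites_captured = length(unique(captured)),
                 unique_termini = sum(uniq),
                 tp_unique_termini = sum(tp[uniq])),
            class = "apa_terminus_benchmark")
}

#' @export
print.apa_terminus_benchmark <- function(x, ...) {
  cat(sprintf(paste0("apa_terminus_benchmark (+/-%d bases):\n",
                     "  %d/%d transcript termini match a true site",
                     " (PPV %.3f)\n",
                     "  %d unique true sites captured;",
                     " %d/%d unique termini match\n"),
              x$cutoff, x$tp_transcripts,
              x$tp_transcripts + x$fp_transcripts, x$ppv,
              x$unique_true_sites_captured, x$tp_unique_termini,
              x$unique_termini))
  invisible(x)
}
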