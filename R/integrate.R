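# Integration: turn positive bin calls into new transcript 3' ends and
# emit the modified transcriptome (original transcripts preserved, new
# isoforms added).

#' Place predicted polyA sites on a transcript
#'
#' Each positive bin yields a candidate new 3' stop at the bin's 3'-most
#' base in transcription orientation, unless (1) the transcript's original
#' stop already lies inside that bin, or (2) the candidate stop is within
#' `suppress_dist` bases of the original stop.
#'
#' @param predictions An `apa_predictions` data frame (per-transcript,
#'   unmerged) restricted to this transcript's region.
#' @param region The transcript's refined [apa_region()].
#' @param transcript The source [apa_transcript()].
#' @param suppress_dist Distance rule (2) in bases.
#' @return Data frame with `transcript_id`, `new_stop`, `bin_start`,
#'   `bin_end`, `probability` (possibly zero rows).
#' @export
place_sites <- function(predictions, region, transcript,
                        suppress_dist = 100) {
  pos <- predictions[predictions$call == 1, , drop = FALSE]
  orig <- transcript_stop3p(transcript)
  out <- data.frame(transcript_id = character(0), new_stop = numeric(0),
                    bin_start = numeric(0), bin_end = numeric(0),
                    probability = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pos))) {
    b_lo <- pos$start[i]; b_hi <- pos$end[i]
    new_stop <- if (transcript$strand == "+") b_hi else b_lo
    if (orig >= b_lo && orig <= b_hi) next          # rule (1)
    if (abs(new_stop - orig) <= suppress_dist) next # rule (2)
    out <- rbind(out, data.frame(
      transcript_id = transcript$transcript_id, new_stop = new_stop,
      bin_start = b_lo, bin_end = b_hi, probability = pos$prob[i],
      stringsAsFactors = FALSE))
  }
  out
}

#' Build the modified transcriptome
#'
#' Adds, for every placement, a copy of the source transcript whose terminal
#' exon's 3' boundary is moved to the new stop; the intron chain is
#' untouched and every input transcript appears unchanged in the output (the
#' integration only adds transcripts). A placement that would push the
#' terminal exon past its own 5' start (inverting it) is rejected and
#' logged. New ids are the source id plus an `".apa<k>"` ordinal, numbered
#' by genomic position of the new stop.
#'
#' @param original Named list of [apa_transcript()] objects.
#' @param placements Data frame from [place_sites()] (rows for any number of
#'   transcripts).
#' @param dedup_across_isoforms Drop a placement whose new stop coincides
#'   with another isoform's existing 3' terminus. Off by default: a site is
#'   added per transcript regardless of other isoforms' stops.
#' @return List of transcripts: all originals followed by the added
#'   isoforms.
#' @export
build_modified_transcriptome <- function(original, placements,
                                         dedup_across_isoforms = FALSE) {
  out <- original
  if (is.null(placements) || nrow(placements) == 0) return(out)
  by_id <- split(placements, placements$transcript_id)
  existing_stops <- if (dedup_across_isoforms) {
    vapply(original, function(t)
      paste(t$chrom, t$strand, transcript_stop3p(t)), "")
  } else character(0)
  for (id in names(by_id)) {
    t <- original[[id]]
    if (is.null(t)) stop_fmt("placement for unknown transcript '%s'", id)
    pl <- by_id[[id]]
    pl <- pl[order(pl$new_stop), , drop = FALSE]
    k <- 0
    for (i in seq_len(nrow(pl))) {
      ns <- pl$new_stop[i]
      ex <- t$exons
      if (t$strand == "+") {
        term <- nrow(ex)
        if (ns < ex[term, 1]) {
          apa_log("placement %s@%d 5' of terminal exon start; rejected",
                  id, as.integer(ns))
          next
        }
        ex[term, 2] <- ns
      } else {
        if (ns > ex[1, 2]) {
          apa_log("placement %s@%d 5' of terminal exon start; rejected",
                  id, as.integer(ns))
          next
        }
        ex[1, 1] <- ns
      }
      if (dedup_across_isoforms &&
          paste(t$chrom, t$strand, ns) %in% existing_stops) next
      k <- k + 1
      new_id <- sprintf("%s.apa%d", id, k)
      if (new_id %in% names(out)) stop_fmt("duplicate output id %s", new_id)
      nt <- apa_transcript(new_id, t$gene_id, t$chrom, t$strand, ex,
                           source = "predicted")
      out[[new_id]] <- nt
    }
  }
  out
}

#' Summarize added isoforms
#'
#' One row per source transcript with the number of sites added and their
#' positions/probabilities; writable as the integration summary TSV.
#' @param placements Data frame from [place_sites()].
#' @param path Optional TSV output path.
#' @return The summary data frame.
#' @export
placement_summary <- function(placements, path = NULL) {
  if (is.null(placements) || nrow(placements) == 0) {
    out <- data.frame(transcript_id = character(0), n_sites_added = integer(0),
                      positions = character(0), probabilities = character(0))
  } else {
    sp <- split(placements, placements$transcript_id)
    out <- do.call(rbind, lapply(sp, function(d) data.frame(
      transcript_id = d$transcript_id[1], n_sites_added = nrow(d),
      positions = paste(as.integer(d$new_stop), collapse = ","),
      probabilities = paste(sprintf("%.4f", d$probability), collapse = ","),
      stringsAsFactors = FALSE)))
    rownames(out) <- NULL
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
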