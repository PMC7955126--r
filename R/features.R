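# Per-bin feature engineering: 4 polyA-signal (PAS) hexamer features, 8 DNA
# sequence-element features, 14 RNA-Seq coverage features and 1
# annotation-end feature, each computed from the bin plus 100 bases of
# flanking context oriented 5'->3' along the transcript strand.
#
# Offsets in this file are 0-based within the oriented window (offset 0 =
# 5'-most window base), matching the interval notation in the docs.

PAS_CANONICAL <- "AATAAA"
PAS_VARIANT1 <- "ATTAAA"
PAS_VARIANT2 <- "AGTAAA"
# The minor-variant class: the eight hexamers implemented here. (Commonly
# cited lists have up to nine; this set is the package's frozen default and
# is part of the feature-config hash.)
PAS_MINOR <- c("AAGAAA", "AAAAAG", "AATACA", "TATAAA", "GATAAA", "AATATA",
               "CATAAA", "AATAGA")

#' Feature configuration
#'
#' Frozen definition of the 27-bin-feature set: window geometry, PAS scan
#' range, element regions and enrichment thresholds. Trained models store a
#' hash of this configuration and refuse mismatched inputs.
#'
#' @param flank Flanking context on each side of the bin, bases.
#' @param pas_upstream How far upstream of the bin's 5' edge the PAS scan
#'   starts, bases (PAS hexamers sit ~10-35 nt upstream of cleavage sites).
#' @param neutral_anchor Offset past the bin's 5' edge used as the anchor
#'   when no PAS is found.
#' @param g_rich_min Min non-overlapping `GGG` count downstream.
#' @param ttt_min Min `TTT` count near-downstream.
#' @param gt_min Min overlapping `GT`/`TG` dimer count downstream.
#' @param gtgt_min Min overlapping `GTGT`/`TGTG` count downstream.
#' @param t_frac Min T fraction for the T-rich regions.
#' @param tgta_min Min overlapping `TGTA`/`TATA` count upstream.
#' @param at_frac Min A+T fraction over the combined up/downstream region.
#' @return A `feature_config` list; pass to [featurize()].
#' @export
feature_config <- function(flank = 100, pas_upstream = 35,
                           neutral_anchor = 15, g_rich_min = 3, ttt_min = 2,
                           gt_min = 6, gtgt_min = 2, t_frac = 0.4,
                           tgta_min = 2, at_frac = 0.65) {
  # scalars coerced to double so the config hash is storage-invariant
  cfg <- list(flank = as.numeric(flank),
              pas_upstream = as.numeric(pas_upstream),
              neutral_anchor = as.numeric(neutral_anchor),
              g_rich_min = as.numeric(g_rich_min),
              ttt_min = as.numeric(ttt_min), gt_min = as.numeric(gt_min),
              gtgt_min = as.numeric(gtgt_min),
              t_frac = as.numeric(t_frac),
              tgta_min = as.numeric(tgta_min),
              at_frac = as.numeric(at_frac),
              hexamers = list(canonical = PAS_CANONICAL,
                              variant1 = PAS_VARIANT1,
                              variant2 = PAS_VARIANT2, minor = PAS_MINOR),
              feature_names = apa_feature_names())
  class(cfg) <- "feature_config"
  cfg
}

#' Names of the 27 bin features, in frozen order
#' @return Character vector of length 27.
#' @export
apa_feature_names <- function() {
  c("pas_canonical", "pas_attaaa", "pas_agtaaa", "pas_minor",
    "el_g_rich_down", "el_ttt_near_down", "el_gt_down", "el_gtgt_down",
    "el_t_rich_down", "el_t_rich_up", "el_tgta_up", "el_at_rich",
    paste0("rna_intra_", c("s_um", "s_md", "s_ud", "log_m", "dlog_um",
                           "dlog_md", "drop")),
    paste0("rna_inter_", c("s_um", "s_md", "s_ud", "log_m", "dlog_um",
                           "dlog_md", "drop")),
    "annot_end")
}

RNA_FEATURE_IDX <- 13:26   # quantitative columns (standardized at training)

#' Build the oriented sequence/coverage window around a bin
#'
#' The window is the bin plus `flank` bases on each side, oriented 5'->3'
#' along the transcript strand: on `-` the sequence is reverse-complemented
#' and the coverage reversed, so "downstream" always means 3' of
#' transcription. Portions clipped at chromosome ends are filled with `N`
#' (sequence) and 0 (coverage).
#'
#' @param chrom,strand,start,end The bin's strand and genomic interval.
#' @param genome An `apa_genome`.
#' @param cov An `apa_coverage`.
#' @param flank Flank width, bases.
#' @return List with `seq` (character scalar), `cov` (numeric vector of the
#'   same length), `bin_size` and `flank`.
#' @export
build_window <- function(chrom, strand, start, end, genome, cov,
                         flank = 100) {
  gstart <- start - flank
  gend <- end + flank
  seq <- genome_fetch(genome, chrom, gstart, gend)
  len <- cov$lengths[[chrom]] %||% chrom_length(genome, chrom)
  lo <- max(1, gstart); hi <- min(len, gend)
  depth <- numeric(gend - gstart + 1)
  if (lo <= hi)
    depth[(lo - gstart + 1):(hi - gstart + 1)] <-
      cov_depth(cov, chrom, strand, lo:hi)
  if (strand == "-") {
    seq <- revcomp(seq)
    depth <- rev(depth)
  }
  list(seq = seq, cov = depth, bin_size = end - start + 1, flank = flank)
}

# Match start offsets (0-based, window coordinates) of a hexamer whose start
# lies in [from, to] (0-based inclusive).
hexamer_offsets <- function(seq, hexamer, from, to) {
  if (to < from) return(integer(0))
  region <- substr(seq, from + 1, to + nchar(hexamer))
  m <- gregexpr(hexamer, region, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  # gregexpr is non-overlapping; re-scan within each match's tail to catch
  # overlapping occurrences of self-overlapping hexamers (e.g. AAAAAG)
  hits <- integer(0)
  chars <- strsplit(region, "", fixed = TRUE)[[1]]
  k <- nchar(hexamer)
  for (i in seq_len(length(chars) - k + 1)) {
    if (all(chars[i:(i + k - 1)] == strsplit(hexamer, "")[[1]]))
      hits <- c(hits, i)
  }
  hits + from - 1
}

#' Scan a window for polyA-signal hexamers
#'
#' A six-base sliding window scans from `pas_upstream` bases upstream of the
#' bin's 5' edge through the bin's 3' edge (offsets `[flank - pas_upstream,
#' flank + bin_size)` in window coordinates), reflecting PAS placement 10-35
#' nt upstream of a cleavage site anywhere in the bin. Four presence/absence
#' features are returned, encoded 1/-1: the canonical AATAAA, ATTAAA,
#' AGTAAA, and any of the minor variants.
#'
#' @param w A window from [build_window()].
#' @param config A [feature_config()].
#' @return List with `features` (named numeric of length 4) and `pas_pos`
#'   (0-based window offset of the highest-priority, 3'-most match, or `NA`).
#'   Priority: canonical > ATTAAA > AGTAAA > minor.
#' @export
scan_pas <- function(w, config = feature_config()) {
  from <- w$flank - config$pas_upstream
  to <- w$flank + w$bin_size - 6          # last start that fits in the region
  hits <- list(
    canonical = hexamer_offsets(w$seq, config$hexamers$canonical, from, to),
    variant1 = hexamer_offsets(w$seq, config$hexamers$variant1, from, to),
    variant2 = hexamer_offsets(w$seq, config$hexamers$variant2, from, to),
    minor = sort(unique(unlist(lapply(config$hexamers$minor,
                                      hexamer_offsets, seq = w$seq,
                                      from = from, to = to)))))
  feats <- vapply(hits, function(h) if (length(h)) 1 else -1, 0)
  names(feats) <- apa_feature_names()[1:4]
  pas_pos <- NA_integer_
  for (cls in c("canonical", "variant1", "variant2", "minor")) {
    if (length(hits[[cls]])) {
      pas_pos <- max(hits[[cls]])          # 3'-most within the class
      break
    }
  }
  list(features = feats, pas_pos = pas_pos)
}

count_kmer_overlapping <- function(chars, kmers) {
  n <- length(chars)
  k <- nchar(kmers[1])
  if (n < k) return(0L)
  total <- 0L
  for (km in kmers) {
    pat <- strsplit(km, "", fixed = TRUE)[[1]]
    ok <- rep(TRUE, n - k + 1)
    for (j in seq_len(k)) ok <- ok & chars[j:(n - k + j)] == pat[j]
    total <- total + sum(ok)
  }
  total
}

count_nonoverlapping <- function(s, kmer) {
  m <- gregexpr(kmer, s, fixed = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

frac_of <- function(chars, bases) {
  if (length(chars) == 0) return(0)
  mean(chars %in% bases)
}

#' Scan DNA sequence elements around the PAS
#'
#' Eight known polyadenylation sequence elements are scored 1/-1 in regions
#' placed relative to the PAS position (or, when no PAS was found, to a
#' neutral anchor just inside the bin): G-rich downstream, TTT
#' near-downstream, GT/TG downstream, GTGT/TGTG downstream, T-rich
#' immediately downstream, T-rich upstream, TGTA/TATA upstream, and AT-rich
#' across both flanks. Thresholds come from the [feature_config()].
#'
#' @param w A window from [build_window()].
#' @param pas_pos 0-based PAS offset from [scan_pas()], or `NA`.
#' @param config A [feature_config()].
#' @return Named numeric vector of 8 values in `{-1, 1}`.
#' @export
scan_elements <- function(w, pas_pos, config = feature_config()) {
  W <- nchar(w$seq)
  chars <- strsplit(w$seq, "", fixed = TRUE)[[1]]
  P <- if (is.na(pas_pos)) w$flank + config$neutral_anchor else pas_pos
  # 0-based half-open regions -> 1-based index ranges
  slice <- function(from0, to0) {
    if (to0 <= from0) return(character(0))
    chars[(from0 + 1):to0]
  }
  D <- slice(P + 6, min(P + 106, W))
  U <- slice(max(P - 100, 0), P)
  N <- slice(P + 6, min(P + 40, W))
  d_str <- paste(D, collapse = "")
  first30_D <- D[seq_len(min(30, length(D)))]
  last30_U <- if (length(U)) U[max(1, length(U) - 29):length(U)] else character(0)
  feats <- c(
    el_g_rich_down = count_nonoverlapping(d_str, "GGG") >= config$g_rich_min,
    el_ttt_near_down = count_nonoverlapping(paste(N, collapse = ""),
                                            "TTT") >= config$ttt_min,
    el_gt_down = count_kmer_overlapping(D, c("GT", "TG")) >= config$gt_min,
    el_gtgt_down = count_kmer_overlapping(D, c("GTGT", "TGTG")) >=
      config$gtgt_min,
    el_t_rich_down = frac_of(first30_D, "T") >= config$t_frac &&
      length(first30_D) > 0,
    el_t_rich_up = frac_of(last30_U, "T") >= config$t_frac &&
      length(last30_U) > 0,
    el_tgta_up = count_kmer_overlapping(U, c("TGTA", "TATA")) >=
      config$tgta_min,
    el_at_rich = frac_of(c(U, D), c("A", "T")) >= config$at_frac &&
      length(c(U, D)) > 0)
  ifelse(feats, 1, -1)
}

signed_ratio <- function(a, b) (a - b) / (a + b + 1)

rna_feature_block <- function(mU, mM, mD) {
  c(s_um = signed_ratio(mU, mM), s_md = signed_ratio(mM, mD),
    s_ud = signed_ratio(mU, mD), log_m = log1p(mM),
    dlog_um = log1p(mU) - log1p(mM), dlog_md = log1p(mM) - log1p(mD),
    drop = mD / (mU + 1))
}

#' RNA-Seq coverage features for a bin
#'
#' Fourteen bounded contrasts of median read depth over three regions in two
#' scenarios: intra-bin (the window's upstream flank, the bin, the
#' downstream flank) and inter-bin (the previous real bin, the current bin,
#' the next real bin along the region; a missing neighbour is a region of
#' zeros). Each scenario yields seven features built from the signed ratio
#' `s(a,b) = (a-b)/(a+b+1)` and `log1p` of the medians, all finite at zero
#' coverage.
#'
#' @param w A window from [build_window()].
#' @param inter_medians Numeric `c(prev, cur, next)` median depths of the
#'   neighbouring bins in transcription order.
#' @return Named numeric vector of 14 values.
#' @export
rna_features <- function(w, inter_medians = c(0, 0, 0)) {
  f <- w$flank
  b <- w$bin_size
  mU <- stats::median(w$cov[seq_len(f)])
  mM <- stats::median(w$cov[(f + 1):(f + b)])
  mD <- stats::median(w$cov[(f + b + 1):(f + b + f)])
  intra <- rna_feature_block(mU, mM, mD)
  inter <- rna_feature_block(inter_medians[1], inter_medians[2],
                             inter_medians[3])
  stats::setNames(c(intra, inter),
                  apa_feature_names()[RNA_FEATURE_IDX])
}

#' Annotation-end feature
#'
#' 1 iff the 3' stop of any source transcript of the region lies within the
#' bin's interval, else -1.
#' @param start,end The bin's genomic interval.
#' @param region The bin's [apa_region()].
#' @return 1 or -1.
#' @export
annot_end_feature <- function(start, end, region) {
  if (any(region$original_stops >= start & region$original_stops <= end))
    1 else -1
}

#' Compute the 27-feature matrix for bin sequences
#'
#' Fills each sequence's `features` slot with a `max_len x 27` matrix in the
#' frozen order (4 PAS, 8 elements, 14 RNA, 1 annotation-end); padded bins
#' hold zeros. Inter-bin coverage neighbours are resolved across chunk
#' boundaries of the same region.
#'
#' @param bin_seqs List of `apa_bins` from [bin_region()] or
#'   [prepare_bin_sequences()].
#' @param genome An `apa_genome`.
#' @param cov An `apa_coverage`.
#' @param config A [feature_config()].
#' @return The input list with `features` matrices filled in; the config is
#'   attached as attribute `"feature_config"`.
#' @export
featurize <- function(bin_seqs, genome, cov, config = feature_config()) {
  region_key <- vapply(bin_seqs, function(s)
    sprintf("%s:%s:%d-%d", s$chrom, s$strand, as.integer(s$region$start),
            as.integer(s$region$end)), "")
  # median depth of every real bin, per region, in transcription order
  med_by_region <- list()
  for (key in unique(region_key)) {
    chunks <- bin_seqs[region_key == key]
    chunks <- chunks[order(vapply(chunks, `[[`, 0, "chunk"))]
    meds <- unlist(lapply(chunks, function(s) {
      vapply(seq_len(s$n_real), function(i)
        stats::median(cov_depth(cov, s$chrom, s$strand,
                                s$start[i]:s$end[i])), 0)
    }))
    med_by_region[[key]] <- meds
  }
  chunk_offset <- integer(length(bin_seqs))
  for (key in unique(region_key)) {
    idx <- which(region_key == key)
    idx <- idx[order(vapply(bin_seqs[idx], `[[`, 0, "chunk"))]
    off <- 0L
    for (i in idx) {
      chunk_offset[i] <- off
      off <- off + bin_seqs[[i]]$n_real
    }
  }
  nm <- apa_feature_names()
  for (si in seq_along(bin_seqs)) {
    s <- bin_seqs[[si]]
    meds <- med_by_region[[region_key[si]]]
    fm <- matrix(0, nrow = s$max_len, ncol = 27,
                 dimnames = list(NULL, nm))
    for (i in seq_len(s$n_real)) {
      w <- build_window(s$chrom, s$strand, s$start[i], s$end[i], genome,
                        cov, config$flank)
      pas <- scan_pas(w, config)
      el <- scan_elements(w, pas$pas_pos, config)
      g <- chunk_offset[si] + i           # global bin index within region
      inter <- c(if (g > 1) meds[g - 1] else 0, meds[g],
                 if (g < length(meds)) meds[g + 1] else 0)
      rna <- rna_features(w, inter)
      fm[i, ] <- c(pas$features, el, rna,
                   annot_end = annot_end_feature(s$start[i], s$end[i],
                                                 s$region))
    }
    s$features <- fm
    bin_seqs[[si]] <- s
  }
  attr(bin_seqs, "feature_config") <- config
  bin_seqs
}

#' Dump a per-bin feature table
#'
#' One row per real bin: coordinates, the 27 features and the label (if
#' any). Useful for inspection or for training external classifiers.
#' @param bin_seqs Featurized `apa_bins` list.
#' @param path Optional TSV output path.
#' @return The table, invisibly if written to `path`.
#' @export
feature_table <- function(bin_seqs, path = NULL) {
  rows <- lapply(bin_seqs, function(s) {
    if (is.null(s$features)) stop_fmt("bin sequences are not featurized")
    i <- seq_len(s$n_real)
    data.frame(seq_id = s$seq_id, chrom = s$chrom,
               start = s$start[i], end = s$end[i], strand = s$strand,
               s$features[i, , drop = FALSE], label = s$label[i],
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
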