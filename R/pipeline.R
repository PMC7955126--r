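# End-to-end pipeline wrappers: train a model from FASTA + coverage + GTF +
# truth BED, and predict/integrate to produce the modified transcriptome.

resolve_coverage <- function(coverage, stranded, genome) {
  if (inherits(coverage, "apa_coverage")) return(coverage)
  load_coverage(coverage, stranded = stranded,
                chrom_lengths = genome$lengths)
}

#' Train a polyA-site model from files
#'
#' Full training flow: read genome, coverage, transcripts and truth sites;
#' isolate/extend/refine terminal exons; merge overlapping regions; bin,
#' label and featurize; fit the classifier with a region-level 60/20/20
#' split; and write the model bundle, the training log and the held-out
#' test evaluation report.
#'
#' @param fasta Genome FASTA path.
#' @param coverage BAM path, bedGraph path(s) (see [load_coverage()]), or an
#'   `apa_coverage`.
#' @param gtf Transcriptome GTF path.
#' @param truth Truth polyA-site BED path (or `apa_sites`).
#' @param out_dir Output directory for `model.json`,
#'   `training_log.tsv` and `eval_report.json` (NULL = don't write).
#' @param stranded Is the coverage stranded?
#' @param config An [apa_model_config()].
#' @param feature_cfg A [feature_config()].
#' @param min_abs_cov,frac Refinement parameters, see [refine_region()].
#' @return List with `model` (an `apa_model`), `report` (test-set
#'   `apa_eval`), and `paths`.
#' @export
run_train <- function(fasta, coverage, gtf, truth, out_dir = NULL,
                      stranded = FALSE, config = apa_model_config(),
                      feature_cfg = feature_config(), min_abs_cov = 5,
                      frac = 0.05) {
  genome <- if (inherits(fasta, "apa_genome")) fasta else read_fasta(fasta)
  cov <- resolve_coverage(coverage, stranded, genome)
  txs <- if (is.list(gtf) && !is.character(gtf)) gtf else read_gtf(gtf)
  sites <- if (inherits(truth, "apa_sites")) truth else read_polya_bed(truth)
  apa_log("training on %d transcripts, %d truth sites", length(txs),
          nrow(sites))
  bins <- prepare_bin_sequences(txs, genome, cov, labels = sites,
                                merge = TRUE, bin_size = config$bin_size,
                                max_len = config$max_len,
                                min_abs_cov = min_abs_cov, frac = frac)
  bins <- featurize(bins, genome, cov, feature_cfg)
  model <- apa_fit(bins, config)
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$model <- file.path(out_dir, "model.json")
    save_apa_model(model, paths$model)
    if (!is.null(model$history)) {
      paths$log <- file.path(out_dir, "training_log.tsv")
      utils::write.table(model$history, paths$log, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(model$test_eval)) {
      paths$report <- file.path(out_dir, "eval_report.json")
      te <- model$test_eval
      jsonlite::write_json(list(counts = as.list(te$counts), P = te$P,
                                R = te$R, F = te$F, AP = te$AP,
                                threshold = te$threshold,
                                n_bins = te$n_bins,
                                prevalence = te$prevalence),
                           paths$report, auto_unbox = TRUE, digits = NA)
    }
  }
  list(model = model, report = model$test_eval, paths = paths)
}

#' Predict polyA sites and emit the modified transcriptome
#'
#' Full prediction flow: per-transcript (unmerged) terminal regions are
#' binned and featurized, the model scores every real bin, positive bins
#' become new 3' stops (subject to the two suppression rules, see
#' [place_sites()]), and the modified transcriptome — all original
#' transcripts plus the added isoforms — is written as GTF.
#'
#' @param fasta Genome FASTA path (or `apa_genome`).
#' @param coverage Coverage input, as in [run_train()].
#' @param gtf Transcriptome GTF path (or transcript list).
#' @param model An `apa_model` or a model bundle path.
#' @param out_gtf Optional output GTF path; a placement summary TSV is
#'   written next to it.
#' @param stranded Is the coverage stranded?
#' @param threshold Probability call threshold (default: the model's).
#' @param suppress_dist Rule-(2) distance, bases.
#' @param dedup_across_isoforms See [build_modified_transcriptome()].
#' @param min_abs_cov,frac Refinement parameters.
#' @return List with `transcripts` (modified transcriptome), `placements`,
#'   `predictions` and `paths`.
#' @export
run_predict <- function(fasta, coverage, gtf, model, out_gtf = NULL,
                        stranded = FALSE, threshold = NULL,
                        suppress_dist = 100,
                        dedup_across_isoforms = FALSE, min_abs_cov = 5,
                        frac = 0.05) {
  if (is.character(model)) model <- load_apa_model(model)
  genome <- if (inherits(fasta, "apa_genome")) fasta else read_fasta(fasta)
  cov <- resolve_coverage(coverage, stranded, genome)
  txs <- if (is.list(gtf) && !is.character(gtf)) gtf else read_gtf(gtf)
  bins <- prepare_bin_sequences(txs, genome, cov, labels = NULL,
                                merge = FALSE, bin_size = model$bin_size,
                                max_len = model$max_len,
                                min_abs_cov = min_abs_cov, frac = frac)
  bins <- featurize(bins, genome, cov, model$feature_config)
  preds <- predict(model, bins,
                   threshold = threshold %||% model$config$threshold)
  seq_tx <- stats::setNames(
    vapply(bins, function(s) s$region$source_transcript_ids[1], ""),
    vapply(bins, `[[`, "", "seq_id"))
  regions <- attr(bins, "regions")
  placements <- do.call(rbind, lapply(names(txs), function(id) {
    pr <- preds[seq_tx[preds$seq_id] == id, , drop = FALSE]
    place_sites(pr, regions[[id]], txs[[id]], suppress_dist)
  }))
  modified <- build_modified_transcriptome(txs, placements,
                                           dedup_across_isoforms)
  apa_log("added %d isoform(s) to %d transcripts",
          length(modified) - length(txs), length(txs))
  paths <- list()
  if (!is.null(out_gtf)) {
    write_gtf(modified, out_gtf)
    paths$gtf <- out_gtf
    paths$summary <- paste0(sub("\\.gtf$", "", out_gtf), "_sites.tsv")
    placement_summary(placements, paths$summary)
  }
  list(transcripts = modified, placements = placements,
       predictions = preds, paths = paths)
}
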