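# Model fitting: region-level data splits, training-set standardization,
# the biLSTM sequence classifier (plus flat random-forest / logistic
# comparator heads), and the `apa_model` S3 interface.

#' Model configuration
#'
#' Tunable training parameters with the pipeline defaults: a bidirectional
#' LSTM of 20 units per direction trained for 25 epochs with Adam on masked,
#' class-weighted binary cross entropy; 60/20/20 region-level splits; bin
#' calls at probability 0.5.
#'
#' @param hidden Hidden units per LSTM direction.
#' @param epochs Training epochs; the minimum-validation-loss epoch's
#'   weights are kept.
#' @param threshold Probability call threshold, in (0, 1).
#' @param split_fractions Train/validation/test fractions (sum to 1).
#' @param seed Integer seed for the split, weight init and batch order.
#' @param bin_size,max_len Bin width (bases) and sequence length (bins);
#'   must match the featurized input.
#' @param class_weighting `"inverse_frequency"` (weights `N/(2 N_class)`
#'   over real training bins) or `"none"`.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size (sequences).
#' @param engine `"bilstm"`, `"random_forest"` or `"linear"`. The flat
#'   engines drop sequence context and act as fast baselines.
#' @param feature_subset `NULL` for all 27 features, `"dna_only"` (the 12
#'   sequence features), `"rna_only"` (the 14 coverage features), or an
#'   integer vector of feature columns.
#' @return An `apa_model_config` list.
#' @export
apa_model_config <- function(hidden = 20, epochs = 25, threshold = 0.5,
                             split_fractions = c(0.6, 0.2, 0.2), seed = 1,
                             bin_size = 100, max_len = 300,
                             class_weighting = c("inverse_frequency",
                                                 "none"),
                             lr = 0.02, batch_size = 32,
                             engine = c("bilstm", "random_forest",
                                        "linear"),
                             feature_subset = NULL) {
  stopifnot(abs(sum(split_fractions) - 1) < 1e-8,
            threshold > 0, threshold < 1)
  structure(list(hidden = hidden, epochs = epochs, threshold = threshold,
                 split_fractions = split_fractions, seed = seed,
                 bin_size = bin_size, max_len = max_len,
                 class_weighting = match.arg(class_weighting), lr = lr,
                 batch_size = batch_size, engine = match.arg(engine),
                 feature_subset = feature_subset),
            class = "apa_model_config")
}

resolve_feature_subset <- function(subset) {
  if (is.null(subset)) return(1:27)
  if (is.character(subset)) {
    switch(subset,
           dna_only = 1:12,
           rna_only = RNA_FEATURE_IDX,
           stop_fmt("unknown feature subset '%s'", subset))
  } else as.integer(subset)
}

#' Split bin sequences into train/validation/test sets
#'
#' Splits at the region level — all chunks of one (merged) region land in
#' the same set — reproducibly under the seed.
#'
#' @param bin_seqs List of labelled `apa_bins`.
#' @param fractions Train/validation/test fractions.
#' @param seed Integer seed.
#' @return List with elements `train`, `val`, `test`.
#' @export
split_data <- function(bin_seqs, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  keys <- vapply(bin_seqs, function(s)
    sprintf("%s:%s:%d-%d", s$chrom, s$strand, as.integer(s$region$start),
            as.integer(s$region$end)), "")
  regions <- unique(keys)
  R <- length(regions)
  if (R < 3) stop_fmt("need at least 3 regions to split, got %d", R)
  n_tr <- max(1L, round(fractions[1] * R))
  n_va <- max(1L, round(fractions[2] * R))
  if (n_tr + n_va >= R) n_tr <- R - n_va - 1L
  shuffled <- with_seed(seed, sample(regions))
  assign_set <- rep("test", R)
  assign_set[seq_len(n_tr)] <- "train"
  assign_set[(n_tr + 1):(n_tr + n_va)] <- "val"
  names(assign_set) <- shuffled
  fc <- attr(bin_seqs, "feature_config")
  out <- list(train = bin_seqs[assign_set[keys] == "train"],
              val = bin_seqs[assign_set[keys] == "val"],
              test = bin_seqs[assign_set[keys] == "test"])
  lapply(out, function(s) { attr(s, "feature_config") <- fc; s })
}

#' Standardize quantitative features
#'
#' Z-scores the 14 RNA coverage features using mean/sd computed over real
#' bins (of the training set when `stats = NULL` is fit there); binary
#' features are untouched; a zero-sd feature is centered and left at 0.
#' Padded bins stay all-zero.
#'
#' @param bin_seqs Featurized `apa_bins` list.
#' @param stats `NULL` to compute stats from `bin_seqs`, or the `stats`
#'   element of a previous call (e.g. training-set stats applied to
#'   validation/test data).
#' @return List with `seqs` (transformed) and `stats` (`mean`, `sd`).
#' @export
standardize_features <- function(bin_seqs, stats = NULL) {
  if (is.null(stats)) {
    rows <- do.call(rbind, lapply(bin_seqs, function(s)
      s$features[s$mask, RNA_FEATURE_IDX, drop = FALSE]))
    mu <- colMeans(rows)
    sd <- apply(rows, 2, stats::sd)
    stats <- list(mean = mu, sd = sd)
  }
  div <- ifelse(stats$sd == 0 | is.na(stats$sd), 1, stats$sd)
  seqs <- lapply(bin_seqs, function(s) {
    f <- s$features
    f[s$mask, RNA_FEATURE_IDX] <-
      sweep(sweep(f[s$mask, RNA_FEATURE_IDX, drop = FALSE], 2, stats$mean),
            2, div, "/")
    s$features <- f
    s
  })
  attributes(seqs) <- attributes(bin_seqs)
  list(seqs = seqs, stats = stats)
}

# Stack sequences into N x T x D / N x T arrays for the recurrent engine.
seqs_to_arrays <- function(bin_seqs, feature_idx = 1:27) {
  N <- length(bin_seqs)
  Tn <- bin_seqs[[1]]$max_len
  D <- length(feature_idx)
  X <- array(0, dim = c(N, Tn, D))
  Y <- matrix(0, N, Tn)
  M <- matrix(0, N, Tn)
  for (i in seq_len(N)) {
    s <- bin_seqs[[i]]
    X[i, , ] <- s$features[, feature_idx, drop = FALSE]
    lab <- s$label
    lab[is.na(lab)] <- 0L
    Y[i, ] <- lab
    M[i, ] <- as.numeric(s$mask)
  }
  list(X = X, Y = Y, M = M)
}

# Flat per-bin rows (sequence context dropped) for the comparator engines.
seqs_to_rows <- function(bin_seqs, feature_idx = 1:27) {
  x <- do.call(rbind, lapply(bin_seqs, function(s)
    s$features[s$mask, feature_idx, drop = FALSE]))
  y <- unlist(lapply(bin_seqs, function(s) s$label[s$mask]))
  list(x = x, y = y)
}

compute_class_weights <- function(labels, scheme) {
  n <- length(labels)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  if (n1 == 0 || n0 == 0)
    stop_fmt("training labels are all one class (%d positives of %d)",
             n1, n)
  if (scheme == "none") c(`0` = 1, `1` = 1)
  else c(`0` = n / (2 * n0), `1` = n / (2 * n1))
}

#' Fit the polyA-site bin classifier
#'
#' The central fitting function: splits labelled, featurized bin sequences
#' at the region level, standardizes the quantitative features with
#' training-set statistics, and trains the classifier — by default the
#' bidirectional LSTM sequence labeller with class-weighted masked binary
#' cross entropy, keeping the minimum-validation-loss epoch. Flat
#' random-forest and logistic engines are available as baselines sharing
#' the same prediction interface.
#'
#' @param bin_seqs Labelled, featurized `apa_bins` list (merged regions).
#' @param config An [apa_model_config()].
#' @param splits Optional pre-made [split_data()] result (overrides the
#'   config's fractions/seed split).
#' @return An `apa_model` object; see [predict.apa_model()],
#'   [summary.apa_model()], [plot.apa_model()].
#' @export
apa_fit <- function(bin_seqs, config = apa_model_config(), splits = NULL) {
  fc <- attr(bin_seqs, "feature_config") %||% feature_config()
  if (any(vapply(bin_seqs, function(s) is.null(s$features), TRUE)))
    stop_fmt("bin sequences are not featurized")
  if (any(vapply(bin_seqs, function(s) all(is.na(s$label[s$mask])), TRUE)))
    stop_fmt("bin sequences are not labelled")
  if (bin_seqs[[1]]$bin_size != config$bin_size ||
      bin_seqs[[1]]$max_len != config$max_len)
    stop_fmt("bin_size/max_len of data (%d/%d) and config (%d/%d) differ",
             bin_seqs[[1]]$bin_size, bin_seqs[[1]]$max_len,
             config$bin_size, config$max_len)
  if (is.null(splits))
    splits <- split_data(bin_seqs, config$split_fractions, config$seed)
  std <- standardize_features(splits$train)
  train <- std$seqs
  val <- standardize_features(splits$val, std$stats)$seqs
  test <- standardize_features(splits$test, std$stats)$seqs
  fidx <- resolve_feature_subset(config$feature_subset)
  cw <- compute_class_weights(unlist(lapply(train, function(s)
    s$label[s$mask])), config$class_weighting)
  fit <- switch(config$engine,
    bilstm = {
      tr <- seqs_to_arrays(train, fidx)
      va <- seqs_to_arrays(val, fidx)
      train_bilstm(tr$X, tr$Y, tr$M, va$X, va$Y, va$M,
                   hidden = config$hidden, epochs = config$epochs,
                   batch_size = config$batch_size, lr = config$lr,
                   class_weights = cw, seed = config$seed)
    },
    random_forest = {
      tr <- seqs_to_rows(train, fidx)
      rf <- with_seed(config$seed,
        randomForest::randomForest(x = tr$x, y = factor(tr$y,
                                                        levels = c(0, 1)),
                                   ntree = 200,
                                   classwt = cw / sum(cw)))
      list(params = rf, best_epoch = NA, val_loss = NA, history = NULL)
    },
    linear = {
      tr <- seqs_to_rows(train, fidx)
      w <- ifelse(tr$y == 1, cw[["1"]], cw[["0"]])
      gl <- suppressWarnings(
        stats::glm.fit(cbind(1, tr$x), tr$y, weights = w,
                       family = stats::binomial()))
      cf <- gl$coefficients
      cf[is.na(cf)] <- 0              # aliased (constant) columns drop out
      list(params = cf, best_epoch = NA, val_loss = NA, history = NULL)
    })
  model <- structure(list(
    engine = config$engine, params = fit$params, config = config,
    standardization = std$stats, feature_idx = fidx,
    feature_config_hash = fnv1a_hash(unclass(fc)),
    feature_config = fc, bin_size = config$bin_size,
    max_len = config$max_len, class_weights = cw,
    best_epoch = fit$best_epoch, val_loss = fit$val_loss,
    history = fit$history,
    n_sequences = vapply(splits, length, 0L)), class = "apa_model")
  model$test_eval <- if (length(test) > 0) {
    pr <- predict(model, test, standardized = TRUE)
    tryCatch(eval_report(pr$prob, pr$label, threshold = config$threshold),
             error = function(e) NULL)
  } else NULL
  model
}

#' Predict polyA-site probabilities for bin sequences
#'
#' Applies the model's stored training-set standardization, runs the
#' classifier, and returns one row per real bin with the predicted
#' probability and the thresholded call. Refuses inputs whose feature
#' configuration, bin size or sequence length disagree with the model.
#'
#' @param object An `apa_model`.
#' @param bin_seqs Featurized `apa_bins` list (per-transcript, unmerged, for
#'   prediction).
#' @param threshold Probability call threshold; defaults to the model's.
#' @param standardized Internal: set when `bin_seqs` are already
#'   standardized with the model's stats.
#' @param ... Unused.
#' @return A data frame (`apa_predictions`) with columns `seq_id`, `chrom`,
#'   `strand`, `start`, `end`, `prob`, `call` and `label` (NA when
#'   unlabelled).
#' @export
predict.apa_model <- function(object, bin_seqs,
                              threshold = object$config$threshold,
                              standardized = FALSE, ...) {
  if (length(bin_seqs) == 0) stop_fmt("no bin sequences to predict on")
  fc <- attr(bin_seqs, "feature_config") %||% feature_config()
  if (!identical(fnv1a_hash(unclass(fc)), object$feature_config_hash))
    stop_fmt("feature configuration of the input does not match the model")
  if (bin_seqs[[1]]$bin_size != object$bin_size ||
      bin_seqs[[1]]$max_len != object$max_len)
    stop_fmt("bin_size/max_len mismatch with the model")
  if (!standardized)
    bin_seqs <- standardize_features(bin_seqs, object$standardization)$seqs
  probs <- switch(object$engine,
    bilstm = {
      arr <- seqs_to_arrays(bin_seqs, object$feature_idx)
      fwd <- bilstm_forward(object$params, arr$X, arr$M)
      lapply(seq_along(bin_seqs), function(i)
        fwd$prob[i, seq_len(bin_seqs[[i]]$n_real)])
    },
    random_forest = {
      rows <- seqs_to_rows(bin_seqs, object$feature_idx)
      p <- stats::predict(object$params, rows$x, type = "prob")[, "1"]
      split_by_seq(p, bin_seqs)
    },
    linear = {
      rows <- seqs_to_rows(bin_seqs, object$feature_idx)
      p <- sigmoid(cbind(1, rows$x) %*% object$params)[, 1]
      split_by_seq(p, bin_seqs)
    })
  out <- do.call(rbind, lapply(seq_along(bin_seqs), function(i) {
    s <- bin_seqs[[i]]
    j <- seq_len(s$n_real)
    data.frame(seq_id = s$seq_id, chrom = s$chrom, strand = s$strand,
               start = s$start[j], end = s$end[j], prob = probs[[i]],
               call = if (threshold >= 1) 0L else
                 as.integer(probs[[i]] >= threshold),
               label = s$label[j], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("apa_predictions", "data.frame")
  out
}

split_by_seq <- function(flat, bin_seqs) {
  ns <- vapply(bin_seqs, `[[`, 0L, "n_real")
  split(flat, rep(seq_along(bin_seqs), ns))
}

#' @export
print.apa_model <- function(x, ...) {
  cat(sprintf("apa_model (%s engine)\n", x$engine))
  cat(sprintf("  features: %d of 27 (config %s); bin %d bases, %d bins/seq\n",
              length(x$feature_idx), x$feature_config_hash, x$bin_size,
              x$max_len))
  cat(sprintf("  sequences: %d train / %d val / %d test\n",
              x$n_sequences[["train"]], x$n_sequences[["val"]],
              x$n_sequences[["test"]]))
  if (x$engine == "bilstm")
    cat(sprintf("  best epoch %d (val loss %.4f) of %d\n", x$best_epoch,
                x$val_loss, x$config$epochs))
  if (!is.null(x$test_eval))
    cat(sprintf("  test: P %.3f R %.3f F %.3f AP %.3f\n", x$test_eval$P,
                x$test_eval$R, x$test_eval$F, x$test_eval$AP))
  invisible(x)
}

#' @export
summary.apa_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  if (!is.null(object$test_eval)) {
    cat("\nHeld-out test set:\n")
    print(object$test_eval)
  }
  invisible(object)
}

#' Plot training curves
#' @param x An `apa_model` with a training history.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.apa_model <- function(x, ...) {
  if (is.null(x$history)) stop_fmt("model has no training history")
  graphics::matplot(x$history$epoch,
                    cbind(x$history$loss, x$history$val_loss),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' @export
coef.apa_model <- function(object, ...) {
  switch(object$engine,
         bilstm = flatten_params(object$params),
         linear = object$params,
         random_forest = object$params$importance)
}

## ---- persistence ------------------------------------------------------

#' Save / load a trained model bundle
#'
#' Persists a biLSTM model as a single JSON bundle: weights, feature order
#' and configuration hash, bin size, sequence length, standardization stats
#' and the training seed. Only the `bilstm` engine is serializable this way;
#' the comparator engines are session objects.
#'
#' @param model An `apa_model` with `engine == "bilstm"`.
#' @param path Output / input path.
#' @return `save_apa_model` the path, invisibly; `load_apa_model` the
#'   restored `apa_model`.
#' @export
save_apa_model <- function(model, path) {
  if (model$engine != "bilstm")
    stop_fmt("only bilstm models are saved as bundles")
  bundle <- list(
    format = "apatail-model-1",
    engine = model$engine,
    config = unclass(model$config),
    feature_idx = model$feature_idx,
    feature_config_hash = model$feature_config_hash,
    feature_config = unclass(model$feature_config),
    bin_size = model$bin_size, max_len = model$max_len,
    standardization = model$standardization,
    class_weights = as.list(model$class_weights),
    best_epoch = model$best_epoch, val_loss = model$val_loss,
    weights = lapply(flatten_params(model$params), function(w)
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
      else list(dim = length(w), data = as.numeric(w))))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_apa_model
#' @export
load_apa_model <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(b$format, "apatail-model-1"))
    stop_fmt("%s is not an apatail model bundle", path)
  wf <- lapply(b$weights, function(w) {
    if (length(w$dim) == 2) matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  hidden <- b$config$hidden
  params <- list(
    fwd = list(Wx = wf$fwd.Wx, Wh = wf$fwd.Wh, b = wf$fwd.b),
    bwd = list(Wx = wf$bwd.Wx, Wh = wf$bwd.Wh, b = wf$bwd.b),
    Wy = wf$Wy, by = wf$by, hidden = hidden,
    input_dim = nrow(wf$fwd.Wx))
  cfgv <- b$config
  config <- apa_model_config(hidden = cfgv$hidden, epochs = cfgv$epochs,
                             threshold = cfgv$threshold,
                             split_fractions = cfgv$split_fractions,
                             seed = cfgv$seed, bin_size = cfgv$bin_size,
                             max_len = cfgv$max_len,
                             class_weighting = cfgv$class_weighting,
                             lr = cfgv$lr, batch_size = cfgv$batch_size,
                             engine = cfgv$engine,
                             feature_subset = cfgv$feature_subset)
  fc <- b$feature_config
  fc$hexamers$minor <- as.character(fc$hexamers$minor)
  fcfg <- do.call(feature_config,
                  fc[setdiff(names(fc), c("hexamers", "feature_names"))])
  structure(list(engine = "bilstm", params = params, config = config,
                 standardization = list(
                   mean = unlist(b$standardization$mean),
                   sd = unlist(b$standardization$sd)),
                 feature_idx = as.integer(b$feature_idx),
                 feature_config_hash = b$feature_config_hash,
                 feature_config = fcfg, bin_size = b$bin_size,
                 max_len = b$max_len,
                 class_weights = unlist(b$class_weights),
                 best_epoch = b$best_epoch, val_loss = b$val_loss,
                 history = NULL,
                 n_sequences = c(train = NA, val = NA, test = NA)),
            class = "apa_model")
}
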