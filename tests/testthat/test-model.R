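# fabricate n tiny labelled/featurized single-chunk sequences, one region
# each, with planted separability for the engine tests
fake_seqs <- function(n_regions = 10, n_real = 8, max_len = 12, seed = 1) {
  apatail:::with_seed(seed, {
    out <- lapply(seq_len(n_regions), function(i) {
      start0 <- (i - 1) * 10000 + 1
      r <- apa_region("chr1", "+", start0, start0 + n_real * 100 - 1,
                      paste0("t", i), start0)
      s <- bin_region(r, 100, max_len)[[1]]
      lab <- rep(NA_integer_, max_len)
      lab[seq_len(n_real)] <- rbinom(n_real, 1, 0.25)
      if (i == 1) lab[1] <- 1               # guarantee both classes
      if (i == 2) lab[1] <- 0
      s$label <- lab
      fm <- matrix(0, max_len, 27)
      fm[seq_len(n_real), 1:12] <- sample(c(-1, 1), n_real * 12,
                                          replace = TRUE)
      fm[seq_len(n_real), 27] <- -1
      fm[seq_len(n_real), 13:26] <- rnorm(n_real * 14)
      # make the signal learnable: feature 13 tracks the label
      fm[seq_len(n_real), 13] <- lab[seq_len(n_real)] * 3 +
        rnorm(n_real, sd = 0.2)
      fm[seq_len(n_real), 1] <- ifelse(lab[seq_len(n_real)] == 1, 1, -1)
      s$features <- fm
      s
    })
    attr(out, "feature_config") <- feature_config()
    out
  })
}

test_that("splits are region-level, reproducible and disjoint", {
  seqs <- fake_seqs(10)
  sp <- split_data(seqs, c(0.6, 0.2, 0.2), seed = 4)
  expect_equal(vapply(sp, length, 0L), c(train = 6L, val = 2L, test = 2L))
  sp2 <- split_data(seqs, c(0.6, 0.2, 0.2), seed = 4)
  expect_identical(lapply(sp, function(x) vapply(x, `[[`, "", "seq_id")),
                   lapply(sp2, function(x) vapply(x, `[[`, "", "seq_id")))
  for (seed in 1:50) {
    spx <- split_data(seqs, c(0.6, 0.2, 0.2), seed = seed)
    ids <- unlist(lapply(spx, function(x) vapply(x, `[[`, "", "seq_id")))
    expect_setequal(ids, vapply(seqs, `[[`, "", "seq_id"))
    expect_equal(anyDuplicated(ids), 0L)
  }
  # a multi-chunk region never straddles sets
  long <- bin_region(apa_region("chr1", "+", 1, 70000, "tL", 5), 100, 300)
  both <- c(seqs, long)
  spl <- split_data(both, seed = 2)
  where <- vapply(spl, function(x)
    sum(grepl("tL|1-70000", vapply(x, `[[`, "", "seq_id"))), 0)
  expect_equal(sum(where > 0), 1)
  expect_error(split_data(seqs[1], seed = 1), "at least 3")
})

test_that("standardization uses training stats only, on real bins only", {
  seqs <- fake_seqs(8)
  std <- standardize_features(seqs)
  rows <- do.call(rbind, lapply(std$seqs, function(s)
    s$features[s$mask, 13:26, drop = FALSE]))
  expect_equal(unname(colMeans(rows)), rep(0, 14), tolerance = 1e-12)
  expect_equal(unname(apply(rows, 2, sd)), rep(1, 14), tolerance = 1e-12)
  # padded bins stay zero; binary features untouched
  for (i in seq_along(seqs)) {
    expect_true(all(std$seqs[[i]]$features[!seqs[[i]]$mask, ] == 0))
    expect_equal(std$seqs[[i]]$features[, 1:12], seqs[[i]]$features[, 1:12])
  }
  # constant feature: centered to all zeros
  cseqs <- lapply(seqs, function(s) { s$features[s$mask, 20] <- 5; s })
  cstd <- standardize_features(cseqs)
  expect_true(all(vapply(cstd$seqs, function(s)
    all(s$features[s$mask, 20] == 0), TRUE)))
  # applying train stats to other data differs from its own z-scores
  other <- fake_seqs(8, seed = 9)
  with_train <- standardize_features(other, std$stats)$seqs
  own <- standardize_features(other)$seqs
  expect_false(isTRUE(all.equal(with_train[[1]]$features[1, 13:26],
                                own[[1]]$features[1, 13:26])))
  expect_false(isTRUE(all.equal(unname(std$stats$mean),
                                unname(standardize_features(other)$stats$mean))))
})

test_that("inverse-frequency class weights follow N/(2 N_class)", {
  labs <- c(rep(1, 2), rep(0, 18))
  w <- apatail:::compute_class_weights(labs, "inverse_frequency")
  expect_equal(w[["1"]], 20 / (2 * 2))
  expect_equal(w[["0"]], 20 / (2 * 18))
  expect_equal(apatail:::compute_class_weights(labs, "none"),
               c(`0` = 1, `1` = 1))
  expect_error(apatail:::compute_class_weights(rep(1, 5),
                                               "inverse_frequency"),
               "one class")
})

test_that("biLSTM gradients agree with finite differences", {
  set.seed(7)
  N <- 3; Tn <- 6; D <- 4; H <- 3
  p <- apatail:::bilstm_init(D, H, seed = 3)
  X <- array(rnorm(N * Tn * D), c(N, Tn, D))
  M <- matrix(1, N, Tn); M[1, 5:6] <- 0; M[3, 6] <- 0
  X[1, 5:6, ] <- 0; X[3, 6, ] <- 0
  Y <- matrix(rbinom(N * Tn, 1, 0.4), N, Tn) * M
  cw <- c(`0` = 0.7, `1` = 2.1)
  g <- apatail:::bilstm_grad(p, X, Y, M, cw)
  fl <- apatail:::flatten_params(p)
  gfl <- apatail:::flatten_params(g$grads)
  eps <- 1e-5
  loss_at <- function(flat) {
    pp <- apatail:::unflatten_into(p, flat)
    apatail:::bce_loss(apatail:::bilstm_forward(pp, X, M)$prob, Y, M, cw)
  }
  for (k in names(fl)) {
    for (i in seq_len(min(5, length(fl[[k]])))) {
      up <- fl; up[[k]][i] <- up[[k]][i] + eps
      dn <- fl; dn[[k]][i] <- dn[[k]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(gfl[[k]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("padded tails never influence training (masking correctness)", {
  set.seed(13)
  N <- 6; Tn <- 10; D <- 5
  X <- array(rnorm(N * Tn * D), c(N, Tn, D))
  M <- matrix(1, N, Tn); M[, 9:10] <- 0; X[, 9:10, ] <- 0
  Y <- matrix(rbinom(N * Tn, 1, 0.3), N, Tn) * M
  grow <- function(A, extra) {
    if (length(dim(A)) == 3) {
      out <- array(0, c(N, Tn + extra, dim(A)[3]))
      out[, 1:Tn, ] <- A
      out
    } else {
      m <- matrix(0, N, Tn + extra)
      m[, 1:Tn] <- A
      m
    }
  }
  fit1 <- apatail:::train_bilstm(X, Y, M, X, Y, M, hidden = 4, epochs = 3,
                                 batch_size = 3, lr = 0.01, seed = 5)
  X2 <- grow(X, 7); M2 <- grow(M, 7); Y2 <- grow(Y, 7)
  fit2 <- apatail:::train_bilstm(X2, Y2, M2, X2, Y2, M2, hidden = 4,
                                 epochs = 3, batch_size = 3, lr = 0.01,
                                 seed = 5)
  expect_equal(fit1$history$loss, fit2$history$loss, tolerance = 1e-10)
  expect_equal(fit1$history$val_loss, fit2$history$val_loss,
               tolerance = 1e-10)
})

test_that("checkpointing keeps the minimum-validation-loss weights", {
  seqs <- fake_seqs(12, seed = 2)
  m <- apa_fit(seqs, apa_model_config(hidden = 4, epochs = 6,
                                      max_len = 12, batch_size = 4,
                                      seed = 3))
  expect_equal(m$val_loss, min(m$history$val_loss))
  expect_lte(m$val_loss, m$history$val_loss[nrow(m$history)])
  expect_equal(m$best_epoch, which.min(m$history$val_loss))
})

test_that("prediction is deterministic and respects threshold edges", {
  seqs <- fake_seqs(12, seed = 2)
  m <- apa_fit(seqs, apa_model_config(hidden = 4, epochs = 4,
                                      max_len = 12, batch_size = 4,
                                      seed = 3))
  p1 <- predict(m, seqs)
  p2 <- predict(m, seqs)
  expect_identical(p1$prob, p2$prob)
  expect_equal(nrow(p1), sum(vapply(seqs, `[[`, 0L, "n_real")))
  expect_true(all(p1$prob >= 0 & p1$prob <= 1))
  expect_true(all(predict(m, seqs, threshold = 0)$call == 1))
  expect_true(all(predict(m, seqs, threshold = 1)$call == 0))
})

test_that("models refuse mismatched feature configurations", {
  seqs <- fake_seqs(12, seed = 2)
  m <- apa_fit(seqs, apa_model_config(hidden = 4, epochs = 2,
                                      max_len = 12, seed = 3))
  other <- seqs
  attr(other, "feature_config") <- feature_config(pas_upstream = 30)
  expect_error(predict(m, other), "feature configuration")
  shrunk <- lapply(seqs, function(s) {
    s$max_len <- 6
    for (f in c("start", "end", "label", "mask"))
      s[[f]] <- s[[f]][1:6]
    s$n_real <- min(s$n_real, 6)
    s$features <- s$features[1:6, , drop = FALSE]
    s
  })
  attr(shrunk, "feature_config") <- feature_config()
  expect_error(predict(m, shrunk), "max_len")
})

test_that("model bundles survive a save/load round trip", {
  seqs <- fake_seqs(12, seed = 2)
  m <- apa_fit(seqs, apa_model_config(hidden = 4, epochs = 3,
                                      max_len = 12, seed = 3))
  path <- tempfile(fileext = ".json")
  save_apa_model(m, path)
  m2 <- load_apa_model(path)
  expect_equal(predict(m2, seqs)$prob, predict(m, seqs)$prob,
               tolerance = 1e-12)
  expect_equal(m2$feature_config_hash, m$feature_config_hash)
  # the reloaded bundle's reconstructed feature config re-hashes identically
  # (featurizing fresh data with it must not trip the mismatch guard)
  expect_equal(apatail:::fnv1a_hash(unclass(m2$feature_config)),
               m2$feature_config_hash)
  expect_equal(m2$standardization$mean, m$standardization$mean,
               tolerance = 1e-12)
  junk <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), junk, auto_unbox = TRUE)
  expect_error(load_apa_model(junk), "bundle")
})

test_that("flat comparator engines share the prediction interface", {
  seqs <- fake_seqs(20, n_real = 10, max_len = 12, seed = 6)
  for (engine in c("random_forest", "linear")) {
    m <- apa_fit(seqs, apa_model_config(engine = engine, max_len = 12,
                                        seed = 3))
    pr <- predict(m, seqs)
    expect_s3_class(pr, "apa_predictions")
    expect_true(all(pr$prob >= 0 & pr$prob <= 1))
    expect_true(all(pr$call %in% 0:1))
    # learnable planted signal: clearly better than chance
    ev <- eval_report(pr$prob, pr$label)
    expect_gt(ev$AP, ev$prevalence)
  }
})

test_that("training errors on unlabelled or one-class input", {
  seqs <- fake_seqs(10)
  none <- lapply(seqs, function(s) { s$label[] <- NA_integer_; s })
  attr(none, "feature_config") <- feature_config()
  expect_error(apa_fit(none, apa_model_config(max_len = 12)), "labelled")
  zeros <- lapply(seqs, function(s) {
    s$label[s$mask] <- 0L
    s
  })
  attr(zeros, "feature_config") <- feature_config()
  expect_error(apa_fit(zeros, apa_model_config(max_len = 12, seed = 1)),
               "one class")
})
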