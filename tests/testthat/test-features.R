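plant <- function(base, motif, offset0) {
  # place motif at 0-based window offset in a character template
  v <- strsplit(base, "", fixed = TRUE)[[1]]
  v[(offset0 + 1):(offset0 + nchar(motif))] <- strsplit(motif, "")[[1]]
  paste(v, collapse = "")
}
polyC <- strrep("C", 300)

test_that("windows are oriented 5'->3' along the transcript strand", {
  g <- make_genome(c(chr1 = paste(rep(c("A", "C", "G", "T"), 125),
                                  collapse = "")))
  v <- seq_len(500)
  cov <- make_coverage(list(chr1 = as.numeric(v)), c(chr1 = 500))
  w <- build_window("chr1", "+", 201, 300, g, cov)
  expect_equal(w$seq, genome_fetch(g, "chr1", 101, 400))
  expect_equal(w$cov, as.numeric(101:400))
  wm <- build_window("chr1", "-", 201, 300, g, cov)
  expect_equal(wm$seq, apatail:::revcomp(genome_fetch(g, "chr1", 101, 400)))
  expect_equal(wm$cov, as.numeric(400:101))
  # chromosome start: leading N / 0 fill
  w0 <- build_window("chr1", "+", 1, 100, g, cov)
  expect_equal(substr(w0$seq, 1, 100), strrep("N", 100))
  expect_equal(w0$cov[1:100], rep(0, 100))
})

test_that("PAS scanning finds hexamers in the placement window only", {
  w <- make_window(plant(polyC, "AATAAA", 120))
  got <- scan_pas(w)
  expect_equal(unname(got$features), c(1, -1, -1, -1))
  expect_equal(got$pas_pos, 120)
  # nothing in a featureless window
  none <- scan_pas(make_window(polyC))
  expect_equal(unname(none$features), rep(-1, 4))
  expect_true(is.na(none$pas_pos))
  # scan range is [flank - 35, flank + bin - 6] for hexamer starts
  expect_equal(scan_pas(make_window(plant(polyC, "AATAAA", 65)))$pas_pos, 65)
  expect_true(is.na(scan_pas(make_window(plant(polyC, "AATAAA",
                                               64)))$pas_pos))
  expect_equal(scan_pas(make_window(plant(polyC, "AATAAA", 194)))$pas_pos,
               194)
  expect_true(is.na(scan_pas(make_window(plant(polyC, "AATAAA",
                                               195)))$pas_pos))
  # priority: canonical beats the major variant regardless of position
  w2 <- make_window(plant(plant(polyC, "ATTAAA", 80), "AATAAA", 150))
  got2 <- scan_pas(w2)
  expect_equal(unname(got2$features), c(1, 1, -1, -1))
  expect_equal(got2$pas_pos, 150)
  # within a class the 3'-most occurrence wins
  w3 <- make_window(plant(plant(polyC, "AATAAA", 80), "AATAAA", 160))
  expect_equal(scan_pas(w3)$pas_pos, 160)
  # each minor variant is detected
  for (hx in apatail:::PAS_MINOR) {
    gm <- scan_pas(make_window(plant(polyC, hx, 120)))
    expect_equal(unname(gm$features), c(-1, -1, -1, 1))
  }
})

test_that("element features respond to planted motifs around the PAS", {
  base <- plant(polyC, "AATAAA", 110)         # P = 110, D = [116, 216)
  expect_equal(unname(scan_elements(make_window(polyC), NA)), rep(-1, 8))
  # three GGG runs downstream
  wg <- plant(plant(plant(base, "GGG", 130), "GGG", 150), "GGG", 170)
  expect_equal(unname(scan_elements(make_window(wg), 110))[1], 1)
  # TTT twice in the near-downstream region [116, 150)
  wt <- plant(plant(base, "TTT", 120), "TTT", 130)
  expect_equal(unname(scan_elements(make_window(wt), 110))[2], 1)
  # GT-rich downstream (>= 6 overlapping dimers)
  wgt <- plant(base, "GTGTGTGTGTGT", 130)
  el <- unname(scan_elements(make_window(wgt), 110))
  expect_equal(el[3], 1)
  expect_equal(el[4], 1)     # GTGT/TGTG repeats come along
  # T-rich immediately downstream: >= 40% T over D's first 30 bases
  wtr <- plant(base, strrep("T", 13), 118)
  expect_equal(unname(scan_elements(make_window(wtr), 110))[5], 1)
  # T-rich upstream over U's last 30 bases
  wtu <- plant(base, strrep("T", 13), 82)
  expect_equal(unname(scan_elements(make_window(wtu), 110))[6], 1)
  # TGTA/TATA upstream
  wta <- plant(plant(base, "TGTA", 40), "TATA", 60)
  expect_equal(unname(scan_elements(make_window(wta), 110))[7], 1)
  # AT-rich across both flanks
  wat <- make_window(plant(paste(rep(c("A", "T"), 150), collapse = ""),
                           "AATAAA", 110))
  expect_equal(unname(scan_elements(wat, 110))[8], 1)
})

test_that("RNA features are bounded contrasts of region medians", {
  # flat coverage: all signed ratios and log differences are zero
  wf <- make_window(polyC, rep(7, 300))
  f <- rna_features(wf, inter_medians = c(7, 7, 7))
  expect_equal(unname(f[c(1, 2, 3, 5, 6)]), rep(0, 5))
  expect_equal(unname(f[4]), log1p(7))
  expect_equal(unname(f[7]), 7 / 8)
  # a step to zero at the bin's 3' edge
  ws <- make_window(polyC, c(rep(100, 200), rep(0, 100)))
  fs <- rna_features(ws)
  expect_equal(unname(fs[2]), 100 / 101)    # s(mM, mD) = (100-0)/(100+0+1)
  # zero coverage: everything 0 (log terms included)
  expect_equal(unname(rna_features(make_window(polyC, rep(0, 300)))),
               rep(0, 14))
  # boundedness of the signed ratios
  set.seed(5)
  for (i in 1:20) {
    w <- make_window(polyC, rpois(300, 40))
    expect_true(all(abs(rna_features(w, rpois(3, 40))[c(1:3, 8:10)]) < 1))
  }
})

test_that("annotation-end feature flags bins holding an original stop", {
  r <- apa_region("chr1", "+", 1, 1000, "t", 300)
  expect_equal(annot_end_feature(201, 300, r), 1)
  expect_equal(annot_end_feature(301, 400, r), -1)
  rm2 <- apa_region("chr1", "+", 1, 1000, c("a", "b"), c(150, 720))
  flags <- vapply(seq(1, 901, by = 100), function(s)
    annot_end_feature(s, s + 99, rm2), 0)
  expect_equal(which(flags == 1), c(2, 8))
})

test_that("featurize matches an independent straight-line recomputation", {
  inp <- tiny_inputs()
  bins <- tiny_bins()
  chars <- oracle_fasta_chars(inp$fx$paths$fasta)
  depth_p <- oracle_bedgraph_vec(inp$fx$paths$coverage_plus,
                                 inp$fx$chrom_lengths)
  depth_m <- oracle_bedgraph_vec(inp$fx$paths$coverage_minus,
                                 inp$fx$chrom_lengths)
  picked <- 0
  for (s in bins) {
    if (picked >= 4) break
    picked <- picked + 1
    depths <- if (s$strand == "+") depth_p[[s$chrom]] else depth_m[[s$chrom]]
    check <- unique(pmin(c(1, 3, s$n_real), s$n_real))
    for (i in check) {
      prev_bin <- if (i > 1) c(s$start[i - 1], s$end[i - 1]) else NULL
      next_bin <- if (i < s$n_real) c(s$start[i + 1], s$end[i + 1]) else NULL
      want <- oracle_bin_features(s$chrom, s$strand, s$start[i], s$end[i],
                                  s$region$original_stops, prev_bin,
                                  next_bin, chars[[s$chrom]], depths)
      expect_equal(unname(s$features[i, ]), want, tolerance = 1e-12)
    }
  }
  expect_gte(picked, 2)
  # binary slots only ever hold -1/1; quantitative slots finite
  for (s in bins) {
    i <- seq_len(s$n_real)
    expect_true(all(s$features[i, c(1:12, 27)] %in% c(-1, 1)))
    expect_true(all(is.finite(s$features[i, 13:26])))
    expect_true(all(s$features[!s$mask, ] == 0))
  }
})

test_that("feature extraction is strand-symmetric", {
  set.seed(21)
  L <- 3000
  fwd_seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
  fwd_cov <- as.numeric(rpois(L, 30))
  g <- make_genome(c(fwd = fwd_seq, rev = apatail:::revcomp(fwd_seq)))
  cov <- make_coverage(list("fwd:+" = fwd_cov, "fwd:-" = numeric(L),
                            "rev:-" = rev(fwd_cov), "rev:+" = numeric(L)),
                       c(fwd = L, rev = L), stranded = TRUE)
  # region [1001, 1400] on fwd:+ mirrors [L-1400+1, L-1000] on rev:-
  rf <- apa_region("fwd", "+", 1001, 1400, "t", 1100)
  rr <- apa_region("rev", "-", L - 1400 + 1, L - 1000, "t", L - 1100 + 1)
  bf <- featurize(bin_region(rf, 100, 300), g, cov)
  br <- featurize(bin_region(rr, 100, 300), g, cov)
  expect_equal(bf[[1]]$features, br[[1]]$features, tolerance = 1e-12)
})

test_that("DNA and RNA features are uncorrelated when channels are", {
  inp <- easy_inputs()
  bins <- cached("indep_bins", {
    # independent channels: the stripped genome carries only background
    # sequence, so DNA features are positionally random while the RNA
    # features keep their real coverage structure
    stripped <- degrade_fixture(inp$fx, strip_pas = TRUE, seed = 5)
    g2 <- read_fasta(stripped$paths$fasta)
    raw <- prepare_bin_sequences(inp$txs, g2, inp$cov,
                                 labels = inp$sites, merge = TRUE)
    featurize(raw, g2, inp$cov)
  })
  ft <- do.call(rbind, lapply(bins, function(s)
    s$features[s$mask, , drop = FALSE]))
  keep_rna <- which(apply(ft[, 13:26], 2, stats::sd) > 0) + 12
  keep_dna <- which(apply(ft[, 1:12], 2, stats::sd) > 0)
  cors <- abs(stats::cor(ft[, keep_dna], ft[, keep_rna]))
  expect_lt(max(cors), 0.1)
})

test_that("PAS features are enriched in labelled bins on synthetic data", {
  bins <- easy_bins()
  ft <- do.call(rbind, lapply(bins, function(s)
    cbind(s$features[s$mask, 1:4, drop = FALSE], s$label[s$mask])))
  pos <- ft[ft[, 5] == 1, 1:4] == 1
  neg <- ft[ft[, 5] == 0, 1:4] == 1
  for (j in 1:4) expect_gt(mean(pos[, j]), mean(neg[, j]))
})

test_that("feature tables carry one row per real bin", {
  bins <- tiny_bins()
  tab <- feature_table(bins)
  expect_equal(nrow(tab), sum(vapply(bins, `[[`, 0L, "n_real")))
  expect_equal(ncol(tab), 5 + 27 + 1)
  path <- tempfile(fileext = ".tsv")
  feature_table(bins, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
  expect_equal(nrow(back), nrow(tab))
})
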