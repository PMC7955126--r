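# Shared fixture builders. Everything is generated in code at test time;
# expensive artefacts (simulated data sets, trained models) are built once
# per session and cached.

test_cache <- function() {
  if (!exists(".apatail_test_cache", envir = globalenv(), inherits = FALSE))
    assign(".apatail_test_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  get(".apatail_test_cache", envir = globalenv())
}

cached <- function(key, expr) {
  ce <- test_cache()
  if (!exists(key, envir = ce)) assign(key, force(expr), envir = ce)
  get(key, envir = ce)
}

# write a FASTA and load it
make_genome <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "w")
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  close(con)
  read_fasta(path)
}

# coverage object straight from per-chrom (or per chrom:strand) vectors
make_coverage <- function(tracks, lengths = NULL, stranded = FALSE) {
  if (is.null(lengths)) {
    chroms <- unique(sub(":[+-]$", "", names(tracks)))
    lengths <- sapply(chroms, function(ch)
      max(sapply(tracks[startsWith(names(tracks), ch)], length)))
  }
  apatail:::new_coverage(tracks, lengths, stranded)
}

flat_coverage <- function(chrom, len, depth, stranded = FALSE) {
  tracks <- if (stranded)
    stats::setNames(list(rep(depth, len), rep(depth, len)),
                    paste0(chrom, c(":+", ":-")))
  else stats::setNames(list(rep(depth, len)), chrom)
  apatail:::new_coverage(tracks, stats::setNames(len, chrom), stranded)
}

# a window object in the shape build_window() returns
make_window <- function(seq, cov = NULL, flank = 100) {
  if (length(seq) > 1) seq <- paste(seq, collapse = "")
  if (is.null(cov)) cov <- numeric(nchar(seq))
  list(seq = seq, cov = cov, bin_size = nchar(seq) - 2 * flank,
       flank = flank)
}

sites_df <- function(chrom, strand, pos) {
  apatail:::new_sites(data.frame(chrom = chrom, strand = strand, pos = pos,
                                 stringsAsFactors = FALSE))
}

# small simulated data set, shared across files
tiny_fixture <- function() {
  cached("tiny_fx", sim_apa_data(
    sim_config(n_transcripts = 6, chrom_length = 120000, seed = 7),
    dir = file.path(tempdir(), "apatail_tiny_fx")))
}

load_fixture_inputs <- function(fx) {
  g <- read_fasta(fx$paths$fasta)
  list(fx = fx, genome = g,
       cov = load_coverage(c(plus = fx$paths$coverage_plus,
                             minus = fx$paths$coverage_minus),
                           stranded = TRUE, chrom_lengths = g$lengths),
       txs = read_gtf(fx$paths$gtf),
       sites = read_polya_bed(fx$paths$truth_bed))
}

tiny_inputs <- function() cached("tiny_in", load_fixture_inputs(tiny_fixture()))

# featurized, labelled, merged bin sequences of the tiny data set
tiny_bins <- function() {
  cached("tiny_bins", {
    inp <- tiny_inputs()
    bins <- prepare_bin_sequences(inp$txs, inp$genome, inp$cov,
                                  labels = inp$sites, merge = TRUE)
    featurize(bins, inp$genome, inp$cov)
  })
}

# the full-scale "easy" study data set and its trained model
easy_inputs <- function() {
  cached("easy_in", load_fixture_inputs(
    cached("easy_fx", sim_apa_data(sim_config(seed = 42),
                                   dir = file.path(tempdir(),
                                                   "apatail_easy_fx")))))
}

easy_bins <- function() {
  cached("easy_bins", {
    inp <- easy_inputs()
    bins <- prepare_bin_sequences(inp$txs, inp$genome, inp$cov,
                                  labels = inp$sites, merge = TRUE)
    featurize(bins, inp$genome, inp$cov)
  })
}

easy_model <- function() {
  cached("easy_model", apa_fit(easy_bins(), apa_model_config(seed = 1)))
}

# permute labels across the real bins of all sequences (null data set)
shuffle_bin_labels <- function(bins, seed = 99) {
  labs <- unlist(lapply(bins, function(s) s$label[s$mask]))
  labs <- apatail:::with_seed(seed, sample(labs))
  k <- 0
  out <- lapply(bins, function(s) {
    n <- s$n_real
    s$label[seq_len(n)] <- labs[k + seq_len(n)]
    k <<- k + n
    s
  })
  attributes(out) <- attributes(bins)
  out
}
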