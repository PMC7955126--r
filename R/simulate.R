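# Synthetic-data generator: desk-scale fixtures with the statistical
# structure the method assumes — genomes with planted polyA-signal grammar,
# transcript GTFs, truth polyA-site BEDs, and per-strand coverage tracks
# with staircase drop-offs at used sites plus a readthrough tail.

#' Simulation configuration
#'
#' Defaults describe an "easy" desk-scale data set: 200 two-exon
#' transcripts over two 1.5-Mb chromosomes (both strands), 1-3 polyA sites
#' per transcript with a PAS hexamer planted 10-35 nt upstream of each site
#' and optional downstream GU-rich/U-rich elements, and coverage that steps
#' down at each used site in proportion to site usage, with Poisson
#' per-base noise and a low readthrough tail modelling precursor-mRNA
#' reads.
#'
#' @param n_transcripts Total transcripts.
#' @param n_chrom,chrom_length Chromosome count and length (bases).
#' @param sites_min,sites_max Range of planted sites per transcript.
#' @param pas_offset_range PAS 3'-end distance upstream of the cleavage
#'   site, bases.
#' @param pas_probs Probabilities of planting the canonical AATAAA, ATTAAA,
#'   AGTAAA, or a random minor variant (must sum to 1).
#' @param element_prob Probability of planting a downstream GT-rich element
#'   at each site.
#' @param t_rich_prob Probability of planting a downstream T-rich element.
#' @param usage_range Relative site usage is drawn uniformly from this range
#'   and normalized per transcript.
#' @param read_depth Expected depth at the terminal exon's 5' end.
#' @param readthrough_fraction Depth beyond the last used site, as a
#'   fraction of `read_depth`.
#' @param readthrough_len Length of the readthrough tail, bases.
#' @param noise Apply per-base Poisson noise to expected coverage?
#' @param term_len_range Terminal-exon length range (annotated stop at the
#'   first site).
#' @param site_gap_range Spacing between consecutive planted sites, bases.
#' @param upstream_exon_len,intron_len Geometry of the 5' exon and intron.
#' @param locus_gap Gap between consecutive gene loci, bases.
#' @param bin_size Bin width the fixture is meant for (geometry check only).
#' @param seed Integer seed; outputs are byte-identical under the same seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 200, n_chrom = 2,
                       chrom_length = 1500000, sites_min = 1, sites_max = 3,
                       pas_offset_range = c(10, 35),
                       pas_probs = c(canonical = 0.70, variant1 = 0.15,
                                     variant2 = 0.05, minor = 0.10),
                       element_prob = 0.6, t_rich_prob = 0.6,
                       usage_range = c(0.5, 1.5), read_depth = 100,
                       readthrough_fraction = 0.05, readthrough_len = 500,
                       noise = TRUE, term_len_range = c(500, 1500),
                       site_gap_range = c(400, 2500),
                       upstream_exon_len = 300, intron_len = 500,
                       locus_gap = 4000, bin_size = 100, seed = 42) {
  stopifnot(abs(sum(pas_probs) - 1) < 1e-8,
            all(pas_offset_range >= 10), all(pas_offset_range <= 35))
  if (site_gap_range[1] < 2 * bin_size)
    stop_fmt("sites too dense for bin separation: min gap %d < 2 x bin %d",
             site_gap_range[1], bin_size)
  max_span <- (sites_max - 1) * site_gap_range[2] + readthrough_len
  if (max_span > 9500)
    stop_fmt("site span (%d) cannot fit in the downstream extension",
             max_span)
  structure(as.list(environment()), class = "sim_config")
}

pick_pas_hexamer <- function(pas_probs) {
  cls <- sample(names(pas_probs), 1, prob = pas_probs)
  switch(cls, canonical = PAS_CANONICAL, variant1 = PAS_VARIANT1,
         variant2 = PAS_VARIANT2, minor = sample(PAS_MINOR, 1))
}

#' Generate a synthetic fixture
#'
#' Writes, into `dir`: `genome.fa`, `annotation.gtf` (annotated stop at
#' each transcript's first/5'-most site), `truth_sites.bed` (all planted
#' sites, BED6), per-strand coverage (`coverage_plus.bedgraph`,
#' `coverage_minus.bedgraph`), an unstranded sum (`coverage.bedgraph`) and
#' `manifest.json`. Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest: a list with `paths`, `sites` (chrom, strand, pos,
#'   usage, transcript_id, hexamer, offset, annotated), `transcripts`, and
#'   `config`.
#' @export
sim_apa_data <- function(config = sim_config(), dir = tempfile("apasim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, sim_apa_data_impl(config, dir))
}

sim_apa_data_impl <- function(cfg, dir) {
  chroms <- paste0("chrS", seq_len(cfg$n_chrom))
  seq_chars <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE))
  names(seq_chars) <- chroms
  cov <- list()
  for (ch in chroms)
    for (s in c("+", "-"))
      cov[[paste0(ch, ":", s)]] <- numeric(cfg$chrom_length)
  cursor <- stats::setNames(rep(10001, cfg$n_chrom), chroms)
  sites <- list(); txs <- list(); spans <- list()
  for (i in seq_len(cfg$n_transcripts)) {
    ch <- chroms[(i - 1) %% cfg$n_chrom + 1]
    strand <- if ((i %% 2) == 0) "-" else "+"
    n_sites <- sample(cfg$sites_min:cfg$sites_max, 1)
    term_len <- round(stats::runif(1, cfg$term_len_range[1],
                                   cfg$term_len_range[2]))
    gaps <- if (n_sites > 1)
      round(stats::runif(n_sites - 1, cfg$site_gap_range[1],
                         cfg$site_gap_range[2])) else numeric(0)
    u <- stats::runif(n_sites, cfg$usage_range[1], cfg$usage_range[2])
    u <- u / sum(u)
    up <- cfg$upstream_exon_len; intr <- cfg$intron_len
    t0 <- up + intr + 1                       # terminal exon start (tx coords)
    tpos <- up + intr + term_len + c(0, cumsum(gaps))  # site positions
    block_len <- tpos[n_sites] + cfg$readthrough_len + 200
    if (cursor[ch] + block_len + cfg$locus_gap > cfg$chrom_length - 10500)
      stop_fmt("chrom_length too small for %d transcripts", cfg$n_transcripts)
    # local sequence (transcript orientation) with planted grammar
    local <- sample(c("A", "C", "G", "T"), block_len, replace = TRUE)
    planted <- character(n_sites)
    offs <- integer(n_sites)
    for (j in seq_len(n_sites)) {
      o <- sample(cfg$pas_offset_range[1]:cfg$pas_offset_range[2], 1)
      hex <- pick_pas_hexamer(cfg$pas_probs)
      planted[j] <- hex; offs[j] <- o
      local[(tpos[j] - o - 5):(tpos[j] - o)] <- strsplit(hex, "")[[1]]
      if (stats::runif(1) < cfg$element_prob)
        local[tpos[j] + 8:19] <- rep(c("T", "G"), 6)
      if (stats::runif(1) < cfg$t_rich_prob)
        local[tpos[j] + 24:31] <- "T"
    }
    # expected coverage (transcript orientation): full depth on the 5'
    # exon, zero in the intron, staircase down the terminal region, then a
    # readthrough tail
    lambda <- numeric(block_len)
    lambda[1:up] <- cfg$read_depth
    seg_lo <- t0
    for (j in seq_len(n_sites)) {      # staircase: level drops past each site
      lambda[seg_lo:tpos[j]] <- cfg$read_depth * sum(u[j:n_sites])
      seg_lo <- tpos[j] + 1
    }
    rt <- (tpos[n_sites] + 1):(tpos[n_sites] + cfg$readthrough_len)
    lambda[rt] <- cfg$read_depth * cfg$readthrough_fraction
    depth <- if (cfg$noise) stats::rpois(block_len, lambda) else round(lambda)
    # map into genome
    base <- cursor[ch]
    if (strand == "+") {
      gpos <- function(tp) base + tp - 1
      seq_chars[[ch]][base:(base + block_len - 1)] <- local
      cov[[paste0(ch, ":+")]][base:(base + block_len - 1)] <-
        cov[[paste0(ch, ":+")]][base:(base + block_len - 1)] + depth
      exons <- rbind(c(gpos(1), gpos(up)),
                     c(gpos(t0), gpos(tpos[1])))
    } else {
      gpos <- function(tp) base + block_len - tp
      seq_chars[[ch]][base:(base + block_len - 1)] <- revcomp_chars(local)
      cov[[paste0(ch, ":-")]][base:(base + block_len - 1)] <-
        cov[[paste0(ch, ":-")]][base:(base + block_len - 1)] + rev(depth)
      exons <- rbind(c(gpos(tpos[1]), gpos(t0)),
                     c(gpos(up), gpos(1)))
    }
    id <- sprintf("SIMT%04d", i)
    txs[[id]] <- apa_transcript(id, sprintf("SIMG%04d", i), ch, strand,
                                exons)
    term_span <- range(gpos(t0), gpos(tpos[n_sites] + cfg$readthrough_len))
    spans[[id]] <- term_span
    sites[[id]] <- data.frame(
      chrom = ch, strand = strand,
      pos = vapply(tpos, gpos, 0), usage = u, transcript_id = id,
      hexamer = planted, offset = offs,
      annotated = seq_len(n_sites) == 1, stringsAsFactors = FALSE)
    cursor[ch] <- cursor[ch] + block_len + cfg$locus_gap
  }
  sites <- do.call(rbind, sites)
  rownames(sites) <- NULL
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    truth_bed = file.path(dir, "truth_sites.bed"),
    coverage_plus = file.path(dir, "coverage_plus.bedgraph"),
    coverage_minus = file.path(dir, "coverage_minus.bedgraph"),
    coverage = file.path(dir, "coverage.bedgraph"),
    manifest = file.path(dir, "manifest.json"))
  # FASTA
  fa <- file(paths$fasta, "w")
  for (ch in chroms) {
    writeLines(paste0(">", ch), fa)
    s <- paste(seq_chars[[ch]], collapse = "")
    writeLines(substring(s, seq(1, nchar(s), 70),
                         pmin(seq(1, nchar(s), 70) + 69, nchar(s))), fa)
  }
  close(fa)
  write_gtf(txs, paths$gtf)
  # truth BED6 (site at BED end on +, start+1 on -; single-base records)
  bed <- sprintf("%s\t%d\t%d\tsite%d\t0\t%s", sites$chrom,
                 as.integer(sites$pos - 1), as.integer(sites$pos),
                 seq_len(nrow(sites)), sites$strand)
  writeLines(bed, paths$truth_bed)
  # bedGraphs
  write_bedgraph <- function(tracks, path) {
    con <- file(path, "w")
    for (key in names(tracks)) {
      ch <- sub(":[+-]$", "", key)
      r <- rle(tracks[[key]])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths    # 0-based
      keep <- r$values != 0
      if (any(keep))
        writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts[keep], ends[keep],
                           r$values[keep]), con)
    }
    close(con)
  }
  write_bedgraph(cov[grepl(":\\+$", names(cov))], paths$coverage_plus)
  write_bedgraph(cov[grepl(":-$", names(cov))], paths$coverage_minus)
  combined <- stats::setNames(lapply(chroms, function(ch)
    cov[[paste0(ch, ":+")]] + cov[[paste0(ch, ":-")]]),
    paste0(chroms, ":+"))
  write_bedgraph(combined, paths$coverage)
  tx_df <- data.frame(
    transcript_id = names(txs),
    chrom = vapply(txs, `[[`, "", "chrom"),
    strand = vapply(txs, `[[`, "", "strand"),
    stop3p = vapply(txs, transcript_stop3p, 0),
    n_sites = as.integer(table(sites$transcript_id)[names(txs)]),
    term_span_lo = vapply(names(txs), function(id) spans[[id]][1], 0),
    term_span_hi = vapply(names(txs), function(id) spans[[id]][2], 0),
    stringsAsFactors = FALSE)
  rownames(tx_df) <- NULL
  manifest <- list(paths = paths, sites = sites, transcripts = tx_df,
                   chrom_lengths = stats::setNames(
                     rep(cfg$chrom_length, cfg$n_chrom), chroms),
                   config = unclass(cfg), dir = dir)
  jsonlite::write_json(manifest[c("sites", "transcripts", "chrom_lengths",
                                  "config")],
                       paths$manifest, auto_unbox = TRUE, digits = NA)
  manifest
}

#' Degrade a synthetic fixture
#'
#' Controlled corruption for robustness tests, each knob isolating one
#' information channel: `shuffle_labels` relocates every truth site to a
#' random position within a random transcript's terminal span (breaking the
#' feature/label association at unchanged prevalence), `zero_coverage`
#' empties the coverage tracks, and `strip_pas` overwrites the planted PAS
#' hexamers and downstream elements with fresh random background sequence.
#' With all knobs off the fixture is returned unchanged.
#'
#' @param fixture A manifest from [sim_apa_data()].
#' @param shuffle_labels,zero_coverage,strip_pas Logical knobs.
#' @param seed Seed for the stochastic knobs.
#' @return The manifest with paths updated to the degraded files (written
#'   next to the originals with a `degraded_` prefix).
#' @export
degrade_fixture <- function(fixture, shuffle_labels = FALSE,
                            zero_coverage = FALSE, strip_pas = FALSE,
                            seed = 1) {
  if (!shuffle_labels && !zero_coverage && !strip_pas) return(fixture)
  dir <- fixture$dir
  with_seed(seed, {
    if (strip_pas) {
      g <- read_fasta(fixture$paths$fasta)
      chars <- lapply(g$seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
      for (i in seq_len(nrow(fixture$sites))) {
        st <- fixture$sites[i, ]
        # genomic extent of planted grammar: PAS upstream + elements
        # downstream of the cleavage site, transcript orientation
        lo_tx <- -(st$offset + 5)   # relative to site, tx orientation
        hi_tx <- 31
        rel <- if (st$strand == "+") st$pos + (lo_tx:hi_tx)
               else st$pos - (lo_tx:hi_tx)
        rel <- rel[rel >= 1 & rel <= length(chars[[st$chrom]])]
        chars[[st$chrom]][rel] <- sample(c("A", "C", "G", "T"),
                                         length(rel), replace = TRUE)
      }
      path <- file.path(dir, "degraded_genome.fa")
      con <- file(path, "w")
      for (ch in names(chars)) {
        writeLines(paste0(">", ch), con)
        s <- paste(chars[[ch]], collapse = "")
        writeLines(substring(s, seq(1, nchar(s), 70),
                             pmin(seq(1, nchar(s), 70) + 69, nchar(s))),
                   con)
      }
      close(con)
      fixture$paths$fasta <- path
    }
    if (zero_coverage) {
      for (nm in c("coverage_plus", "coverage_minus", "coverage")) {
        path <- file.path(dir, paste0("degraded_", basename(
          fixture$paths[[nm]])))
        writeLines(character(0), path)
        fixture$paths[[nm]] <- path
      }
    }
    if (shuffle_labels) {
      tx <- fixture$transcripts
      sites <- fixture$sites
      for (i in seq_len(nrow(sites))) {
        # relocate uniformly within a random transcript's terminal span
        j <- sample.int(nrow(tx), 1)
        lo <- tx$term_span_lo[j]; hi <- tx$term_span_hi[j]
        sites$pos[i] <- lo + sample.int(hi - lo + 1, 1) - 1
        sites$chrom[i] <- tx$chrom[j]
        sites$strand[i] <- tx$strand[j]
      }
      path <- file.path(dir, "degraded_truth_sites.bed")
      writeLines(sprintf("%s\t%d\t%d\tsite%d\t0\t%s", sites$chrom,
                         as.integer(sites$pos - 1), as.integer(sites$pos),
                         seq_len(nrow(sites)), sites$strand), path)
      fixture$paths$truth_bed <- path
      fixture$sites <- sites
    }
  })
  fixture
}
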