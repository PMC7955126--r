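# Readers/writers for the standard formats the pipeline touches.
#
# Coordinate conventions: everything is 1-based inclusive internally (the GTF
# convention). BED and bedGraph are 0-based half-open and are converted at the
# boundary, in these readers/writers only.

GTF_SOURCE_TAG <- "apatail"

## ---- genome -----------------------------------------------------------

#' Read a genome FASTA
#'
#' Loads a multi-record FASTA (one record per chromosome) into an
#' `apa_genome` object. Lowercase (soft-masked) bases are uppercased;
#' chromosome names are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return An `apa_genome` object with accessors [chrom_names()],
#'   [chrom_length()] and [genome_fetch()].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' g <- read_fasta(fa)
#' genome_fetch(g, "chr1", 1, 4)   # "ACGT"
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  set <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e) stop_fmt("malformed FASTA '%s': %s",
                                          path, conditionMessage(e))),
    warning = function(w) {
      if (grepl("invalid one-letter sequence", conditionMessage(w)))
        stop_fmt("non-ACGTN characters in FASTA %s: %s", path,
                 conditionMessage(w))
    })
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms))
    stop_fmt("duplicate chromosome header in %s: %s", path,
             nms[duplicated(nms)][1])
  seqs <- toupper(as.character(set))
  names(seqs) <- nms
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop_fmt("non-ACGTN characters in record '%s'", nms[bad][1])
  structure(list(seqs = seqs, lengths = setNames(nchar(seqs), nms)),
            class = "apa_genome")
}

#' @rdname read_fasta
#' @param genome An `apa_genome`.
#' @export
chrom_names <- function(genome) names(genome$seqs)

#' @rdname read_fasta
#' @param chrom Chromosome name.
#' @export
chrom_length <- function(genome, chrom) {
  if (!chrom %in% names(genome$lengths))
    stop_fmt("unknown chromosome '%s'", chrom)
  unname(genome$lengths[[chrom]])
}

#' @rdname read_fasta
#' @param start,end 1-based inclusive interval. Portions outside
#'   `[1, chrom_length]` are filled with `N`.
#' @export
genome_fetch <- function(genome, chrom, start, end) {
  len <- chrom_length(genome, chrom)
  if (end < start) stop_fmt("end < start in genome_fetch")
  lo <- max(1L, start); hi <- min(len, end)
  core <- if (lo > hi) "" else substr(genome$seqs[[chrom]], lo, hi)
  paste0(strrep("N", max(0L, lo - start)), core,
         paste0(strrep("N", max(0L, end - hi))))
}

#' @export
print.apa_genome <- function(x, ...) {
  cat("apa_genome:", length(x$seqs), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bases\n")
  invisible(x)
}

## ---- transcripts ------------------------------------------------------

#' Construct a transcript model
#'
#' A transcript is an exon chain on one strand of one chromosome. Exons are
#' 1-based inclusive `[start, end]` intervals, kept sorted by genomic
#' coordinate and non-overlapping. The 3' stop is the last base of the last
#' exon on `+`, and the first base of the first exon on `-`.
#'
#' @param transcript_id,gene_id Identifier strings.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`; unstranded records are rejected.
#' @param exons Two-column matrix (start, end) of exon intervals.
#' @param source `"original"` (input annotation) or `"predicted"` (added by
#'   the polyA-site integration step).
#' @return An `apa_transcript` object.
#' @export
apa_transcript <- function(transcript_id, gene_id, chrom, strand, exons,
                           source = "original") {
  if (!strand %in% c("+", "-"))
    stop_fmt("transcript %s: strand must be '+' or '-'", transcript_id)
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] < exons[, 1]))
    stop_fmt("transcript %s: exon end < start", transcript_id)
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop_fmt("transcript %s: overlapping exons", transcript_id)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 source = source),
            class = "apa_transcript")
}

#' 3' stop position of a transcript
#' @param t An `apa_transcript`.
#' @return 1-based genomic position of the transcript's 3' terminus.
#' @export
transcript_stop3p <- function(t) {
  if (t$strand == "+") max(t$exons[, 2]) else min(t$exons[, 1])
}

#' @export
print.apa_transcript <- function(x, ...) {
  cat(sprintf("apa_transcript %s (%s) %s:%s %d exon(s), 3' stop %d\n",
              x$transcript_id, x$source, x$chrom, x$strand,
              nrow(x$exons), as.integer(transcript_stop3p(x))))
  invisible(x)
}

#' Read transcript models from a GTF
#'
#' Parses exon features into one [apa_transcript()] per `transcript_id`.
#' Records on strand `"."` are dropped (with a logged count): the downstream
#' 3'-end logic is strand-specific by construction.
#'
#' @param path Path to a GTF file with `exon` features carrying
#'   `transcript_id` and `gene_id` attributes.
#' @return Named list of `apa_transcript` objects (names = transcript ids),
#'   in order of first appearance.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop_fmt("GTF file not found: %s", path)
  body_lines <- grep("^[^#]", readLines(path), value = TRUE)
  if (length(body_lines) == 0)
    return(structure(list(), names = character(0)))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) return(structure(list(), names = character(0)))
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop_fmt("GTF %s: exon feature without transcript_id attribute", path)
  unstranded <- as.character(GenomicRanges::strand(gr)) == "*"
  if (any(unstranded)) {
    apa_log("dropping %d unstranded exon record(s)", sum(unstranded))
    gr <- gr[!unstranded]
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = gr$transcript_id,
    gene_id = if (is.null(gr$gene_id)) gr$transcript_id else gr$gene_id,
    stringsAsFactors = FALSE)
  tag <- if (!is.null(gr$source_tag)) gr$source_tag else rep(NA_character_, nrow(df))
  df$source <- ifelse(!is.na(tag) & tag == GTF_SOURCE_TAG,
                      "predicted", "original")
  ids <- unique(df$transcript_id)
  out <- lapply(ids, function(id) {
    e <- df[df$transcript_id == id, ]
    apa_transcript(id, e$gene_id[1], e$chrom[1], e$strand[1],
                   cbind(e$start, e$end), source = e$source[1])
  })
  names(out) <- ids
  out
}

#' Write transcript models to a GTF
#'
#' Emits one `transcript` line and one `exon` line per exon for each model.
#' Predicted transcripts carry a `source_tag "apatail"` attribute so they are
#' distinguishable from the original annotation when re-read.
#'
#' @param transcripts List of [apa_transcript()] objects.
#' @param path Output path.
#' @export
write_gtf <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## apatail transcript models", con)
  for (t in transcripts) {
    tag <- if (identical(t$source, "predicted"))
      sprintf(' source_tag "%s";', GTF_SOURCE_TAG) else ""
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                     t$gene_id, t$transcript_id, tag)
    lines <- c(
      sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              t$chrom, GTF_SOURCE_TAG, as.integer(min(t$exons[, 1])),
              as.integer(max(t$exons[, 2])), t$strand, attrs),
      sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
              t$chrom, GTF_SOURCE_TAG, as.integer(t$exons[, 1]),
              as.integer(t$exons[, 2]), t$strand, attrs))
    writeLines(lines, con)
  }
  invisible(path)
}

## ---- coverage ---------------------------------------------------------

cov_key <- function(chrom, strand, stranded) {
  if (stranded) paste0(chrom, ":", strand) else chrom
}

new_coverage <- function(tracks, lengths, stranded) {
  structure(list(tracks = tracks, lengths = lengths, stranded = stranded),
            class = "apa_coverage")
}

#' Load per-base read coverage
#'
#' Builds a base-resolution coverage track from either a coordinate-sorted,
#' indexed BAM of genome-aligned reads or a bedGraph. BAM coverage counts
#' each aligned read segment once with split (`N` CIGAR) segments excluded —
#' the `bedtools genomecov -split` semantics; secondary and supplementary
#' alignments are excluded, duplicates are kept (configurable via `flag`).
#' bedGraph intervals (0-based half-open) are converted to 1-based inclusive.
#'
#' @param path BAM path, a single bedGraph path (`stranded = FALSE`), or a
#'   length-2 vector `c(plus=, minus=)` of bedGraph paths (`stranded = TRUE`).
#' @param stranded Keep the two strands as separate tracks?
#' @param chrom_lengths Optional named vector of chromosome lengths; queries
#'   beyond a declared length are an error. When omitted, lengths are taken
#'   from the BAM header or from the furthest bedGraph interval.
#' @param keep_duplicates Keep PCR/optical duplicate alignments (BAM only).
#' @return An `apa_coverage` object; query with [cov_depth()].
#' @export
load_coverage <- function(path, stranded = FALSE, chrom_lengths = NULL,
                          keep_duplicates = TRUE) {
  is_bam <- length(path) == 1 && grepl("\\.bam$", path, ignore.case = TRUE)
  if (is_bam) {
    load_coverage_bam(path, stranded, chrom_lengths, keep_duplicates)
  } else {
    if (stranded && length(path) != 2)
      stop_fmt(paste("stranded bedGraph coverage needs two files",
                     "c(plus=, minus=); for a single unstranded bedGraph",
                     "call load_coverage(path, stranded = FALSE)"))
    if (!stranded && length(path) != 1)
      stop_fmt("unstranded coverage takes a single bedGraph path")
    load_coverage_bedgraph(path, stranded, chrom_lengths)
  }
}

load_coverage_bam <- function(path, stranded, chrom_lengths, keep_duplicates) {
  bai <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))
  if (!any(file.exists(bai)))
    stop_fmt("BAM %s has no index (.bai); sort and index it first", path)
  bf <- Rsamtools::BamFile(path)
  hdr_len <- Rsamtools::scanBamHeader(path)[[1]]$targets
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = if (keep_duplicates) NA else FALSE)
  aln <- GenomicAlignments::readGAlignments(bf,
           param = Rsamtools::ScanBamParam(flag = flag))
  lengths <- if (is.null(chrom_lengths)) hdr_len else chrom_lengths
  tracks <- list()
  fill <- function(sub, strand_lab) {
    covs <- GenomicAlignments::coverage(sub)  # CIGAR-aware; N gaps excluded
    for (chrom in names(covs)) {
      v <- as.integer(covs[[chrom]])
      length(v) <- lengths[[chrom]]          # pad tail with NA -> 0
      v[is.na(v)] <- 0L
      tracks[[cov_key(chrom, strand_lab, stranded)]] <<- v
    }
  }
  if (stranded) {
    st <- as.character(GenomicAlignments::strand(aln))
    fill(aln[st == "+"], "+")
    fill(aln[st == "-"], "-")
  } else fill(aln, "+")
  for (chrom in names(lengths)) {           # chromosomes with no reads
    for (s in if (stranded) c("+", "-") else "+") {
      k <- cov_key(chrom, s, stranded)
      if (is.null(tracks[[k]])) tracks[[k]] <- integer(lengths[[chrom]])
    }
  }
  new_coverage(tracks, lengths, stranded)
}

read_bedgraph_df <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0)))
  df <- utils::read.table(text = lines, header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  if (any(df$end <= df$start))
    stop_fmt("bedGraph %s: interval with end <= start", path)
  df
}

load_coverage_bedgraph <- function(path, stranded, chrom_lengths) {
  paths <- if (stranded) {
    if (is.null(names(path))) setNames(path, c("+", "-"))
    else setNames(path[c("plus", "minus")], c("+", "-"))
  } else setNames(path, "+")
  tracks <- list()
  maxend <- c()
  for (s in names(paths)) {
    df <- read_bedgraph_df(paths[[s]])
    for (chrom in unique(df$chrom)) {
      sub <- df[df$chrom == chrom, ]
      len <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]] else max(sub$end)
      if (any(sub$end > len))
        stop_fmt("bedGraph interval beyond declared length of %s", chrom)
      v <- numeric(len)
      for (i in seq_len(nrow(sub)))               # 0-based half-open -> 1-based
        v[(sub$start[i] + 1):sub$end[i]] <- sub$value[i]
      tracks[[cov_key(chrom, s, stranded)]] <- v
      maxend[chrom] <- max(maxend[chrom] %||% 0, len, na.rm = TRUE)
    }
  }
  lengths <- if (!is.null(chrom_lengths)) chrom_lengths else maxend
  for (chrom in names(lengths)) {
    for (s in names(paths)) {
      k <- cov_key(chrom, s, stranded)
      if (is.null(tracks[[k]])) tracks[[k]] <- numeric(lengths[[chrom]])
      else if (length(tracks[[k]]) < lengths[[chrom]]) {
        v <- tracks[[k]]; length(v) <- lengths[[chrom]]; v[is.na(v)] <- 0
        tracks[[k]] <- v
      }
    }
  }
  new_coverage(tracks, lengths, stranded)
}

#' Query read depth
#'
#' @param cov An `apa_coverage` from [load_coverage()].
#' @param chrom Chromosome name; unknown chromosomes are an error.
#' @param strand `"+"` or `"-"`; on an unstranded track both return the same
#'   values.
#' @param pos Vector of 1-based positions; positions outside
#'   `[1, chrom_length]` are an error.
#' @return Numeric vector of read depths (>= 0).
#' @export
cov_depth <- function(cov, chrom, strand, pos) {
  if (!chrom %in% names(cov$lengths))
    stop_fmt("coverage has no chromosome '%s'", chrom)
  len <- cov$lengths[[chrom]]
  if (any(pos < 1 | pos > len))
    stop_fmt("coverage query outside [1, %d] on %s", as.integer(len), chrom)
  v <- cov$tracks[[cov_key(chrom, strand, cov$stranded)]]
  out <- numeric(length(pos))
  inside <- pos <= length(v)
  out[inside] <- v[pos[inside]]
  out
}

#' @export
print.apa_coverage <- function(x, ...) {
  cat(sprintf("apa_coverage: %d track(s), %s, total depth %s\n",
              length(x$tracks), if (x$stranded) "stranded" else "unstranded",
              format(sum(vapply(x$tracks, sum, 0)), big.mark = ",")))
  invisible(x)
}

## ---- polyA sites ------------------------------------------------------

#' Read a polyA-site BED file
#'
#' Reads a BED6-like file of cleavage sites (3'-seq derived). The site
#' position is the `end` coordinate on `+` and `start + 1` on `-`
#' (single-base records resolve to `start + 1` either way, i.e. the base the
#' record covers). Duplicate records collapse to one site.
#'
#' @param path BED path; a strand column (column 6) is required.
#' @return An `apa_sites` data frame with columns `chrom`, `strand`, `pos`.
#' @export
read_polya_bed <- function(path) {
  if (!file.exists(path)) stop_fmt("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(new_sites(data.frame(chrom = character(0), strand = character(0),
                                pos = numeric(0))))
  df <- utils::read.table(text = lines, header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6)
    stop_fmt("polyA BED %s must have a strand column (BED6)", path)
  strand <- as.character(df[[6]])
  if (!all(strand %in% c("+", "-")))
    stop_fmt("polyA BED %s: invalid strand value(s)", path)
  start <- as.numeric(df[[2]]); end <- as.numeric(df[[3]])
  pos <- ifelse(end - start == 1, start + 1, ifelse(strand == "+", end, start + 1))
  out <- unique(data.frame(chrom = as.character(df[[1]]), strand = strand,
                           pos = pos, stringsAsFactors = FALSE))
  new_sites(out)
}

new_sites <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("apa_sites", "data.frame")
  df
}

#' Sites falling inside an interval
#' @param sites An `apa_sites` data frame.
#' @param chrom,strand,start,end Strand-specific 1-based inclusive interval.
#' @return Subset of `sites` inside the interval.
#' @export
sites_in_interval <- function(sites, chrom, strand, start, end) {
  sites[sites$chrom == chrom & sites$strand == strand &
        sites$pos >= start & sites$pos <= end, , drop = FALSE]
}
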