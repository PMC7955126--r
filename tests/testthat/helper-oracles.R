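# Independent brute-force oracles. These deliberately avoid the package's
# accessors and recompute expected values straight from raw files/arrays.

ap_brute <- function(probs, labels) {
  ths <- sort(unique(probs), decreasing = TRUE)
  prev_r <- 0; ap <- 0
  for (th in ths) {
    tp <- sum(probs >= th & labels == 1)
    pp <- sum(probs >= th)
    prec <- tp / pp
    rec <- tp / sum(labels == 1)
    ap <- ap + (rec - prev_r) * prec
    prev_r <- rec
  }
  ap
}

oracle_revcomp <- function(chars) chartr("ACGTN", "TGCAN", rev(chars))

oracle_fasta_chars <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  lapply(as.list(as.character(set)), function(s)
    strsplit(toupper(s), "", fixed = TRUE)[[1]])
}

oracle_bedgraph_vec <- function(path, lengths) {
  df <- utils::read.table(path, col.names = c("chrom", "start", "end", "v"))
  out <- lapply(lengths, function(l) numeric(l))
  for (i in seq_len(nrow(df)))
    out[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- df$v[i]
  out
}

# full 27-feature recomputation for one bin, from character/ depth vectors
oracle_bin_features <- function(chrom, strand, start, end, region_stops,
                                prev_bin, next_bin, chars, depths) {
  flank <- 100
  bin_size <- end - start + 1
  idx <- (start - flank):(end + flank)
  seqv <- ifelse(idx >= 1 & idx <= length(chars), chars[pmax(idx, 1)], "N")
  covv <- ifelse(idx >= 1 & idx <= length(depths), depths[pmax(idx, 1)], 0)
  if (strand == "-") { seqv <- oracle_revcomp(seqv); covv <- rev(covv) }
  W <- length(seqv)
  hex_at <- function(off, hx) {   # off is 0-based
    paste(seqv[(off + 1):(off + 6)], collapse = "") == hx
  }
  scan_range <- (flank - 35):(flank + bin_size - 6)
  find_all <- function(hx) scan_range[vapply(scan_range, hex_at, TRUE,
                                             hx = hx)]
  minors <- c("AAGAAA", "AAAAAG", "AATACA", "TATAAA", "GATAAA", "AATATA",
              "CATAAA", "AATAGA")
  h_can <- find_all("AATAAA"); h_v1 <- find_all("ATTAAA")
  h_v2 <- find_all("AGTAAA")
  h_mi <- sort(unique(unlist(lapply(minors, find_all))))
  pas <- c(length(h_can) > 0, length(h_v1) > 0, length(h_v2) > 0,
           length(h_mi) > 0)
  P <- if (length(h_can)) max(h_can) else if (length(h_v1)) max(h_v1)
       else if (length(h_v2)) max(h_v2) else if (length(h_mi)) max(h_mi)
       else flank + 15
  slice <- function(a, b) if (b <= a) character(0) else seqv[(a + 1):b]
  D <- slice(P + 6, min(P + 106, W)); U <- slice(max(P - 100, 0), P)
  Nn <- slice(P + 6, min(P + 40, W))
  count_no <- function(v, k) {   # non-overlapping, greedy left-to-right
    n <- 0; i <- 1; kl <- nchar(k)
    while (i + kl - 1 <= length(v)) {
      if (paste(v[i:(i + kl - 1)], collapse = "") == k) {
        n <- n + 1; i <- i + kl
      } else i <- i + 1
    }
    n
  }
  count_ov <- function(v, ks) {
    n <- 0
    for (k in ks) {
      kl <- nchar(k)
      if (length(v) < kl) next
      for (i in 1:(length(v) - kl + 1))
        if (paste(v[i:(i + kl - 1)], collapse = "") == k) n <- n + 1
    }
    n
  }
  d30 <- D[seq_len(min(30, length(D)))]
  u30 <- if (length(U)) U[max(1, length(U) - 29):length(U)] else character(0)
  els <- c(count_no(D, "GGG") >= 3,
           count_no(Nn, "TTT") >= 2,
           count_ov(D, c("GT", "TG")) >= 6,
           count_ov(D, c("GTGT", "TGTG")) >= 2,
           length(d30) > 0 && mean(d30 == "T") >= 0.4,
           length(u30) > 0 && mean(u30 == "T") >= 0.4,
           count_ov(U, c("TGTA", "TATA")) >= 2,
           length(c(U, D)) > 0 && mean(c(U, D) %in% c("A", "T")) >= 0.65)
  med_int <- function(a, b) {
    p <- a:b
    p <- p[p >= 1 & p <= length(depths)]
    if (!length(p)) 0 else stats::median(depths[p])
  }
  mU <- stats::median(covv[1:flank])
  mM <- stats::median(covv[(flank + 1):(flank + bin_size)])
  mD <- stats::median(covv[(flank + bin_size + 1):(flank + bin_size + flank)])
  MU <- if (is.null(prev_bin)) 0 else med_int(prev_bin[1], prev_bin[2])
  MM <- med_int(start, end)
  MD <- if (is.null(next_bin)) 0 else med_int(next_bin[1], next_bin[2])
  s <- function(a, b) (a - b) / (a + b + 1)
  blk <- function(a, b, d) c(s(a, b), s(b, d), s(a, d), log1p(b),
                             log1p(a) - log1p(b), log1p(b) - log1p(d),
                             d / (a + 1))
  unname(c(ifelse(pas, 1, -1), ifelse(els, 1, -1), blk(mU, mM, mD),
           blk(MU, MM, MD),
           if (any(region_stops >= start & region_stops <= end)) 1 else -1))
}

# per-base coverage from a SAM text by walking CIGARs (split-aware)
oracle_sam_coverage <- function(sam_lines, chrom_len) {
  v <- integer(chrom_len)
  for (ln in sam_lines) {
    if (startsWith(ln, "@")) next
    f <- strsplit(ln, "\t")[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 256) > 0 || bitwAnd(flag, 2048) > 0) next
    pos <- as.integer(f[4])
    cig <- f[6]
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
    at <- pos
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        v[at:(at + n - 1)] <- v[at:(at + n - 1)] + 1L
        at <- at + n
      } else if (type %in% c("D", "N")) at <- at + n
      # I/S/H/P consume no reference
    }
  }
  v
}
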