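# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals (splits, simulation,
#' weight initialisation) do not perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Polynomial rolling hash over the serialized object (mod 2^31 - 1, exact
# in doubles); stable fingerprint for feature configs.
fnv1a_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # skip the serialization header (R version stamps) to keep hashes portable
  bytes <- bytes[-seq_len(14)]
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

# Reverse complement of a plain character scalar (A/C/G/T/N).
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# Reverse complement of a character vector of single bases.
revcomp_chars <- function(v) chartr("ACGTN", "TGCAN", rev(v))

apa_log <- function(...) {
  if (isTRUE(getOption("apatail.verbose", FALSE)))
    message("[apatail] ", sprintf(...))
  invisible(NULL)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
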