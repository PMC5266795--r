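# internal helpers: seed substreams, hashing, TSV IO conventions

# Stage codes for the deterministic substream scheme. A single user-facing
# seed is expanded into independent per-stage, per-unit seeds so that adding
# a study (or reordering stages) does not perturb the draws of other units.
.stage_codes <- c(
  genotypes  = 1L,
  cohort     = 2L,
  consortium = 3L,
  pipeline   = 4L,
  replicate  = 5L
)

#' Derive a reproducible substream seed
#'
#' Expands one global seed into a per-stage, per-unit seed by a fixed affine
#' counter scheme modulo a Mersenne prime, so every simulation unit owns an
#' independent, order-insensitive stream.
#'
#' @param seed integer global seed.
#' @param stage one of `"genotypes"`, `"cohort"`, `"consortium"`,
#'   `"pipeline"`, `"replicate"`.
#' @param index non-negative unit index (e.g. study number).
#' @return a single integer suitable for [set.seed()].
#' @keywords internal
#' @export
substream_seed <- function(seed, stage = "pipeline", index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  code <- .stage_codes[[match.arg(stage, names(.stage_codes))]]
  m <- 2147483629 # largest prime below 2^31
  s <- (abs(seed) %% m) * 48271 + code * 97003 + index * 7919
  as.integer(s %% m)
}

# FNV-1a 32-bit hash of a character scalar; used for run manifests so no
# external hashing package is required.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h %/% 2^31 %% 2)), b)
    # keep arithmetic in doubles, reduce mod 2^32
    h <- (as.double(h) %% 2^32) * 16777619 %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# All tabular interchange is TSV with a fixed float format: 6 significant
# digits, IEEE round-half-even (what signif() does), so golden files are
# portable across platforms.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

#' Write a data frame as a TSV interchange table
#'
#' Numeric columns are serialised with 6 significant digits (round-half-even)
#' so outputs are byte-reproducible across platforms.
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV interchange table
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# 97.5% normal quantile used for every CI (large-sample convention; no
# small-sample t adjustment).
.z975 <- 1.959964

`%||%` <- function(a, b) if (is.null(a)) b else a
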