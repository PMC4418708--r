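# Internal helpers shared across modules.

# Canonical key for an unordered protein pair: lexicographically sorted ids
# joined by "|".  Idempotent and order-insensitive.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Canonicalize a two-column pair data.frame: sorted ids, deduplicated.
canonicalize_pairs <- function(df) {
  stopifnot(ncol(df) >= 2)
  a <- as.character(df[[1]])
  b <- as.character(df[[2]])
  out <- data.frame(protein_a = pmin(a, b), protein_b = pmax(a, b),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(pair_key(out$protein_a, out$protein_b)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive an independent sub-seed for a named generator from one master seed.
# Counter-based: adding a new generator never perturbs the streams of
# existing ones.  Kept below 2^31 - 1 (R integers are 32-bit).
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483587 + 1)
}

# TSV conventions used by every reader/writer: tab-delimited, header row,
# '#' comment lines ignored, never quoted.
read_tsv <- function(path, ...) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("input file not found: %s", path),
                        class = c("dmi_missing_input", "error")))
  }
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
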