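#' Mean disorder of a candidate motif
#'
#' Per-residue disorder scores (IUPred-style, in [0, 1]) are averaged over
#' the motif; the motif is called disordered when the mean is strictly
#' greater than 0.5, the cutoff recommended for IUPred scores.
#'
#' @param scores Numeric per-residue disorder track for the motif's protein.
#' @param start,end 1-based inclusive motif coordinates.
#' @param cutoff Disorder cutoff on the mean score.
#' @return List with `mean` and logical `disordered`.
#' @export
motif_disorder <- function(scores, start, end, cutoff = 0.5) {
  if (start < 1 || end > length(scores) || end < start) {
    stop("motif [", start, ", ", end, "] outside disorder track of length ",
         length(scores))
  }
  m <- mean(scores[start:end])
  list(mean = m, disordered = m > cutoff)
}

#' Per-residue conservation from an ortholog alignment
#'
#' For each alignment column where the reference (human) row is not a gap,
#' the information content is \eqn{IC = log2(20) - H}, with `H` the Shannon
#' entropy of the amino-acid frequencies among the column's non-gap entries,
#' and the score is `IC` multiplied by the column's non-gap fraction.  Scores
#' are indexed by reference-sequence residue position.  Non-standard letters
#' are treated as `X`: they count toward the non-gap fraction but are
#' excluded from the frequency distribution.
#'
#' @param msa Character matrix from [read_msa()].
#' @param human_row_id Row name of the reference sequence.
#' @return Numeric vector of conservation scores (bits), one per reference
#'   residue.
#' @export
column_conservation <- function(msa, human_row_id) {
  if (!human_row_id %in% rownames(msa)) {
    stop("reference row ", human_row_id, " absent from alignment")
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  gap <- c("-", ".")
  human <- msa[human_row_id, ]
  cols <- which(!human %in% gap)
  depth <- nrow(msa)
  scores <- vapply(cols, function(j) {
    col <- msa[, j]
    nongap <- col[!col %in% gap]
    counts <- table(factor(nongap[nongap %in% aa], levels = aa))
    p <- counts / max(sum(counts), 1)
    p <- p[p > 0]
    H <- if (length(p) > 0) -sum(p * log2(p)) else 0
    (log2(20) - H) * (length(nongap) / depth)
  }, numeric(1))
  unname(scores)
}

#' Local conservation flags
#'
#' A residue is locally conserved when its conservation score is strictly
#' higher than the mean score of its surrounding residues, up to
#' `half_window` (default 31) positions upstream and downstream, the window
#' truncated at the sequence ends and excluding the residue itself.
#'
#' @param scores Numeric per-residue conservation scores.
#' @param half_window Residues considered on each side.
#' @return Logical vector of per-residue flags.
#' @export
local_conservation <- function(scores, half_window = 31) {
  n <- length(scores)
  if (n == 0) stop("empty conservation track")
  if (n == 1) return(FALSE)
  cs <- cumsum(scores)
  lo <- pmax(1L, seq_len(n) - half_window)
  hi <- pmin(n, seq_len(n) + half_window)
  win_sum <- cs[hi] - c(0, cs)[lo]
  win_n <- hi - lo + 1L
  nb_mean <- (win_sum - scores) / (win_n - 1L)
  scores > nb_mean
}

#' Is a motif locally conserved?
#'
#' TRUE only when every residue in `[start, end]` carries a local
#' conservation flag.
#'
#' @param flags Logical per-residue flags from [local_conservation()].
#' @param start,end 1-based inclusive motif coordinates.
#' @return Logical scalar.
#' @export
motif_conserved <- function(flags, start, end) {
  if (start < 1 || end > length(flags) || end < start) {
    stop("motif [", start, ", ", end, "] outside conservation track of ",
         "length ", length(flags))
  }
  all(flags[start:end])
}
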