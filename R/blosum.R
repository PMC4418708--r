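#' BLOSUM62 substitution matrix used for window scoring
#'
#' The standard BLOSUM62 matrix over the 20 amino acids plus `X`.  Any
#' non-standard letter is mapped to `X`, and `X` scores 0 against every
#' residue (including itself) so that unknown positions neither reward nor
#' penalize a window.
#'
#' @return Integer matrix with row/column names `ACDEFGHIKLMNPQRSTVWY` + `X`.
#' @export
blosum62 <- function() {
  m <- get0(".blosum62", envir = .dmi_cache)
  if (!is.null(m)) return(m)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- e$BLOSUM62[aa, aa]
  m <- rbind(cbind(m, X = 0L), X = 0L)
  storage.mode(m) <- "integer"
  assign(".blosum62", m, envir = .dmi_cache)
  m
}

.dmi_cache <- new.env(parent = emptyenv())

# Map an amino-acid string to row indices of blosum62(); anything outside the
# 20 standard letters becomes the X row.
aa_index <- function(seq) {
  m <- blosum62()
  i <- match(strsplit(seq, "")[[1]], rownames(m))
  i[is.na(i)] <- nrow(m)
  i
}

#' Score a window against a template peptide
#'
#' Ungapped sum of position-wise BLOSUM62 substitution scores between two
#' equal-length sequences.  `X` (and any non-standard letter) scores 0
#' against anything.
#'
#' @param window,template_motif Equal-length amino-acid strings.
#' @return Integer score.
#' @export
score_window <- function(window, template_motif) {
  if (nchar(window) != nchar(template_motif)) {
    stop("window and template motif must have equal lengths")
  }
  m <- blosum62()
  sum(m[cbind(aa_index(window), aa_index(template_motif))])
}
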