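#' Match an ELM consensus pattern against one protein
#'
#' The consensus regular expression is attempted at every start position of
#' the sequence, so overlapping matches are all reported (one match per start
#' position, leftmost extent).  A leading `^` restricts the match to position
#' 1 and `$` retains its end-of-sequence meaning.
#'
#' @param protein One-row proteome data.frame (or list) with `protein_id` and
#'   `sequence`.
#' @param elm_class One-row class definition with `class_id` and `pattern`.
#' @return Candidate-motif data.frame with columns `protein_id`, `start`,
#'   `end`, `sequence`, `source`; zero rows when nothing matches.
#' @export
match_consensus <- function(protein, elm_class) {
  seq <- as.character(protein$sequence)[1]
  pat <- as.character(elm_class$pattern)[1]
  L <- nchar(seq)
  anchored_start <- startsWith(pat, "^")
  core <- if (anchored_start) substring(pat, 2) else pat
  anchored <- paste0("^(?:", core, ")")
  starts <- integer(0); ends <- integer(0)
  positions <- if (anchored_start) 1L else seq_len(L)
  for (i in positions) {
    m <- regexpr(anchored, substring(seq, i), perl = TRUE)
    len <- attr(m, "match.length")
    if (m == 1L && len > 0L) {
      starts <- c(starts, i)
      ends <- c(ends, i + len - 1L)
    }
  }
  data.frame(protein_id = rep(as.character(protein$protein_id)[1],
                              length(starts)),
             start = starts, end = ends,
             sequence = if (length(starts)) substring(seq, starts, ends)
                        else character(0),
             source = rep(as.character(elm_class$class_id)[1],
                          length(starts)),
             stringsAsFactors = FALSE)
}

#' Assign a similarity-percentile bin
#'
#' Window-scan candidates are binned by the fraction of all scanned windows
#' scoring at least as high: B1 for the top 0.0001\%, B2 up to 0.001\%, B3 up
#' to 0.01\%, B4 up to 0.05\%; anything ranked below the top 0.05\% is
#' rejected (`NA`).
#'
#' @param rank_fraction Numeric vector in (0, 1].
#' @return Character vector of `"B1"`..`"B4"` or `NA` for rejected.
#' @export
assign_sim_bin <- function(rank_fraction) {
  if (any(rank_fraction <= 0 | rank_fraction > 1)) {
    stop("rank_fraction must lie in (0, 1]")
  }
  cut(rank_fraction, breaks = c(0, 1e-6, 1e-5, 1e-4, 5e-4),
      labels = c("B1", "B2", "B3", "B4"), right = TRUE) |> as.character()
}

#' Scan a template peptide across a proteome
#'
#' Every window of the template's length that fits fully inside a protein is
#' scored with [score_window()].  The retention cutoff is the score of the
#' `ceiling(top_fraction * N)`-th best window out of all `N` windows; every
#' window scoring at least that (ties at the boundary included) is retained.
#' Each retained window gets `rank_fraction` = (number of windows scoring >=
#' its score) / N and a percentile bin from [assign_sim_bin()] (`NA` when a
#' boundary tie pushes its rank fraction past `top_fraction`).
#'
#' @param proteome Proteome data.frame from [read_fasta()].
#' @param template_motif Template peptide sequence, 5-35 residues.
#' @param top_fraction Retained fraction of all windows (default 5e-4, i.e.
#'   the top 0.05\%).
#' @param template_id Label recorded in the `source` column.
#' @return Candidate-motif data.frame with columns `protein_id`, `start`,
#'   `end`, `sequence`, `source`, `sim_score`, `rank_fraction`, `sim_bin`,
#'   ordered by decreasing score.
#' @export
scan_template_motif <- function(proteome, template_motif,
                                top_fraction = 5e-4,
                                template_id = "template") {
  x <- nchar(template_motif)
  if (x < 5 || x > 35) stop("template motif length must be in [5, 35]")
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]")
  }
  m <- blosum62()
  tidx <- aa_index(template_motif)

  per_prot <- lapply(seq_len(nrow(proteome)), function(i) {
    L <- proteome$length[i]
    nw <- L - x + 1L
    if (nw < 1L) return(NULL)
    sidx <- aa_index(proteome$sequence[i])
    sc <- integer(nw)
    for (j in seq_len(x)) {
      sc <- sc + m[cbind(sidx[j:(j + nw - 1L)], tidx[j])]
    }
    data.frame(protein_id = proteome$protein_id[i], start = seq_len(nw),
               score = sc, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_prot)
  if (is.null(all) || nrow(all) == 0) {
    stop("no windows: template is longer than every protein")
  }
  N <- nrow(all)
  k <- ceiling(top_fraction * N)
  cutoff <- sort(all$score, decreasing = TRUE)[k]
  keep <- all[all$score >= cutoff, , drop = FALSE]
  # rank fraction: windows scoring >= this one, counting the window itself
  n_ge <- vapply(keep$score, function(s) sum(all$score >= s), numeric(1))
  keep$rank_fraction <- n_ge / N
  keep <- keep[order(-keep$score, keep$protein_id, keep$start), ]
  sequences <- substring(
    setNames(proteome$sequence, proteome$protein_id)[keep$protein_id],
    keep$start, keep$start + x - 1L)
  data.frame(protein_id = keep$protein_id, start = keep$start,
             end = keep$start + x - 1L, sequence = unname(sequences),
             source = template_id, sim_score = keep$score,
             rank_fraction = keep$rank_fraction,
             sim_bin = assign_sim_bin(keep$rank_fraction),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname scan_template_motif
#' @param motifs Candidate-motif data.frame.
#' @param path Output TSV path.
#' @export
write_motifs <- function(motifs, path) write_tsv(motifs, path)
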