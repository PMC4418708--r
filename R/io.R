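#' Read a proteome from a FASTA file
#'
#' Sequences are uppercased and trailing `*` stop characters stripped.  The
#' protein id is the first whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A data.frame with columns `protein_id`, `sequence`, `length`,
#'   one row per entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("input file not found: %s", path),
                        class = c("dmi_missing_input", "error")))
  }
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("cannot parse FASTA: ",
                                            conditionMessage(e)))
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate protein id(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  sq <- toupper(as.character(seqs))
  sq <- sub("\\*+$", "", sq)
  if (any(nchar(sq) < 1)) stop("zero-length sequence in FASTA: ", path)
  data.frame(protein_id = unname(ids), sequence = unname(sq),
             length = unname(nchar(sq)), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write a proteome data.frame to FASTA
#'
#' @param proteome Data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  x <- Biostrings::BStringSet(setNames(proteome$sequence,
                                       proteome$protein_id))
  Biostrings::writeXStringSet(x, path, width = 70)
  invisible(path)
}

#' Read ELM-style motif class definitions
#'
#' Expects a TSV with columns `class_id`, `family_id` (Pfam accession of the
#' peptide-recognition domain) and `pattern` (consensus regular expression).
#' Every pattern is compiled to validate it; a non-compiling pattern aborts
#' with the offending class id.
#'
#' @param path Path to the TSV.
#' @return Data.frame with columns `class_id`, `family_id`, `pattern`.
#' @export
read_elm_classes <- function(path) {
  df <- read_tsv(path)
  need <- c("class_id", "family_id", "pattern")
  if (!all(need %in% names(df))) {
    stop("ELM class TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("ELM class file is empty: ", path)
    return(df[, need])
  }
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({
      suppressWarnings(regexpr(df$pattern[i], "", perl = TRUE))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      stop(sprintf("invalid consensus pattern for class %s: %s",
                   df$class_id[i], df$pattern[i]))
    }
  }
  df[, need]
}

#' @rdname read_elm_classes
#' @param classes Data.frame of class definitions.
#' @export
write_elm_classes <- function(classes, path) write_tsv(classes, path)

#' Construct a true-positive / true-negative pair set
#'
#' Pairs are unordered: each is stored canonically with the
#' lexicographically smaller id first, and duplicates (including reversed
#' duplicates) are collapsed.  A pair present in both sets is an error.
#'
#' @param positives,negatives Two-column data.frames of protein ids.
#' @return An object of class `pair_set` with elements `positives`,
#'   `negatives` (canonical data.frames), `N_TP`, `N_TN`.
#' @export
pair_set <- function(positives, negatives) {
  tp <- canonicalize_pairs(positives)
  tn <- canonicalize_pairs(negatives)
  both <- intersect(pair_key(tp$protein_a, tp$protein_b),
                    pair_key(tn$protein_a, tn$protein_b))
  if (length(both) > 0) {
    stop("pair(s) present in both TP and TN sets: ",
         paste(head(both, 10), collapse = ", "),
         if (length(both) > 10) sprintf(" (and %d more)", length(both) - 10))
  }
  structure(list(positives = tp, negatives = tn,
                 N_TP = nrow(tp), N_TN = nrow(tn)),
            class = "pair_set")
}

#' Read TP/TN pair lists from two TSV files
#'
#' Each file has columns `protein_a`, `protein_b`.
#'
#' @param tp_path,tn_path Paths to the true-positive and true-negative TSVs.
#' @return A [pair_set()] object.
#' @export
read_pair_set <- function(tp_path, tn_path) {
  tp <- read_tsv(tp_path)
  tn <- read_tsv(tn_path)
  pair_set(tp, tn)
}

#' @rdname read_pair_set
#' @param pairs A `pair_set` object.
#' @export
write_pair_set <- function(pairs, tp_path, tn_path) {
  write_tsv(pairs$positives, tp_path)
  write_tsv(pairs$negatives, tn_path)
  invisible(c(tp_path, tn_path))
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("Pair set: %d true-positive, %d true-negative pairs\n",
              x$N_TP, x$N_TN))
  invisible(x)
}

#' Read a non-structural evidence table
#'
#' Non-structural (NS) likelihood ratios — co-expression, GO similarity,
#' phylogenetic profile similarity, already combined — are consumed as a
#' pre-computed pair -> LR table.  Lookups are symmetric in the two ids and
#' a pair absent from the table gets the neutral LR 1.
#'
#' @param path TSV with columns `protein_a`, `protein_b`, `lr`.
#' @return An object of class `ns_table`.
#' @export
read_ns_table <- function(path) {
  df <- read_tsv(path)
  need <- c("protein_a", "protein_b", "lr")
  if (!all(need %in% names(df))) {
    stop("NS table must have columns: ", paste(need, collapse = ", "))
  }
  ns_table(df)
}

#' @rdname read_ns_table
#' @param df Data.frame with columns `protein_a`, `protein_b`, `lr`.
#' @export
ns_table <- function(df) {
  lr <- as.numeric(df$lr)
  if (any(!is.finite(lr)) || any(lr <= 0)) {
    stop("non-structural LR values must be positive and finite")
  }
  keys <- pair_key(as.character(df$protein_a), as.character(df$protein_b))
  if (anyDuplicated(keys)) stop("duplicate pair(s) in NS table")
  structure(list(lr = setNames(lr, keys)), class = "ns_table")
}

#' @rdname read_ns_table
#' @param table An `ns_table` object.
#' @param a,b Protein ids (vectorized).
#' @export
ns_lookup <- function(table, a, b) {
  stopifnot(inherits(table, "ns_table"))
  v <- unname(table$lr[pair_key(a, b)])
  v[is.na(v)] <- 1
  v
}

#' @rdname read_ns_table
#' @export
write_ns_table <- function(table, path) {
  ab <- strsplit(names(table$lr), "|", fixed = TRUE)
  write_tsv(data.frame(protein_a = vapply(ab, `[`, "", 1),
                       protein_b = vapply(ab, `[`, "", 2),
                       lr = unname(table$lr), stringsAsFactors = FALSE),
            path)
}

#' Read domain annotations
#'
#' Pre-computed domain hits (e.g. hmmscan against Pfam) as a TSV with columns
#' `protein_id`, `family_id`, `start`, `end`; coordinates 1-based inclusive.
#'
#' @param path Path to the TSV.
#' @param proteome Optional proteome data.frame for bounds checking.
#' @return Data.frame with the four columns above.
#' @export
read_domain_annotations <- function(path, proteome = NULL) {
  df <- read_tsv(path)
  need <- c("protein_id", "family_id", "start", "end")
  if (!all(need %in% names(df))) {
    stop("domain annotation TSV must have columns: ",
         paste(need, collapse = ", "))
  }
  if (any(df$start < 1) || any(df$end < df$start)) {
    stop("domain annotations must satisfy 1 <= start <= end")
  }
  if (!is.null(proteome)) {
    len <- setNames(proteome$length, proteome$protein_id)
    L <- len[df$protein_id]
    if (any(is.na(L))) stop("domain annotation references unknown protein")
    if (any(df$end > L)) stop("domain annotation exceeds protein length")
  }
  df[, need]
}

#' Read per-residue disorder scores
#'
#' IUPred-style pre-computed scores, TSV columns `protein_id`, `position`,
#' `score` with scores in [0, 1].  Positions must form a contiguous 1..L run
#' per protein.
#'
#' @param path Path to the TSV.
#' @return Named list of numeric score vectors, one per protein.
#' @export
read_disorder <- function(path) {
  df <- read_tsv(path)
  need <- c("protein_id", "position", "score")
  if (!all(need %in% names(df))) {
    stop("disorder TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$score < 0 | df$score > 1)) {
    stop("disorder scores must lie in [0, 1]")
  }
  out <- lapply(split(df, df$protein_id), function(d) {
    d <- d[order(d$position), ]
    if (!identical(as.integer(d$position), seq_len(nrow(d)))) {
      stop("disorder positions for ", d$protein_id[1],
           " are not contiguous 1..L")
    }
    d$score
  })
  out
}

#' @rdname read_disorder
#' @param tracks Named list of per-residue score vectors.
#' @export
write_disorder <- function(tracks, path) {
  df <- do.call(rbind, lapply(names(tracks), function(id) {
    data.frame(protein_id = id, position = seq_along(tracks[[id]]),
               score = tracks[[id]], stringsAsFactors = FALSE)
  }))
  write_tsv(df, path)
}

#' Read an ortholog multiple sequence alignment
#'
#' FASTA alignment; all rows must have equal aligned length.  Returned as a
#' character matrix (rows = sequences, columns = alignment columns) with the
#' sequence ids as row names.
#'
#' @param path Path to the aligned FASTA.
#' @return Character matrix of single characters.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("input file not found: %s", path),
                        class = c("dmi_missing_input", "error")))
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("empty alignment: ", path)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1) {
    stop("alignment rows have unequal lengths in ", path)
  }
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(m) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  m
}

#' Read structural alignments of candidate domains to template PRDs
#'
#' One TSV holds all alignments: columns `template_id`, `protein_id`, `psd`
#' (protein structural distance from an external structural aligner) and one
#' row per aligned residue with `template_res` / `candidate_res` residue
#' references (`chain:resnum`).
#'
#' @param path Path to the TSV.
#' @return List of `struct_alignment` objects.
#' @export
read_struct_alignments <- function(path) {
  df <- read_tsv(path)
  need <- c("template_id", "protein_id", "psd", "template_res",
            "candidate_res")
  if (!all(need %in% names(df))) {
    stop("structural alignment TSV must have columns: ",
         paste(need, collapse = ", "))
  }
  key <- paste(df$template_id, df$protein_id, sep = "\r")
  lapply(unname(split(df, key)), function(d) {
    struct_alignment(d$template_id[1], d$protein_id[1], d$psd[1],
                     setNames(d$candidate_res, d$template_res))
  })
}

#' @rdname read_struct_alignments
#' @param alignments List of `struct_alignment` objects.
#' @export
write_struct_alignments <- function(alignments, path) {
  df <- do.call(rbind, lapply(alignments, function(a) {
    data.frame(template_id = a$template_id, protein_id = a$protein_id,
               psd = a$psd, template_res = names(a$correspondence),
               candidate_res = unname(a$correspondence),
               stringsAsFactors = FALSE)
  }))
  write_tsv(df, path)
}
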