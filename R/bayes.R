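# Naive Bayes likelihood-ratio engine: clue-LR estimation from TP/TN pair
# sets, the two LR(DMI) combination formulas, per-pair aggregation, NS
# multiplication and the strong-prediction threshold.

#' Flatten candidate matches to long-form clue observations
#'
#' A match table has one row per candidate domain-motif interface with
#' columns `protein_a`, `protein_b`, `method` (`"prd_motif"` or `"struct"`)
#' and its clue columns (`class`, `psd`, `sim`, `diso`, `consv`; `NA` where
#' not applicable).  The long form has one row per (pair, method, clue,
#' value), deduplicated per pair, which is the counting substrate for
#' [estimate_clue_lr()].
#'
#' @param matches Match data.frame.
#' @return Data.frame with columns `protein_a`, `protein_b`, `method`,
#'   `clue_id`, `value`.
#' @export
matches_to_observations <- function(matches) {
  if (nrow(matches) == 0) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      method = character(), clue_id = character(),
                      value = character(), stringsAsFactors = FALSE))
  }
  a <- pmin(matches$protein_a, matches$protein_b)
  b <- pmax(matches$protein_a, matches$protein_b)
  one <- function(clue_id, value) {
    keep <- !is.na(value)
    data.frame(protein_a = a[keep], protein_b = b[keep],
               method = matches$method[keep],
               clue_id = rep(clue_id, sum(keep)),
               value = as.character(value[keep]), stringsAsFactors = FALSE)
  }
  obs <- rbind(
    one("match", rep("present", nrow(matches))),
    one("class", matches$class %||% rep(NA, nrow(matches))),
    one("psd",   matches$psd   %||% rep(NA, nrow(matches))),
    one("sim",   matches$sim   %||% rep(NA, nrow(matches))),
    one("diso",  matches$diso  %||% rep(NA, nrow(matches))),
    one("consv", matches$consv %||% rep(NA, nrow(matches)))
  )
  obs[!duplicated(obs), , drop = FALSE]
}

#' Estimate clue likelihood ratios from TP/TN pair sets
#'
#' For each (method, clue, value), `n_TP` counts the true-positive pairs
#' observed with that clue value and `n_TN` the true-negative pairs, by
#' exhaustive enumeration.  The likelihood ratio is
#' \deqn{LR = \frac{(n_{TP} + \alpha) / (N_{TP} + \alpha K)}
#'                 {(n_{TN} + \alpha) / (N_{TN} + \alpha K)}}
#' with `K` the number of observed values of that clue.  With `alpha = 0`
#' (the default) a clue never seen among true negatives would be infinite;
#' it is capped at `lr_cap` and flagged.
#'
#' @param observations Long-form observations from
#'   [matches_to_observations()]; every pair must belong to `pairs`.
#' @param pairs A [pair_set()].
#' @param alpha Additive smoothing pseudocount.
#' @param lr_cap Upper bound on any single-clue LR.
#' @return Data.frame of class `lr_table` with columns `method`, `clue_id`,
#'   `value`, `n_TP`, `n_TN`, `lr`, `capped`, plus attributes `N_TP`,
#'   `N_TN`, `alpha`, `lr_cap`.
#' @export
estimate_clue_lr <- function(observations, pairs, alpha = 0, lr_cap = 1e6) {
  stopifnot(inherits(pairs, "pair_set"))
  if (pairs$N_TP == 0 || pairs$N_TN == 0) {
    stop("both TP and TN sets must be non-empty")
  }
  tp_keys <- pair_key(pairs$positives$protein_a, pairs$positives$protein_b)
  tn_keys <- pair_key(pairs$negatives$protein_a, pairs$negatives$protein_b)
  keys <- pair_key(observations$protein_a, observations$protein_b)
  in_tp <- keys %in% tp_keys
  in_tn <- keys %in% tn_keys
  if (any(!in_tp & !in_tn)) {
    stop("observation references pair(s) outside the TP/TN sets: ",
         paste(head(unique(keys[!in_tp & !in_tn]), 5), collapse = ", "))
  }
  grp <- paste(observations$method, observations$clue_id, observations$value,
               sep = "\r")
  ug <- unique(grp)
  n_tp <- vapply(ug, function(g) length(unique(keys[grp == g & in_tp])),
                 numeric(1))
  n_tn <- vapply(ug, function(g) length(unique(keys[grp == g & in_tn])),
                 numeric(1))
  parts <- do.call(rbind, strsplit(ug, "\r", fixed = TRUE))
  tab <- data.frame(method = parts[, 1], clue_id = parts[, 2],
                    value = parts[, 3], n_TP = unname(n_tp),
                    n_TN = unname(n_tn), stringsAsFactors = FALSE)
  # K: number of observed values per (method, clue)
  kk <- tapply(tab$value, paste(tab$method, tab$clue_id, sep = "\r"),
               function(v) length(unique(v)))
  K <- as.numeric(kk[paste(tab$method, tab$clue_id, sep = "\r")])
  p_tp <- (tab$n_TP + alpha) / (pairs$N_TP + alpha * K)
  p_tn <- (tab$n_TN + alpha) / (pairs$N_TN + alpha * K)
  lr <- ifelse(p_tn == 0, lr_cap, p_tp / p_tn)
  tab$capped <- lr >= lr_cap
  tab$lr <- pmin(lr, lr_cap)
  tab <- tab[order(tab$method, tab$clue_id, tab$value),
             c("method", "clue_id", "value", "n_TP", "n_TN", "lr", "capped")]
  rownames(tab) <- NULL
  base::structure(tab, N_TP = pairs$N_TP, N_TN = pairs$N_TN, alpha = alpha,
                  lr_cap = lr_cap, class = c("lr_table", "data.frame"))
}

#' @rdname estimate_clue_lr
#' @param table An `lr_table`.
#' @param path Output TSV path.
#' @export
write_lr_table <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}

#' @rdname estimate_clue_lr
#' @export
read_lr_table <- function(path) {
  df <- read_tsv(path)
  base::structure(df, class = c("lr_table", "data.frame"))
}

# Look up one clue LR; a (method, clue, value) never seen in training is
# uninformative and scores the neutral LR 1.
lr_lookup <- function(table, method, clue_id, value) {
  i <- match(paste(method, clue_id, value, sep = "\r"),
             paste(table$method, table$clue_id, table$value, sep = "\r"))
  out <- table$lr[i]
  out[is.na(out)] <- 1
  out
}

#' Fit the naive Bayes domain-motif interaction classifier
#'
#' The model is a table of clue likelihood ratios estimated from a curated
#' true-positive / true-negative pair set.  `matches` rows whose pair is not
#' in `pairs` are ignored during fitting (they can still be scored with
#' [predict.dmi_nb()]).
#'
#' @param matches Candidate-interface match table (see
#'   [matches_to_observations()]).
#' @param pairs A [pair_set()] of training pairs.
#' @param alpha,lr_cap Passed to [estimate_clue_lr()].
#' @return An object of class `dmi_nb` with elements `table` (the
#'   `lr_table`), `N_TP`, `N_TN`, `alpha`, `lr_cap`, `call`.
#' @seealso [predict.dmi_nb()], [cross_validate()]
#' @export
dmi_nb <- function(matches, pairs, alpha = 0, lr_cap = 1e6) {
  stopifnot(inherits(pairs, "pair_set"))
  keys <- pair_key(matches$protein_a, matches$protein_b)
  known <- keys %in% c(pair_key(pairs$positives$protein_a,
                                pairs$positives$protein_b),
                       pair_key(pairs$negatives$protein_a,
                                pairs$negatives$protein_b))
  obs <- matches_to_observations(matches[known, , drop = FALSE])
  tab <- estimate_clue_lr(obs, pairs, alpha = alpha, lr_cap = lr_cap)
  base::structure(list(table = tab, N_TP = pairs$N_TP, N_TN = pairs$N_TN,
                       alpha = alpha, lr_cap = lr_cap,
                       call = match.call()),
                  class = "dmi_nb")
}

#' @export
print.dmi_nb <- function(x, ...) {
  cat("Naive Bayes domain-motif interaction classifier\n")
  cat(sprintf("  trained on %d TP / %d TN pairs; alpha = %g, LR cap = %g\n",
              x$N_TP, x$N_TN, x$alpha, x$lr_cap))
  cat(sprintf("  %d clue values across %d clue(s), %d capped\n",
              nrow(x$table), length(unique(paste(x$table$method,
                                                 x$table$clue_id))),
              sum(x$table$capped)))
  invisible(x)
}

#' @method summary dmi_nb
#' @export
summary.dmi_nb <- function(object, ...) {
  cat("Clue likelihood ratios:\n")
  print(as.data.frame(object$table), digits = 4)
  invisible(object$table)
}

#' @importFrom stats coef
#' @method coef dmi_nb
#' @export
coef.dmi_nb <- function(object, ...) {
  setNames(object$table$lr,
           paste(object$table$method, object$table$clue_id,
                 object$table$value, sep = "/"))
}

#' Combine clue LRs for a consensus-pattern (PRD/motif) interface
#'
#' The class, disorder and conservation clues are conditional on a match
#' being present, so each is normalized by the match LR before multiplying:
#' \deqn{LR(DMI) = LR(match) \cdot \frac{LR(class)}{LR(match)} \cdot
#'   \frac{LR(diso)}{LR(match)} \cdot \frac{LR(consv)}{LR(match)}}
#'
#' @param lr_match,lr_class,lr_diso,lr_consv Positive clue LRs (vectorized).
#' @return Numeric LR(DMI).
#' @export
dmi_lr_prd_motif <- function(lr_match, lr_class, lr_diso, lr_consv) {
  if (any(lr_match == 0)) stop("untrained match clue: LR(match) = 0")
  lr_match * (lr_class / lr_match) * (lr_diso / lr_match) *
    (lr_consv / lr_match)
}

#' Combine clue LRs for a template-based (Struct) interface
#'
#' Five clues; the PSD, similarity, disorder and conservation clues are each
#' normalized by the match LR:
#' \deqn{LR(DMI) = LR(match) \cdot \frac{LR(PSD)}{LR(match)} \cdot
#'   \frac{LR(SIM)}{LR(match)} \cdot \frac{LR(diso)}{LR(match)} \cdot
#'   \frac{LR(consv)}{LR(match)}}
#'
#' @param lr_match,lr_psd,lr_sim,lr_diso,lr_consv Positive clue LRs.
#' @return Numeric LR(DMI).
#' @export
dmi_lr_struct <- function(lr_match, lr_psd, lr_sim, lr_diso, lr_consv) {
  if (any(lr_match == 0)) stop("untrained match clue: LR(match) = 0")
  lr_match * (lr_psd / lr_match) * (lr_sim / lr_match) *
    (lr_diso / lr_match) * (lr_consv / lr_match)
}

#' Per-match LR(DMI) under a fitted classifier
#'
#' @param object A `dmi_nb` model.
#' @param matches Match table.
#' @return Numeric vector, one LR(DMI) per match row.
#' @export
score_matches <- function(object, matches) {
  stopifnot(inherits(object, "dmi_nb"))
  n <- nrow(matches)
  if (n == 0) return(numeric(0))
  tab <- object$table
  m <- matches$method
  lr_match <- lr_lookup(tab, m, "match", "present")
  lr_diso <- lr_lookup(tab, m, "diso", as.character(matches$diso))
  lr_consv <- lr_lookup(tab, m, "consv", as.character(matches$consv))
  out <- numeric(n)
  is_prd <- m == "prd_motif"
  if (any(is_prd)) {
    lr_class <- lr_lookup(tab, m[is_prd], "class",
                          as.character(matches$class[is_prd]))
    out[is_prd] <- dmi_lr_prd_motif(lr_match[is_prd], lr_class,
                                    lr_diso[is_prd], lr_consv[is_prd])
  }
  if (any(!is_prd)) {
    lr_psd <- lr_lookup(tab, m[!is_prd], "psd",
                        as.character(matches$psd[!is_prd]))
    lr_sim <- lr_lookup(tab, m[!is_prd], "sim",
                        as.character(matches$sim[!is_prd]))
    out[!is_prd] <- dmi_lr_struct(lr_match[!is_prd], lr_psd, lr_sim,
                                  lr_diso[!is_prd], lr_consv[!is_prd])
  }
  out
}

#' Aggregate interface LRs for one pair
#'
#' A pair can carry several candidate interfaces (several classes, several
#' templates, both methods).  The default policy keeps the maximum LR(DMI) —
#' the different interfaces usually describe the same physical contact, so
#' multiplying would double-count; `"product"` is available for comparison.
#' No interface means no DMI evidence: the neutral LR 1.
#'
#' @param lr_values Numeric LR(DMI) values for one pair.
#' @param policy `"max"` or `"product"`.
#' @return Scalar aggregated LR.
#' @export
aggregate_pair <- function(lr_values, policy = c("max", "product")) {
  policy <- match.arg(policy)
  if (length(lr_values) == 0) return(1)
  if (policy == "max") max(lr_values) else prod(lr_values)
}

#' Multiply DMI and non-structural evidence
#'
#' @param lr_dmi,lr_ns Positive likelihood ratios.
#' @return `lr_dmi * lr_ns`.
#' @export
combine_with_ns <- function(lr_dmi, lr_ns) {
  if (any(lr_dmi <= 0) || any(lr_ns <= 0)) {
    stop("likelihood ratios must be positive")
  }
  lr_dmi * lr_ns
}

#' Merge a domain-domain structural LR with the DMI LR
#'
#' When a pair already has a structure-based LR from rigid domain-domain
#' modelling, the larger of that LR and the DMI LR is kept and multiplied
#' with the non-structural evidence.
#'
#' @param lr_struct_orig,lr_dmi Non-negative LRs.
#' @param lr_ns Positive NS LR.
#' @return Final LR.
#' @export
merge_preppi <- function(lr_struct_orig, lr_dmi, lr_ns) {
  if (any(lr_struct_orig < 0) || any(lr_dmi < 0)) {
    stop("structural LRs must be non-negative")
  }
  if (any(lr_ns <= 0)) stop("NS LR must be positive")
  pmax(lr_struct_orig, lr_dmi) * lr_ns
}

#' Posterior interaction probability
#'
#' Posterior odds are the LR times the prior odds; the probability is
#' `odds / (1 + odds)`.  With the default prior odds of 1 interacting pair
#' in 600, an LR of 600 gives probability 0.5.
#'
#' @param lr Non-negative likelihood ratio (vectorized).
#' @param prior_odds Prior odds of interaction.
#' @return Probability in [0, 1).
#' @export
posterior <- function(lr, prior_odds = 1 / 600) {
  if (any(lr < 0)) stop("LR must be non-negative")
  if (prior_odds <= 0) stop("prior odds must be positive")
  odds <- lr * prior_odds
  odds / (1 + odds)
}

#' @rdname posterior
#' @param p Target posterior probability in (0, 1).
#' @return `lr_for_posterior`: the LR at which the posterior reaches `p`.
#' @export
lr_for_posterior <- function(p, prior_odds = 1 / 600) {
  stopifnot(p > 0, p < 1)
  (p / (1 - p)) / prior_odds
}

#' Flag strong predictions
#'
#' Strictly greater than the threshold (default LR 600, i.e. posterior
#' probability above 0.5 under prior odds 1/600).
#'
#' @param lr_final Non-negative final LRs.
#' @param threshold Strong-prediction cutoff.
#' @return Logical vector.
#' @export
flag_strong <- function(lr_final, threshold = 600) {
  if (any(lr_final < 0)) stop("LR must be non-negative")
  lr_final > threshold
}

#' Predict pair interaction LRs from a fitted classifier
#'
#' Scores every match, aggregates per pair under `policy`, multiplies with
#' non-structural evidence (neutral 1 when `ns_table` is `NULL` or the pair
#' is absent) and flags strong predictions.
#'
#' @param object A `dmi_nb` model.
#' @param matches Match table of candidate interfaces to score.
#' @param ns_table Optional [ns_table()] of non-structural LRs.
#' @param policy Per-pair aggregation policy, `"max"` or `"product"`.
#' @param threshold Strong-prediction LR cutoff.
#' @param extra_pairs Optional two-column data.frame of pairs to score even
#'   when they have no match (they get the neutral LR 1 times NS evidence);
#'   used to keep evaluation denominators fixed.
#' @param ... Unused.
#' @return Data.frame with columns `protein_a`, `protein_b`, `lr_dmi`,
#'   `lr_ns`, `lr_final`, `strong`.
#' @export
predict.dmi_nb <- function(object, matches, ns_table = NULL,
                           policy = c("max", "product"), threshold = 600,
                           extra_pairs = NULL, ...) {
  policy <- match.arg(policy)
  if (nrow(matches) > 0) {
    lr <- score_matches(object, matches)
    key <- pair_key(matches$protein_a, matches$protein_b)
    agg <- tapply(lr, key, aggregate_pair, policy = policy)
    pred <- data.frame(key = names(agg), lr_dmi = as.numeric(agg),
                       stringsAsFactors = FALSE)
  } else {
    pred <- data.frame(key = character(), lr_dmi = numeric(),
                       stringsAsFactors = FALSE)
  }
  if (!is.null(extra_pairs) && nrow(extra_pairs) > 0) {
    ek <- pair_key(as.character(extra_pairs[[1]]),
                   as.character(extra_pairs[[2]]))
    missing <- setdiff(ek, pred$key)
    if (length(missing) > 0) {
      pred <- rbind(pred, data.frame(key = missing, lr_dmi = 1,
                                     stringsAsFactors = FALSE))
    }
  }
  ab <- strsplit(pred$key, "|", fixed = TRUE)
  pred$protein_a <- vapply(ab, `[`, "", 1)
  pred$protein_b <- vapply(ab, `[`, "", 2)
  pred$lr_ns <- if (is.null(ns_table)) {
    rep(1, nrow(pred))
  } else {
    ns_lookup(ns_table, pred$protein_a, pred$protein_b)
  }
  # direct product: an LR(DMI) of 0 (clue never seen among true positives)
  # legitimately zeroes the final score
  pred$lr_final <- pred$lr_dmi * pred$lr_ns
  pred$strong <- flag_strong(pred$lr_final, threshold)
  pred <- pred[order(-pred$lr_final), c("protein_a", "protein_b", "lr_dmi",
                                        "lr_ns", "lr_final", "strong")]
  rownames(pred) <- NULL
  pred
}

#' @rdname predict.dmi_nb
#' @param predictions Prediction data.frame.
#' @param path Output TSV path.
#' @export
write_predictions <- function(predictions, path) write_tsv(predictions, path)
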