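# Cross-validated evaluation: fold assignment, ROC and precision-recall.

#' Split a pair set into k folds
#'
#' TP and TN pairs are partitioned independently by a seeded pseudo-random
#' shuffle; fold sizes within each set differ by at most one.  The caller's
#' RNG state is untouched.
#'
#' @param pairs A [pair_set()].
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Object of class `fold_assignment`: list with `k`, `seed`,
#'   `tp_fold` and `tn_fold` (integer fold index per pair, named by pair
#'   key).
#' @export
kfold_split <- function(pairs, k = 5, seed = 1) {
  stopifnot(inherits(pairs, "pair_set"))
  if (k < 2) stop("k must be at least 2")
  if (pairs$N_TP < k || pairs$N_TN < k) {
    stop("each set must have at least k = ", k, " pairs")
  }
  assign_folds <- function(n, s) {
    with_seed(s, sample(rep_len(seq_len(k), n)))
  }
  tp <- assign_folds(pairs$N_TP, sub_seed(seed, "kfold_tp"))
  tn <- assign_folds(pairs$N_TN, sub_seed(seed, "kfold_tn"))
  base::structure(list(
    k = k, seed = seed,
    tp_fold = setNames(tp, pair_key(pairs$positives$protein_a,
                                    pairs$positives$protein_b)),
    tn_fold = setNames(tn, pair_key(pairs$negatives$protein_a,
                                    pairs$negatives$protein_b))),
    class = "fold_assignment")
}

# One threshold sweep shared by roc_curve and pr_curve: thresholds are the
# distinct scores in descending order (tied scores collapse to one step).
sweep_thresholds <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  P <- sum(labels); N <- sum(!labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- which(diff(s) != 0)
  idx <- c(last, length(s))          # last index of each tie group
  tp <- cumsum(y)[idx]
  fp <- cumsum(!y)[idx]
  data.frame(threshold = s[idx],
             tpr = if (P > 0) tp / P else rep(NA_real_, length(idx)),
             fpr = if (N > 0) fp / N else rep(NA_real_, length(idx)),
             precision = tp / (tp + fp),
             recall = if (P > 0) tp / P else rep(NA_real_, length(idx)))
}

#' ROC curve and AUC
#'
#' Thresholds sweep the distinct scores in descending order, tied scores
#' grouped at one threshold; AUC by the trapezoidal rule.  The curve starts
#' at (0, 0) and ends at (1, 1).
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param labels Logical (or 0/1) true labels; both classes must be present.
#' @return List with `points` (threshold, tpr, fpr, precision, recall) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (sum(labels) == 0 || sum(!labels) == 0) {
    stop("both classes must be present")
  }
  pts <- sweep_thresholds(scores, labels)
  fpr <- c(0, pts$fpr); tpr <- c(0, pts$tpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Precision-recall curve and area
#'
#' Same threshold sweep as [roc_curve()]; no interpolation (step curve); the
#' area is the step integral \eqn{\sum_i (R_i - R_{i-1}) P_i} over the
#' threshold steps.
#'
#' @inheritParams roc_curve
#' @return List with `points` and `auprc`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (sum(labels) == 0) stop("at least one positive required")
  pts <- sweep_thresholds(scores, labels)
  rec <- c(0, pts$recall)
  auprc <- sum(diff(rec) * pts$precision)
  list(points = pts, auprc = auprc)
}

#' Cross-validated evaluation of the DMI classifier
#'
#' For each fold, the clue-LR table is fitted on the other `k - 1` folds'
#' pairs and the held-out pairs are scored (pairs with no candidate
#' interface keep the neutral LR 1 so the denominators stay fixed).  Scores
#' are pooled across folds into one ROC and one precision-recall curve.
#'
#' @param matches Match table of candidate interfaces covering the pairs.
#' @param pairs A [pair_set()].
#' @param k Number of folds.
#' @param seed Integer seed for the fold split.
#' @param ns_table Optional [ns_table()] multiplied into the final score.
#' @param policy Per-pair aggregation policy.
#' @param alpha,lr_cap Passed to [dmi_nb()].
#' @return List of class `dmi_cv`: `scores` (data.frame with pair key,
#'   fold, score, label), `roc`, `pr`, `per_fold` (list of per-fold
#'   ROC/PR), `folds`.
#' @export
cross_validate <- function(matches, pairs, k = 5, seed = 1, ns_table = NULL,
                           policy = "max", alpha = 0, lr_cap = 1e6) {
  if (k < 2) stop("k must be at least 2")
  folds <- kfold_split(pairs, k = k, seed = seed)
  mkey <- pair_key(matches$protein_a, matches$protein_b)
  all_scores <- NULL
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr_tp <- pairs$positives[folds$tp_fold != f, , drop = FALSE]
    tr_tn <- pairs$negatives[folds$tn_fold != f, , drop = FALSE]
    te_tp <- pairs$positives[folds$tp_fold == f, , drop = FALSE]
    te_tn <- pairs$negatives[folds$tn_fold == f, , drop = FALSE]
    train_pairs <- pair_set(tr_tp, tr_tn)
    fit <- dmi_nb(matches, train_pairs, alpha = alpha, lr_cap = lr_cap)
    test_pairs <- rbind(te_tp, te_tn)
    te_keys <- pair_key(test_pairs$protein_a, test_pairs$protein_b)
    te_matches <- matches[mkey %in% te_keys, , drop = FALSE]
    pred <- predict(fit, te_matches, ns_table = ns_table, policy = policy,
                    extra_pairs = test_pairs)
    pk <- pair_key(pred$protein_a, pred$protein_b)
    lab <- pk %in% pair_key(te_tp$protein_a, te_tp$protein_b)
    sc <- data.frame(key = pk, fold = f, score = pred$lr_final,
                     label = lab, stringsAsFactors = FALSE)
    per_fold[[f]] <- list(roc = roc_curve(sc$score, sc$label),
                          pr = pr_curve(sc$score, sc$label))
    all_scores <- rbind(all_scores, sc)
  }
  base::structure(list(scores = all_scores,
                       roc = roc_curve(all_scores$score, all_scores$label),
                       pr = pr_curve(all_scores$score, all_scores$label),
                       per_fold = per_fold, folds = folds),
                  class = "dmi_cv")
}

#' @export
print.dmi_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation on %d pairs\n", x$folds$k,
              nrow(x$scores)))
  cat(sprintf("  pooled ROC AUC: %.4f\n", x$roc$auc))
  cat(sprintf("  pooled PR  AUC: %.4f\n", x$pr$auprc))
  invisible(x)
}

#' @rdname cross_validate
#' @param cv A `dmi_cv` object.
#' @param path Output TSV path for the pooled curve points.
#' @export
write_curves <- function(cv, path) {
  write_tsv(cv$roc$points, path)
}
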