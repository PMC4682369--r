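#' Confusion matrix from truth and prediction vectors
#'
#' @param truth,pred Logical vectors (TRUE = positive) of equal length, or
#'   supply counts directly via \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @param tp,fp,tn,fn Direct counts (used when \code{truth} is missing).
#' @return A list of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(truth, pred, tp = NULL, fp = NULL, tn = NULL,
                             fn = NULL) {
  if (missing(truth)) {
    cm <- list(TP = tp, FP = fp, TN = tn, FN = fn)
  } else {
    stopifnot(length(truth) == length(pred))
    cm <- list(TP = sum(truth & pred), FP = sum(!truth & pred),
               TN = sum(!truth & !pred), FN = sum(truth & !pred))
  }
  cm <- lapply(cm, as.numeric)
  class(cm) <- "confusion_matrix"
  cm
}

#' Sensitivity, specificity, accuracy and MCC of a confusion matrix
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total and
#' MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)); MCC is
#' defined as 0 when any factor under the root is 0.
#'
#' @param cm A \code{\link{confusion_matrix}} (or a list with TP/FP/TN/FN).
#' @return Named list with \code{Sn}, \code{Sp}, \code{Acc}, \code{MCC}.
#' @export
classification_metrics <- function(cm) {
  tp <- cm$TP; fp <- cm$FP; tn <- cm$TN; fn <- cm$FN
  total <- tp + fp + tn + fn
  if (total < 1) stop("confusion matrix is empty")
  denom2 <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  list(Sn = if (tp + fn > 0) tp / (tp + fn) else NaN,
       Sp = if (tn + fp > 0) tn / (tn + fp) else NaN,
       Acc = (tp + tn) / total,
       MCC = if (denom2 > 0) (tp * tn - fn * fp) / sqrt(denom2) else 0)
}

#' Remove test fragments homologous to training fragments
#'
#' Ungapped identity between equal-length fragments = fraction of positions
#' with identical symbols (two padding symbols count as a match). Test
#' fragments whose identity to any training fragment reaches the cutoff are
#' dropped.
#'
#' @param test,train Window data frames or fragment vectors.
#' @param identity_cutoff Identity in (0, 1]; 1.0 removes exact duplicates
#'   only.
#' @return The retained subset of \code{test}.
#' @export
homology_filter <- function(test, train, identity_cutoff = 1.0) {
  stopifnot(identity_cutoff > 0, identity_cutoff <= 1)
  test_frags <- as_fragments(test)
  train_frags <- as_fragments(train)
  if (!length(train_frags) || !length(test_frags)) return(test)
  tm <- fragment_matrix(test_frags)
  rm_ <- fragment_matrix(unique(train_frags))
  if (ncol(tm) != ncol(rm_)) stop("test and train fragment lengths differ")
  L <- ncol(tm)
  matches <- matrix(0L, nrow(tm), nrow(rm_))
  for (p in seq_len(L))
    matches <- matches + outer(tm[, p], rm_[, p], `==`)
  keep <- apply(matches / L, 1L, max) < identity_cutoff
  if (is.data.frame(test)) test[keep, , drop = FALSE] else test[keep]
}

#' Repeated stratified k-fold cross-validation
#'
#' Per repeat a fresh seeded stratified partition is drawn; the supplied
#' trainer runs on the training folds only and its predictor is applied to
#' the held-out fold. Fold sizes per class differ by at most one.
#'
#' @param positives,negatives Window data frames or fragment vectors.
#' @param trainer Function \code{(train_pos, train_neg, seed)} returning a
#'   predictor: a function mapping a fragment vector to a logical vector
#'   (TRUE = called positive).
#' @param k Number of folds (default 5).
#' @param repeats Rounds of cross-validation (default 30).
#' @param seed Integer master seed.
#' @return List with \code{average} (metrics averaged over all folds),
#'   \code{by_round} (metrics averaged within each round) and \code{folds}
#'   (one row per fold: counts plus metrics).
#' @export
cross_validate <- function(positives, negatives, trainer, k = 5L,
                           repeats = 30L, seed = 1L) {
  pos <- as_fragments(positives)
  neg <- as_fragments(negatives)
  if (length(pos) < k || length(neg) < k)
    stop("each class must have at least k members")
  rows <- list()
  for (r in seq_len(repeats)) {
    round_seed <- seed + (r - 1L) * 1000L
    set.seed(round_seed)
    fp <- stratified_fold_ids(rep(c(TRUE, FALSE), c(length(pos), length(neg))),
                              k)
    fold_pos <- fp[seq_along(pos)]
    fold_neg <- fp[length(pos) + seq_along(neg)]
    for (f in seq_len(k)) {
      predictor <- trainer(pos[fold_pos != f], neg[fold_neg != f],
                           round_seed + f)
      pred <- predictor(c(pos[fold_pos == f], neg[fold_neg == f]))
      truth <- rep(c(TRUE, FALSE), c(sum(fold_pos == f), sum(fold_neg == f)))
      cm <- confusion_matrix(truth, pred)
      met <- classification_metrics(cm)
      rows[[length(rows) + 1L]] <- data.frame(
        round = r, fold = f, TP = cm$TP, FN = cm$FN, TN = cm$TN, FP = cm$FP,
        Sn = met$Sn, Sp = met$Sp, Acc = met$Acc, MCC = met$MCC)
    }
  }
  folds <- do.call(rbind, rows)
  metric_cols <- c("Sn", "Sp", "Acc", "MCC")
  by_round <- stats::aggregate(folds[metric_cols], list(round = folds$round),
                               mean)
  list(average = as.list(colMeans(folds[metric_cols])),
       by_round = by_round, folds = folds)
}

#' Evaluate a trained model on an independent test set
#'
#' @param model A \code{two_layer_model}.
#' @param positives,negatives Independent test windows or fragments
#'   (disjoint from training; see \code{\link{homology_filter}}).
#' @return List with \code{cm} (confusion matrix) and \code{metrics}.
#' @export
independent_test <- function(model, positives, negatives) {
  pos <- as_fragments(positives)
  neg <- as_fragments(negatives)
  if (!length(pos)) stop("independent test requires a non-empty positive set")
  thr <- model$second_layer$prob_threshold
  pred <- c(predict_prob(model, pos), predict_prob(model, neg)) > thr
  truth <- rep(c(TRUE, FALSE), c(length(pos), length(neg)))
  cm <- confusion_matrix(truth, pred)
  list(cm = cm, metrics = classification_metrics(cm))
}

#' Write a Sn/Sp/Acc/MCC report table
#'
#' @param folds Fold-level data frame (e.g. from \code{\link{cross_validate}}).
#' @param path Output TSV path.
#' @export
write_metrics_report <- function(folds, path) {
  metric_cols <- c("Sn", "Sp", "Acc", "MCC")
  avg <- folds[1, , drop = FALSE]
  for (cl in c("TP", "FN", "TN", "FP", metric_cols))
    avg[[cl]] <- mean(folds[[cl]])
  if ("round" %in% names(avg)) avg$round <- NA
  if ("fold" %in% names(avg)) avg$fold <- NA
  out <- rbind(folds, avg)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
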