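#' Configuration for the two-layer predictor
#'
#' Collects every tunable of the training pipeline with its default.
#'
#' @param w Window half-width (windows are \code{2w+1}-mers).
#' @param scheme Physicochemical group scheme for MDD.
#' @param chi2_cutoff MDD splitting threshold (default 34.3, the
#'   chi-squared 16-df upper 0.005 point).
#' @param min_size Minimum MDD cluster size eligible for division.
#' @param pseudocount Profile-HMM emission pseudocount.
#' @param null Profile-HMM null model ("uniform" or "empirical").
#' @param objective Per-motif threshold calibration objective.
#' @param encoding Fragment encoding for k-means balancing
#'   ("onehot" = per-position 21-symbol indicator, "group" = 5-group
#'   indicator).
#' @param svm_grid Data frame of (C, gamma) values searched for the
#'   second-layer RBF SVM.
#' @param cv_folds Folds of the internal grid-search cross-validation.
#' @param prob_threshold Probability above which a site is called positive.
#' @param seed Integer seed governing every stochastic step.
#' @return A list of class \code{two_layer_config}.
#' @export
two_layer_config <- function(w = 5L, scheme = default_group_scheme(),
                             chi2_cutoff = 34.3, min_size = 30L,
                             pseudocount = 1, null = "uniform",
                             objective = "accuracy", encoding = "onehot",
                             svm_grid = default_svm_grid(), cv_folds = 5L,
                             prob_threshold = 0.5, seed = 1L) {
  cfg <- list(w = w, scheme = scheme, chi2_cutoff = chi2_cutoff,
              min_size = min_size, pseudocount = pseudocount, null = null,
              objective = objective, encoding = encoding,
              svm_grid = svm_grid, cv_folds = cv_folds,
              prob_threshold = prob_threshold, seed = as.integer(seed))
  class(cfg) <- "two_layer_config"
  cfg
}

#' @rdname two_layer_config
#' @export
default_svm_grid <- function() {
  expand.grid(C = 2^seq(-5, 15, by = 4), gamma = 2^seq(-15, 3, by = 4),
              KEEP.OUT.ATTRS = FALSE)
}

#' One-hot encoding of fragments for k-means
#'
#' @param fragments Character vector of equal-length fragments.
#' @param encoding "onehot" (21 symbols per position) or "group" (5 groups
#'   per position; null symbols encode as all-zero).
#' @param scheme Group scheme used when \code{encoding = "group"}.
#' @return Numeric matrix, one row per fragment.
#' @export
encode_fragments <- function(fragments, encoding = c("onehot", "group"),
                             scheme = default_group_scheme()) {
  encoding <- match.arg(encoding)
  fm <- fragment_matrix(as_fragments(fragments))
  L <- ncol(fm)
  if (encoding == "onehot") {
    levels <- AA_SYMBOLS
    codes <- matrix(match(fm, levels), nrow = nrow(fm))
  } else {
    levels <- GROUP_LEVELS
    codes <- matrix(match(unname(scheme[fm]), levels), nrow = nrow(fm))
  }
  k <- length(levels)
  out <- matrix(0, nrow = nrow(fm), ncol = L * k)
  for (p in seq_len(L)) {
    idx <- codes[, p]
    ok <- !is.na(idx)
    out[cbind(which(ok), (p - 1L) * k + idx[ok])] <- 1
  }
  out
}

#' Balance the negative class by k-means undersampling
#'
#' Encodes the negative fragments numerically, clusters them into
#' \code{n_target} k-means clusters, and keeps one representative per
#' cluster (the member nearest its centroid). Empty clusters are backfilled
#' with the unchosen fragments nearest their own centroids, so the output
#' size is exactly \code{n_target}.
#'
#' @param negatives Negative windows (data frame) or fragment vector.
#' @param n_target Number of negatives to keep (usually the positive count).
#' @param encoding,scheme See \code{\link{encode_fragments}}.
#' @param seed Integer seed for the k-means initialization.
#' @return The selected subset of \code{negatives} (same type as the input).
#' @export
kmeans_balance <- function(negatives, n_target, encoding = "onehot",
                           scheme = default_group_scheme(), seed = 1L) {
  frags <- as_fragments(negatives)
  n <- length(frags)
  if (n_target > n)
    stop("n_target (", n_target, ") exceeds the number of negatives (", n, ")")
  if (n_target == n) return(negatives)
  first_idx <- which(!duplicated(frags))
  if (length(first_idx) < n_target)
    stop("fewer distinct negative fragments (", length(first_idx),
         ") than n_target (", n_target, ")")
  X <- encode_fragments(frags[first_idx], encoding, scheme)
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(X, centers = n_target, iter.max = 25L, nstart = 1L,
                  algorithm = "Lloyd"))
  d2 <- rowSums((X - km$centers[km$cluster, , drop = FALSE])^2)
  chosen <- integer()
  for (cl in seq_len(n_target)) {
    members <- which(km$cluster == cl)
    if (length(members))
      chosen <- c(chosen, members[which.min(d2[members])])
  }
  if (length(chosen) < n_target) {
    rest <- setdiff(order(d2), chosen)
    chosen <- c(chosen, rest[seq_len(n_target - length(chosen))])
  }
  sel <- sort(first_idx[chosen])
  if (is.data.frame(negatives)) negatives[sel, , drop = FALSE] else negatives[sel]
}

#' Bit-score feature vectors from the motif HMM layer
#'
#' @param fragments Fragments of length \code{2w+1}.
#' @param model A \code{two_layer_model} (or its \code{hmms} list).
#' @return Numeric matrix, one row per fragment, one column per motif HMM in
#'   fixed OGT1..OGTk order.
#' @export
featureize <- function(fragments, model) {
  hmms <- if (inherits(model, "two_layer_model")) model$hmms else model
  frags <- as_fragments(fragments)
  F <- vapply(hmms, function(h) score_phmm(h$model, frags),
              numeric(length(frags)))
  F <- matrix(F, nrow = length(frags),
              dimnames = list(NULL, unname(vapply(hmms, `[[`, "", "leaf_id"))))
  F
}

# RBF decision values from stored support vectors:
# f(x) = sum_i coef_i * exp(-gamma ||sv_i - x||^2) - rho
svm_decision <- function(layer, X) {
  SV <- layer$SV
  d2 <- outer(rowSums(X^2), rowSums(SV^2), `+`) - 2 * X %*% t(SV)
  K <- exp(-layer$gamma * pmax(d2, 0))
  as.vector(K %*% layer$coefs) - layer$rho
}

second_layer_prob <- function(layer, X) {
  dv <- svm_decision(layer, X)
  if (layer$flip) dv <- -dv
  stats::plogis(layer$platt[1] + layer$platt[2] * dv)
}

stratified_fold_ids <- function(y, k) {
  ids <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    ids[idx] <- rep_len(seq_len(k), length(idx))
  }
  ids
}

#' Train the second-layer RBF SVM on bit-score features
#'
#' Grid-searches (C, gamma) by seeded stratified cross-validated accuracy
#' (ties: smaller C, then smaller gamma), refits on all data, and fits a
#' Platt-style logistic probability map on out-of-fold decision values.
#'
#' @param pos_features,neg_features Feature matrices from
#'   \code{\link{featureize}}.
#' @param grid Data frame of candidate (C, gamma) pairs.
#' @param cv_folds Number of cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @param prob_threshold Decision threshold on the probability scale.
#' @return A list of class \code{second_layer} with the support vectors,
#'   kernel parameters and calibration map.
#' @export
train_second_layer <- function(pos_features, neg_features,
                               grid = default_svm_grid(), cv_folds = 5L,
                               seed = 1L, prob_threshold = 0.5) {
  if (!nrow(pos_features) || !nrow(neg_features))
    stop("both classes must be non-empty")
  X <- rbind(pos_features, neg_features)
  y <- factor(rep(c("pos", "neg"), c(nrow(pos_features), nrow(neg_features))),
              levels = c("neg", "pos"))
  grid <- grid[order(grid$C, grid$gamma), , drop = FALSE]
  set.seed(seed)
  fold <- stratified_fold_ids(y, cv_folds)
  acc <- vapply(seq_len(nrow(grid)), function(gi) {
    hits <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr],
                        type = "C-classification", kernel = "radial",
                        cost = grid$C[gi], gamma = grid$gamma[gi],
                        scale = FALSE)
      hits <- hits + sum(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
    }
    hits / length(y)
  }, numeric(1))
  best <- which.max(acc)  # grid sorted: ties take smaller C then gamma
  C <- grid$C[best]; gamma <- grid$gamma[best]

  fit <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  layer <- list(C = C, gamma = gamma,
                SV = unname(as.matrix(fit$SV)),
                coefs = as.vector(fit$coefs), rho = fit$rho,
                flip = FALSE, platt = c(0, 1),
                prob_threshold = prob_threshold,
                grid_accuracy = data.frame(grid, accuracy = acc))
  class(layer) <- "second_layer"

  # out-of-fold decision values for Platt calibration
  dv_oof <- numeric(length(y))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    ffit <- e1071::svm(X[tr, , drop = FALSE], y[tr],
                       type = "C-classification", kernel = "radial",
                       cost = C, gamma = gamma, scale = FALSE)
    flayer <- list(SV = unname(as.matrix(ffit$SV)),
                   coefs = as.vector(ffit$coefs), rho = ffit$rho,
                   gamma = gamma)
    dv_oof[!tr] <- svm_decision(flayer, X[!tr, , drop = FALSE])
  }
  layer$flip <- mean(dv_oof[y == "pos"]) < mean(dv_oof[y == "neg"])
  odv <- if (layer$flip) -dv_oof else dv_oof
  cal <- suppressWarnings(
    stats::glm((y == "pos") ~ odv, family = stats::binomial()))
  layer$platt <- unname(stats::coef(cal))
  layer
}

#' Train the full two-layer O-GlcNAcylation site predictor
#'
#' Pipeline: MDD clustering of the positives into motif subgroups; one
#' profile HMM per subgroup with a calibrated bit-score threshold; k-means
#' undersampling of the negatives to the positive count; bit-score feature
#' vectors for both classes; RBF-SVM second layer with probability output.
#'
#' @param positives,negatives Labeled windows (data frames) or fragment
#'   vectors.
#' @param config A \code{\link{two_layer_config}}.
#' @return A \code{two_layer_model}.
#' @export
train_two_layer <- function(positives, negatives, config = two_layer_config()) {
  pos <- as_fragments(positives)
  neg <- as_fragments(negatives)
  if (length(neg) < length(pos))
    stop("need at least as many negatives as positives")
  tree <- mdd_cluster(pos, config$scheme, config$w, config$chi2_cutoff,
                      config$min_size)
  leaves <- mdd_leaves(tree)
  bal <- as_fragments(kmeans_balance(neg, length(pos), config$encoding,
                                     config$scheme, config$seed))
  hmms <- lapply(leaves, function(leaf) {
    m <- build_phmm(leaf$fragments, pseudocount = config$pseudocount,
                    null = config$null)
    thr <- calibrate_threshold(m, leaf$fragments, bal, config$objective)
    list(leaf_id = leaf$leaf_id, model = m, threshold = thr)
  })
  pos_feat <- featureize(pos, hmms)
  neg_feat <- featureize(bal, hmms)
  second <- train_second_layer(pos_feat, neg_feat, config$svm_grid,
                               config$cv_folds, config$seed,
                               config$prob_threshold)
  model <- list(
    w = config$w, scheme = config$scheme, tree = tree, hmms = hmms,
    second_layer = second, config = config,
    metadata = list(format_version = "1.0", n_pos = length(pos),
                    n_neg = length(neg), n_balanced = length(bal),
                    leaf_sizes = vapply(leaves, function(l)
                      length(l$members), integer(1)),
                    chi2_cutoff = config$chi2_cutoff,
                    min_size = config$min_size, seed = config$seed))
  class(model) <- "two_layer_model"
  model
}

#' @export
print.two_layer_model <- function(x, ...) {
  cat("Two-layer O-GlcNAcylation site predictor\n")
  cat("  motif HMMs:", length(x$hmms),
      paste0("(", paste(names(x$metadata$leaf_sizes),
                        x$metadata$leaf_sizes, sep = "=", collapse = ", "), ")"),
      "\n")
  cat("  SVM: RBF, C =", x$second_layer$C, ", gamma =", x$second_layer$gamma,
      "\n")
  invisible(x)
}

#' Second-layer probability for peptide fragments
#'
#' @param model A \code{two_layer_model}.
#' @param fragments Fragments of the model window length.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_prob <- function(model, fragments) {
  F <- featureize(fragments, model)
  second_layer_prob(model$second_layer, F)
}

#' Predict O-GlcNAcylation sites on protein sequences
#'
#' Scores every Ser/Thr of each input protein: extracts the window, computes
#' motif bit scores, and applies the second layer. A site is positive when
#' the probability strictly exceeds the threshold. The matched motif is the
#' highest-scoring HMM among those exceeding their calibrated thresholds;
#' when none does, the overall best HMM is reported with a '*' suffix.
#'
#' @param object A \code{two_layer_model}.
#' @param records Data frame from \code{\link{read_fasta}} (columns
#'   \code{id}, \code{sequence}) or a single sequence string.
#' @param ... Unused.
#' @return Data frame with columns protein_id, position, residue, fragment,
#'   probability, label, matched_motif, motif_bit_scores.
#' @export
predict.two_layer_model <- function(object, records, ...) {
  if (is.character(records))
    records <- data.frame(id = "query", sequence = records,
                          stringsAsFactors = FALSE)
  wins <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
    extract_windows(records$sequence[i], records$id[i], object$w)))
  if (is.null(wins) || !nrow(wins)) {
    out <- empty_windows()
    out$probability <- numeric(); out$matched_motif <- character()
    out$motif_bit_scores <- character()
    return(out[, c("protein_id", "position", "residue", "fragment",
                   "probability", "label", "matched_motif",
                   "motif_bit_scores")])
  }
  F <- featureize(wins$fragment, object)
  prob <- second_layer_prob(object$second_layer, F)
  thr <- vapply(object$hmms, `[[`, numeric(1), "threshold")
  ids <- vapply(object$hmms, `[[`, "", "leaf_id")
  matched <- vapply(seq_len(nrow(F)), function(r) {
    over <- which(F[r, ] > thr)
    if (length(over)) ids[over[which.max(F[r, over])]]
    else paste0(ids[which.max(F[r, ])], "*")
  }, "")
  data.frame(
    protein_id = wins$protein_id, position = wins$position,
    residue = wins$residue, fragment = wins$fragment,
    probability = prob,
    label = ifelse(prob > object$second_layer$prob_threshold,
                   "positive", "negative"),
    matched_motif = matched,
    motif_bit_scores = apply(round(F, 4), 1L, paste, collapse = ";"),
    stringsAsFactors = FALSE)
}
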