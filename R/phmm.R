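# numeric floor applied to emission/null ratios so that symbols absent from
# both the model and the null (e.g. padding never seen in training) score 0
# rather than 0/0
PHMM_PROB_FLOOR <- 1e-9

#' Build a profile HMM from a gapless fixed-length fragment alignment
#'
#' Match emissions at position p are background-weighted additive estimates,
#' \code{(count(a, p) + pseudocount * null(a)) / (n + pseudocount)}, over the
#' 21-symbol alphabet (20 letters + the padding symbol '-'). Fragments are a
#' gapless fixed-length alignment, so transitions default to match->match
#' with a small fixed leak to insert and delete states.
#'
#' @param fragments Character vector of equal-length fragments (or a window
#'   data frame).
#' @param pseudocount Non-negative pseudocount mass (default 1).
#' @param null Null model: \code{"uniform"} (1/20 per letter, scaled by the
#'   empirical padding frequency for '-') or \code{"empirical"} (symbol
#'   frequencies of \code{background}).
#' @param background Fragments supplying the empirical null (default: the
#'   training fragments themselves).
#' @param insert_leak,delete_leak Match-state transition leak probabilities
#'   (defaults 0; the fixed-length windows make indel states vestigial, and
#'   a zero leak keeps bit scores exactly position-decomposable).
#' @return A \code{profile_hmm} object.
#' @export
build_phmm <- function(fragments, pseudocount = 1, null = c("uniform", "empirical"),
                       background = NULL, insert_leak = 0, delete_leak = 0) {
  fragments <- as_fragments(fragments)
  null <- match.arg(null)
  if (!length(fragments)) stop("need at least one fragment")
  fm <- fragment_matrix(fragments)
  if (any(!fm %in% c(AA_SYMBOLS, UNKNOWN_SYMBOL)))
    stop("fragments contain symbols outside the amino-acid alphabet")
  L <- ncol(fm)
  n <- nrow(fm)

  null_vec <- switch(null,
    uniform = {
      padf <- mean(fm == PAD_SYMBOL)
      stats::setNames(c(rep((1 - padf) / 20, 20), padf), AA_SYMBOLS)
    },
    empirical = {
      bg <- if (is.null(background)) fragments else as_fragments(background)
      bm <- fragment_matrix(bg)
      cnt <- table(factor(bm, levels = AA_SYMBOLS))
      stats::setNames(as.numeric(cnt) / sum(cnt), AA_SYMBOLS)
    })

  emis <- matrix(0, nrow = L, ncol = length(AA_SYMBOLS),
                 dimnames = list(NULL, AA_SYMBOLS))
  for (p in seq_len(L)) {
    cnt <- table(factor(fm[, p], levels = AA_SYMBOLS))
    n_eff <- sum(cnt)  # 'X' carries no count
    emis[p, ] <- (as.numeric(cnt) + pseudocount * null_vec) /
      (n_eff + pseudocount)
  }

  if (insert_leak < 0 || delete_leak < 0 || insert_leak + delete_leak >= 1)
    stop("transition leaks must be non-negative and sum below 1")
  model <- list(
    length = L,
    match_emissions = emis,
    insert_emissions = null_vec,
    transitions = list(mm = 1 - insert_leak - delete_leak,
                       mi = insert_leak, md = delete_leak,
                       ii = 0.1, im = 0.9, dd = 0.1, dm = 0.9),
    null_model = null_vec,
    pseudocount = pseudocount,
    n_train = n
  )
  class(model) <- "profile_hmm"
  model
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("Profile HMM: length", x$length, "| trained on", x$n_train,
      "fragments | pseudocount", x$pseudocount, "\n")
  invisible(x)
}

#' Bit score of fragments against a profile HMM
#'
#' The bit score is \code{log2(P(fragment | model) / P(fragment | null))}.
#' For fragments of the model length the gapless match path gives
#' \code{sum_p log2(e_p(a_p) / null(a_p))} plus the constant match-transition
#' term; this is the fast path used here. Use \code{\link{phmm_forward}} for
#' full forward-algorithm scoring.
#'
#' @param model A \code{profile_hmm}.
#' @param fragments Character vector of fragments of the model length.
#' @return Numeric vector of bit scores.
#' @export
score_phmm <- function(model, fragments) {
  fragments <- as_fragments(fragments)
  if (!length(fragments)) return(numeric())
  fm <- fragment_matrix(fragments)
  if (ncol(fm) != model$length)
    stop("fragment length (", ncol(fm), ") differs from model length (",
         model$length, "); use phmm_forward() for unequal lengths")
  bad <- setdiff(unique(as.vector(fm)), c(AA_SYMBOLS, UNKNOWN_SYMBOL))
  if (length(bad))
    stop("fragments contain symbols outside the model alphabet: ",
         paste(bad, collapse = ", "))
  lo <- log2(pmax(model$match_emissions, PHMM_PROB_FLOOR))
  lo <- sweep(lo, 2L, log2(pmax(model$null_model, PHMM_PROB_FLOOR)))
  sym_idx <- match(fm, AA_SYMBOLS)  # NA for 'X': uninformative, scores 0
  pos_idx <- rep(seq_len(model$length), each = nrow(fm))
  contrib <- matrix(lo[cbind(pos_idx, sym_idx)], nrow = nrow(fm))
  contrib[is.na(contrib)] <- 0
  tconst <- model$length * log2(model$transitions$mm)
  rowSums(contrib) + tconst
}

#' Forward-algorithm bit score of one fragment
#'
#' Sums over all match/insert/delete state paths of the profile HMM; with a
#' zero transition leak and a fragment of the model length this equals the
#' gapless score of \code{\link{score_phmm}}.
#'
#' @param model A \code{profile_hmm}.
#' @param fragment Single fragment string (any length >= 1).
#' @return Bit score (scalar).
#' @export
phmm_forward <- function(model, fragment) {
  chars <- strsplit(fragment, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c(AA_SYMBOLS, UNKNOWN_SYMBOL)))
    stop("fragment contains symbols outside the model alphabet")
  sym <- match(chars, AA_SYMBOLS)  # NA = 'X', emission cancels in the ratio
  n <- length(sym)
  L <- model$length
  tr <- model$transitions
  l2 <- function(p) ifelse(p > 0, log2(p), -Inf)
  eM <- log2(pmax(model$match_emissions, PHMM_PROB_FLOOR))   # L x 21
  eI <- log2(pmax(model$insert_emissions, PHMM_PROB_FLOOR))  # 21
  # transition log2s; begin state behaves like match state 0
  a_mm <- l2(tr$mm); a_mi <- l2(tr$mi); a_md <- l2(tr$md)
  a_ii <- l2(tr$ii); a_im <- l2(tr$im)
  a_dd <- l2(tr$dd); a_dm <- l2(tr$dm)
  lse <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(-Inf)
    m <- max(x)
    m + log2(sum(2^(x - m)))
  }
  NEG <- -Inf
  # fM[i, k]: log2 prob of emitting first i symbols ending in M_k; similarly I, D
  fM <- matrix(NEG, n + 1L, L + 1L)  # column k+1 is state k
  fI <- matrix(NEG, n + 1L, L + 1L)  # I_0..I_L
  fD <- matrix(NEG, n + 1L, L + 1L)  # D_1..D_L (column 1 unused)
  # initialization: begin = M_0 with probability 1 before any emission
  fM[1L, 1L] <- 0
  # silent delete chain reachable before emissions
  for (k in seq_len(L)) {
    from_m <- fM[1L, k] + a_md
    from_d <- if (k >= 2L) fD[1L, k] + a_dd else NEG
    fD[1L, k + 1L] <- lse(c(from_m, from_d))
  }
  for (i in seq_len(n)) {
    s <- sym[i]
    for (k in 0:L) {
      col <- k + 1L
      if (k >= 1L) {
        prev <- c(fM[i, col - 1L] + a_mm,
                  fI[i, col - 1L] + a_im,
                  if (k >= 2L) fD[i, col - 1L] + a_dm else NEG)
        fM[i + 1L, col] <- lse(prev) + (if (is.na(s)) 0 else eM[k, s])
      }
      prev_i <- c(fM[i + 1L - 1L, col] + a_mi,  # from M_k having emitted i-1
                  fI[i, col] + a_ii)
      fI[i + 1L, col] <- lse(prev_i) + (if (is.na(s)) 0 else eI[s])
    }
    for (k in seq_len(L)) {
      from_m <- fM[i + 1L, k] + a_md
      from_d <- if (k >= 2L) fD[i + 1L, k] + a_dd else NEG
      fD[i + 1L, k + 1L] <- lse(c(from_m, from_d))
    }
  }
  # termination: End reached from M_L (prob 1 - mi), I_L (prob im), D_L (prob 1)
  end_mm <- l2(1 - tr$mi)
  log_fwd <- lse(c(fM[n + 1L, L + 1L] + end_mm,
                   fI[n + 1L, L + 1L] + a_im,
                   fD[n + 1L, L + 1L]))
  log_null <- sum(log2(pmax(model$null_model[sym[!is.na(sym)]],
                            PHMM_PROB_FLOOR)))
  log_fwd - log_null
}

#' Calibrate a bit-score decision threshold for one motif HMM
#'
#' Scans the midpoints of the sorted observed scores and returns the
#' threshold maximizing the objective on the supplied labelled fragments;
#' ties resolve to the smaller threshold (favouring sensitivity).
#'
#' @param model A \code{profile_hmm}.
#' @param positives,negatives Fragment sets (character vectors or window
#'   data frames), both non-empty.
#' @param objective \code{"accuracy"} or \code{"youden"} (Sn + Sp - 1).
#' @return The calibrated threshold (scalar); a fragment is called positive
#'   when its bit score strictly exceeds it.
#' @export
calibrate_threshold <- function(model, positives, negatives,
                                objective = c("accuracy", "youden")) {
  threshold_scan(score_phmm(model, positives),
                 score_phmm(model, negatives), objective)
}

#' @rdname calibrate_threshold
#' @param scores_pos,scores_neg Observed scores of the two classes.
#' @export
threshold_scan <- function(scores_pos, scores_neg,
                           objective = c("accuracy", "youden")) {
  objective <- match.arg(objective)
  sp <- scores_pos; sn <- scores_neg
  if (!length(sp) || !length(sn)) stop("both score sets must be non-empty")
  all_s <- sort(unique(c(sp, sn)))
  cand <- c(all_s[1] - 1,
            if (length(all_s) > 1L) (all_s[-length(all_s)] + all_s[-1]) / 2)
  obj <- vapply(cand, function(thr) {
    tp <- sum(sp > thr); fn <- length(sp) - tp
    tn <- sum(sn <= thr); fp <- length(sn) - tn
    switch(objective,
           accuracy = (tp + tn) / (length(sp) + length(sn)),
           youden = tp / (tp + fn) + tn / (tn + fp) - 1)
  }, numeric(1))
  cand[which.max(obj)]  # first maximum = smallest threshold
}
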