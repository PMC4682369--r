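#' Position-specific amino-acid composition of a fragment set
#'
#' @param fragments Window data frame or fragment vector (equal lengths).
#' @return Matrix of relative frequencies, one row per window offset
#'   (\code{-w..+w}), one column per symbol (20 letters plus the padding
#'   column); each row sums to 1.
#' @export
composition_matrix <- function(fragments) {
  frags <- as_fragments(fragments)
  if (!length(frags)) stop("no fragments")
  fm <- fragment_matrix(frags)
  w <- (ncol(fm) - 1L) %/% 2L
  out <- t(apply(fm, 2L, function(col) {
    cnt <- table(factor(col, levels = AA_SYMBOLS))
    as.numeric(cnt) / sum(cnt)
  }))
  dimnames(out) <- list(as.character(seq(-w, w)), AA_SYMBOLS)
  out
}

#' Residues enriched or depleted around positive sites
#'
#' For every (position, residue) pair, compares the positive-set frequency
#' with the negative-set frequency by a pooled two-proportion z-test and
#' reports pairs with p below \code{alpha}, with the direction of the
#' difference. The padding symbol is excluded. No multiple-testing
#' correction is applied (per-cell display convention of two-sample sequence
#' logos).
#'
#' @param pos,neg Fragment sets (window data frames or vectors).
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns \code{position}, \code{residue},
#'   \code{direction} ("enriched"/"depleted" in the positive set),
#'   \code{p_value}, \code{freq_pos}, \code{freq_neg}.
#' @export
enrichment <- function(pos, neg, alpha = 0.05) {
  pf <- as_fragments(pos)
  nf <- as_fragments(neg)
  if (!length(pf) || !length(nf)) stop("both fragment sets must be non-empty")
  pm <- fragment_matrix(pf)
  nm <- fragment_matrix(nf)
  stopifnot(ncol(pm) == ncol(nm))
  w <- (ncol(pm) - 1L) %/% 2L
  rows <- list()
  for (col in seq_len(ncol(pm))) {
    for (aa in AA_LETTERS) {
      x1 <- sum(pm[, col] == aa); n1 <- nrow(pm)
      x2 <- sum(nm[, col] == aa); n2 <- nrow(nm)
      if (x1 + x2 == 0L || x1 + x2 == n1 + n2) next
      p1 <- x1 / n1; p2 <- x2 / n2
      p_pool <- (x1 + x2) / (n1 + n2)
      z <- (p1 - p2) / sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
      pval <- 2 * stats::pnorm(-abs(z))
      if (pval < alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          position = col - w - 1L, residue = aa,
          direction = if (p1 > p2) "enriched" else "depleted",
          p_value = pval, freq_pos = p1, freq_neg = p2,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(position = integer(), residue = character(),
                      direction = character(), p_value = numeric(),
                      freq_pos = numeric(), freq_neg = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
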