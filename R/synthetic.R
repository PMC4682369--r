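# Synthetic peptide-window generator. Positives are a mixture over motif
# specifications: each motif enforces, with a given probability, a
# physicochemical group at a set of window offsets (the letter is drawn
# uniformly within the group); all unconstrained positions follow the
# background. Negatives are pure background. The generator exists so the
# whole MDD -> profile HMM -> SVM pipeline is testable without any external
# site database.

#' Motif specification for the synthetic generator
#'
#' @param constraints Data frame with columns \code{offset} (nonzero window
#'   offset), \code{group} (group label) and \code{prob} (enforcement
#'   probability in (0, 1]).
#' @param weight Mixture proportion of this motif among positives.
#' @return A list of class \code{motif_spec}.
#' @export
motif_spec <- function(constraints, weight = 1) {
  stopifnot(is.data.frame(constraints),
            all(c("offset", "group", "prob") %in% names(constraints)),
            all(constraints$offset != 0L),
            all(constraints$prob > 0 & constraints$prob <= 1),
            all(constraints$group %in% GROUP_LEVELS))
  structure(list(constraints = constraints, weight = weight),
            class = "motif_spec")
}

#' Dataset specification for the synthetic generator
#'
#' @param n_pos,n_neg Numbers of positive and negative windows.
#' @param motifs List of \code{\link{motif_spec}}s; weights are normalized.
#' @param background "uniform" (each letter 1/20), "natural"
#'   (vertebrate-like composition) or a named probability vector over the
#'   20 letters.
#' @param center_ratio Probability that the centre residue is 'S' (vs 'T').
#' @param w Window half-width.
#' @param seed Integer seed; the generated data are fully determined by it.
#' @return A list of class \code{dataset_spec}.
#' @export
dataset_spec <- function(n_pos, n_neg, motifs = list(),
                         background = "uniform", center_ratio = 0.5,
                         w = 5L, seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  if (n_pos > 0 && !length(motifs))
    motifs <- list(motif_spec(data.frame(offset = -3L, group = "hydrophobic",
                                         prob = 1), weight = 1))
  bg <- background_frequencies(background)
  wts <- vapply(motifs, `[[`, numeric(1), "weight")
  for (i in seq_along(motifs)) motifs[[i]]$weight <- wts[i] / sum(wts)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 motifs = motifs, background = bg,
                 center_ratio = center_ratio, w = as.integer(w),
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

background_frequencies <- function(background) {
  if (is.character(background)) {
    switch(background,
           uniform = stats::setNames(rep(1 / 20, 20), AA_LETTERS),
           natural = natural_aa_frequencies(),
           stop("unknown background preset: ", background))
  } else {
    stopifnot(setequal(names(background), AA_LETTERS))
    background[AA_LETTERS] / sum(background)
  }
}

sample_background_matrix <- function(n, L, bg) {
  matrix(sample(AA_LETTERS, n * L, replace = TRUE, prob = bg),
         nrow = n, ncol = L)
}

#' Generate labeled peptide windows with planted motifs
#'
#' @param spec A \code{\link{dataset_spec}}.
#' @return List with \code{positives} and \code{negatives} (window data
#'   frames) and \code{truth} (integer motif index per positive).
#' @export
generate_windows <- function(spec) {
  set.seed(spec$seed)
  L <- 2L * spec$w + 1L
  center_col <- spec$w + 1L
  scheme <- default_group_scheme()

  make_df <- function(frag_mat, prefix) {
    if (!nrow(frag_mat)) return(empty_windows())
    frags <- apply(frag_mat, 1L, paste, collapse = "")
    data.frame(protein_id = paste0(prefix, seq_len(nrow(frag_mat))),
               position = spec$w + 1L,
               residue = frag_mat[, center_col],
               fragment = frags,
               label = if (prefix == "pos") "positive" else "negative",
               stringsAsFactors = FALSE)
  }

  n_pos <- spec$n_pos
  truth <- integer(0)
  if (n_pos > 0) {
    pm <- sample_background_matrix(n_pos, L, spec$background)
    wts <- vapply(spec$motifs, `[[`, numeric(1), "weight")
    truth <- sample.int(length(spec$motifs), n_pos, replace = TRUE,
                        prob = wts)
    for (mi in seq_along(spec$motifs)) {
      rows <- which(truth == mi)
      cons <- spec$motifs[[mi]]$constraints
      for (ci in seq_len(nrow(cons))) {
        letters_in <- group_letters(scheme, cons$group[ci])
        col <- cons$offset[ci] + spec$w + 1L
        enforce <- rows[stats::runif(length(rows)) < cons$prob[ci]]
        if (length(enforce))
          pm[enforce, col] <- sample(letters_in, length(enforce),
                                     replace = TRUE)
      }
    }
    pm[, center_col] <- ifelse(stats::runif(n_pos) < spec$center_ratio,
                               "S", "T")
  } else pm <- matrix(character(), 0, L)

  if (spec$n_neg > 0) {
    nm <- sample_background_matrix(spec$n_neg, L, spec$background)
    nm[, center_col] <- ifelse(stats::runif(spec$n_neg) < spec$center_ratio,
                               "S", "T")
  } else nm <- matrix(character(), 0, L)

  list(positives = make_df(pm, "pos"), negatives = make_df(nm, "neg"),
       truth = truth)
}

#' Generate whole proteins with planted O-GlcNAcylation sites
#'
#' Background proteins receive \code{sites_per_protein} planted positive
#' windows (generated as in \code{\link{generate_windows}}) at
#' non-overlapping internal positions; every other Ser/Thr is an implicit
#' negative. A matching annotation table is emitted so the full FASTA ->
#' window -> prediction path can be exercised.
#'
#' @param spec A \code{\link{dataset_spec}} (its \code{n_pos} is ignored;
#'   the planted count is \code{n_proteins * sites_per_protein}).
#' @param n_proteins Number of proteins.
#' @param length_range Integer range of protein lengths.
#' @param sites_per_protein Planted positive sites per protein.
#' @return List with \code{records} (data frame id/sequence),
#'   \code{annotations} (protein_id, position, residue, label) and
#'   \code{truth} (motif index per planted site, in annotation order).
#' @export
generate_proteins <- function(spec, n_proteins = 10L,
                              length_range = c(80L, 120L),
                              sites_per_protein = 3L) {
  L <- 2L * spec$w + 1L
  if (min(length_range) < L)
    stop("proteins must be at least one window long")
  planted_spec <- spec
  planted_spec$n_pos <- n_proteins * sites_per_protein
  planted_spec$n_neg <- 0L
  gen <- generate_windows(planted_spec)  # seeds the RNG
  frags <- gen$positives$fragment
  recs <- vector("list", n_proteins)
  anns <- vector("list", n_proteins)
  fi <- 0L
  for (p in seq_len(n_proteins)) {
    len <- sample(seq(min(length_range), max(length_range)), 1L)
    chars <- sample(AA_LETTERS, len, replace = TRUE, prob = spec$background)
    # non-overlapping internal slots, one window apart
    starts <- seq(spec$w + 1L, len - spec$w, by = L)
    centers <- sample(starts, sites_per_protein)
    rows <- list()
    for (cen in sort(centers)) {
      fi <- fi + 1L
      fchars <- strsplit(frags[fi], "", fixed = TRUE)[[1]]
      chars[(cen - spec$w):(cen + spec$w)] <- fchars
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = paste0("prot", p), position = cen,
        residue = fchars[spec$w + 1L], label = "positive",
        stringsAsFactors = FALSE)
    }
    recs[[p]] <- data.frame(id = paste0("prot", p),
                            sequence = paste(chars, collapse = ""),
                            stringsAsFactors = FALSE)
    anns[[p]] <- do.call(rbind, rows)
  }
  list(records = do.call(rbind, recs), annotations = do.call(rbind, anns),
       truth = gen$truth)
}

#' Write generated proteins as FASTA plus annotation TSV
#'
#' @param proteins Result of \code{\link{generate_proteins}}.
#' @param fasta_path,annotation_path Output paths.
#' @export
write_synthetic_dataset <- function(proteins, fasta_path, annotation_path) {
  writeLines(paste0(">", proteins$records$id, "\n", proteins$records$sequence),
             fasta_path)
  utils::write.table(proteins$annotations, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta_path, annotations = annotation_path))
}
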