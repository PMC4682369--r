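#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and any character outside the 20 amino-acid
#' letters is mapped to 'X'. Record ids are taken from the header up to the
#' first whitespace.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A data frame with columns \code{id} and \code{sequence}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (!length(aas)) {
    warning("FASTA file contains no records: ", path)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- toupper(as.character(aas))
  seqs <- vapply(seqs, sanitize_sequence, character(1), USE.NAMES = FALSE)
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

sanitize_sequence <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[!chars %in% AA_LETTERS] <- UNKNOWN_SYMBOL
  paste(chars, collapse = "")
}

#' Read site annotations from a TSV file
#'
#' Expected columns: \code{protein_id}, \code{position} (1-based),
#' \code{residue} ('S' or 'T') and \code{label} ("positive"/"negative").
#' A header row is required; lines starting with '#' are skipped.
#'
#' @param path Path to the annotation table.
#' @return Data frame of annotations.
#' @export
read_site_annotations <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue", "label")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table is missing column(s): ", paste(miss, collapse = ", "))
  ann$position <- as.integer(ann$position)
  ann$residue <- toupper(ann$residue)
  ann
}

#' Extract fixed-length peptide windows centred on given residues
#'
#' One window of length \code{2*w + 1} is produced per occurrence of a centre
#' residue; windows overlapping a terminus are padded with '-'.
#'
#' @param sequence Protein sequence string (or a one-row data frame from
#'   \code{\link{read_fasta}}).
#' @param id Protein identifier recorded with each window.
#' @param w Half-width of the window (default 5, i.e. 11-mers).
#' @param center_residues Characters accepted at the centre (default S and T).
#' @return Data frame with columns \code{protein_id}, \code{position},
#'   \code{residue}, \code{fragment}, \code{label} (initially "unlabeled").
#' @export
#' @examples
#' extract_windows("MKSAPVTR", "p1")$fragment[1]  # "---MKSAPVTR"
extract_windows <- function(sequence, id = "seq", w = 5L,
                            center_residues = c("S", "T")) {
  if (is.data.frame(sequence)) {
    id <- sequence$id[1]
    sequence <- sequence$sequence[1]
  }
  stopifnot(w >= 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pos <- which(chars %in% center_residues)
  if (!length(pos)) {
    return(empty_windows())
  }
  pad <- strrep(PAD_SYMBOL, w)
  padded <- paste0(pad, sequence, pad)
  frags <- substring(padded, pos, pos + 2L * w)
  data.frame(protein_id = id, position = pos, residue = chars[pos],
             fragment = frags, label = "unlabeled",
             stringsAsFactors = FALSE)
}

empty_windows <- function() {
  data.frame(protein_id = character(), position = integer(),
             residue = character(), fragment = character(),
             label = character(), stringsAsFactors = FALSE)
}

#' Label extracted windows from a site-annotation table
#'
#' Windows at annotated positive positions become positives; every other
#' window from the same proteins becomes a negative.
#'
#' @param windows Window data frame from \code{\link{extract_windows}}.
#' @param annotations Annotation data frame (see
#'   \code{\link{read_site_annotations}}); only rows with
#'   \code{label == "positive"} mark positives.
#' @return The window data frame with \code{label} filled in.
#' @export
label_windows <- function(windows, annotations) {
  validate_annotations(windows, annotations)
  pos_ann <- annotations[annotations$label == "positive", , drop = FALSE]
  key <- function(id, p) paste(id, p, sep = "\r")
  is_pos <- key(windows$protein_id, windows$position) %in%
    key(pos_ann$protein_id, pos_ann$position)
  windows$label <- ifelse(is_pos, "positive", "negative")
  windows
}

validate_annotations <- function(windows, annotations) {
  k_w <- paste(windows$protein_id, windows$position, sep = "\r")
  k_a <- paste(annotations$protein_id, annotations$position, sep = "\r")
  idx <- match(k_a, k_w)
  bad <- which(!is.na(idx) &
                 windows$residue[idx] != annotations$residue)
  missing <- which(is.na(idx))
  if (length(bad) || length(missing)) {
    msg <- character()
    if (length(bad))
      msg <- c(msg, paste0("residue mismatch at rows: ",
                           paste(bad, collapse = ", ")))
    if (length(missing))
      msg <- c(msg, paste0("annotated positions absent from window set at rows: ",
                           paste(missing, collapse = ", ")))
    stop("invalid site annotations; ", paste(msg, collapse = "; "))
  }
  invisible(TRUE)
}

#' Remove duplicate fragments within each label class
#'
#' Keeps the first occurrence of each distinct fragment string per class,
#' preserving order. A fragment appearing in both classes is retained in
#' both, with a warning.
#'
#' @param windows Labeled window data frame.
#' @return Deduplicated window data frame.
#' @export
dedupe_windows <- function(windows) {
  if (!nrow(windows)) return(windows)
  keep <- !duplicated(paste(windows$label, windows$fragment, sep = "\r"))
  out <- windows[keep, , drop = FALSE]
  pos_frags <- out$fragment[out$label == "positive"]
  neg_frags <- out$fragment[out$label == "negative"]
  both <- intersect(pos_frags, neg_frags)
  if (length(both))
    warning(length(both),
            " fragment(s) occur in both classes and are kept in both")
  rownames(out) <- NULL
  out
}

#' Write / read plain-text fragment lists (one fragment per line)
#'
#' @param fragments Character vector of fragments.
#' @param path Output path.
#' @export
write_fragments <- function(fragments, path) {
  writeLines(fragments, path)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}
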