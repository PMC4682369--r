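# The 20 standard amino-acid letters, the terminal padding symbol '-',
# and 'X' for unknown residues. '-' is treated as a 21st emittable symbol
# downstream; 'X' belongs to no physicochemical group and is skipped by
# the dependence statistics.
AA_LETTERS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
PAD_SYMBOL <- "-"
UNKNOWN_SYMBOL <- "X"
AA_SYMBOLS <- c(AA_LETTERS, PAD_SYMBOL)

GROUP_LEVELS <- c("polar", "acidic", "basic", "hydrophobic", "aromatic")

#' Default physicochemical grouping of the 20 amino acids
#'
#' Partition of the amino-acid alphabet into the five classes used as the
#' MDD contingency alphabet: polar, acidic, basic, hydrophobic and aromatic.
#' Every letter belongs to exactly one group; the padding symbol and 'X'
#' belong to none and are excluded from all group counts.
#'
#' @return Named character vector mapping each of the 20 letters to a group
#'   label in \code{c("polar","acidic","basic","hydrophobic","aromatic")}.
#' @export
#' @examples
#' default_group_scheme()[["D"]]  # "acidic"
default_group_scheme <- function() {
  c(
    S = "polar", T = "polar", C = "polar", N = "polar", Q = "polar", Y = "polar",
    D = "acidic", E = "acidic",
    H = "basic", K = "basic", R = "basic",
    A = "hydrophobic", G = "hydrophobic", I = "hydrophobic",
    L = "hydrophobic", M = "hydrophobic", P = "hydrophobic", V = "hydrophobic",
    F = "aromatic", W = "aromatic"
  )
}

#' Read a group scheme from a two-column text table
#'
#' @param path Path to a whitespace- or tab-separated file with two columns:
#'   amino-acid letter and group label. Lines starting with '#' are skipped.
#' @return Named character vector as \code{\link{default_group_scheme}}.
#' @export
read_group_scheme <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("letter", "group"))
  scheme <- stats::setNames(tab$group, toupper(tab$letter))
  validate_group_scheme(scheme)
  scheme
}

validate_group_scheme <- function(scheme) {
  if (!setequal(names(scheme), AA_LETTERS))
    stop("group scheme must map exactly the 20 amino-acid letters")
  if (anyDuplicated(names(scheme)))
    stop("group scheme maps a letter more than once")
  bad <- setdiff(unique(scheme), GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (!all(GROUP_LEVELS %in% scheme))
    stop("every group must contain at least one letter")
  invisible(scheme)
}

group_letters <- function(scheme, group) names(scheme)[scheme == group]

# character matrix (n x L) from equal-length fragment strings
fragment_matrix <- function(fragments) {
  if (!length(fragments)) return(matrix(character(), 0, 0))
  L <- unique(nchar(fragments))
  if (length(L) != 1L)
    stop("fragments must all have the same length")
  matrix(unlist(strsplit(fragments, "", fixed = TRUE), use.names = FALSE),
         nrow = length(fragments), ncol = L, byrow = TRUE)
}

# Amino-acid background frequencies (Robinson & Robinson vertebrate-style
# composition), used as the optional "natural" generator background.
natural_aa_frequencies <- function() {
  f <- c(
    A = 0.0780, C = 0.0192, D = 0.0536, E = 0.0629, F = 0.0387,
    G = 0.0738, H = 0.0226, I = 0.0514, K = 0.0574, L = 0.0901,
    M = 0.0224, N = 0.0448, P = 0.0520, Q = 0.0426, R = 0.0512,
    S = 0.0712, T = 0.0585, V = 0.0644, W = 0.0132, Y = 0.0320
  )
  f / sum(f)
}
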