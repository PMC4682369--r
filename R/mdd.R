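#' Encode a fragment as physicochemical group symbols
#'
#' @param fragment Fragment string over the amino-acid alphabet plus 'X'/'-'.
#' @param scheme Group scheme (see \code{\link{default_group_scheme}}).
#' @return Character vector of group labels, one per residue; 'X' and '-'
#'   map to \code{NA} (a null symbol excluded from all counts).
#' @export
group_encode <- function(fragment, scheme = default_group_scheme()) {
  chars <- strsplit(fragment, "", fixed = TRUE)[[1]]
  unname(scheme[chars])
}

# group codes for a set of fragments at one window offset
offset_groups <- function(fragmat, offset, w, scheme) {
  col <- offset + w + 1L
  factor(unname(scheme[fragmat[, col]]), levels = GROUP_LEVELS)
}

#' Group-by-group contingency table between two window positions
#'
#' Counts, over the fragment set, co-occurrences of physicochemical groups at
#' offsets \code{i} and \code{j} relative to the centre. Fragments carrying a
#' null symbol ('X' or '-') at either position are skipped.
#'
#' @param fragments Character vector of equal-length fragments (or a window
#'   data frame with a \code{fragment} column).
#' @param i,j Window offsets in \code{[-w, w]}, both nonzero, \code{i != j}.
#' @param scheme Group scheme.
#' @param w Window half-width; defaults to \code{(L - 1) / 2}.
#' @return 5x5 integer matrix with group-labelled dimnames.
#' @export
contingency <- function(fragments, i, j, scheme = default_group_scheme(),
                        w = NULL) {
  fragments <- as_fragments(fragments)
  fm <- fragment_matrix(fragments)
  if (is.null(w)) w <- (ncol(fm) - 1L) %/% 2L
  if (i == 0L || j == 0L)
    stop("offsets must not address the fixed centre position")
  if (i == j) stop("offsets i and j must differ")
  gi <- offset_groups(fm, i, w, scheme)
  gj <- offset_groups(fm, j, w, scheme)
  table(gi, gj, dnn = NULL)
}

as_fragments <- function(x) {
  if (is.data.frame(x)) x$fragment else x
}

#' Pearson chi-squared statistic of a group contingency table
#'
#' Computes \eqn{\sum_{m,n} (X_{mn} - E_{mn})^2 / E_{mn}} with
#' \eqn{E_{mn} = X_{mR} X_{Cn} / X}; cells with \eqn{E_{mn} = 0} contribute 0.
#'
#' @param table Non-negative count matrix (any dimension).
#' @return The chi-squared statistic (non-negative scalar).
#' @export
chi_square <- function(table) {
  X <- sum(table)
  if (X < 1) stop("contingency table has zero total count")
  E <- outer(rowSums(table), colSums(table)) / X
  ok <- E > 0
  sum((table[ok] - E[ok])^2 / E[ok])
}

#' Chi-squared dependence scan over all position pairs
#'
#' @inheritParams contingency
#' @return Data frame with columns \code{i}, \code{j} (offsets, \code{i < j})
#'   and \code{chi2}; \code{2w(2w-1)/2} rows. Pairs whose table is empty
#'   (all fragments null at a position) score \code{NA}.
#' @export
dependence_scan <- function(fragments, scheme = default_group_scheme(),
                            w = 5L) {
  fragments <- as_fragments(fragments)
  if (length(fragments) < 2L) stop("need at least 2 fragments")
  offs <- setdiff(seq(-w, w), 0L)
  pairs <- utils::combn(offs, 2L)
  fm <- fragment_matrix(fragments)
  gcache <- lapply(offs, function(o) offset_groups(fm, o, w, scheme))
  names(gcache) <- as.character(offs)
  chi2 <- apply(pairs, 2L, function(p) {
    tab <- table(gcache[[as.character(p[1])]],
                 gcache[[as.character(p[2])]], dnn = NULL)
    if (sum(tab) < 1) NA_real_ else chi_square(tab)
  })
  data.frame(i = pairs[1, ], j = pairs[2, ], chi2 = chi2)
}

#' Select the MDD split position and group
#'
#' Aggregates pairwise dependence as \eqn{D_i = \sum_{j \ne i} \chi^2(A_i,
#' A_j)} and splits on \code{i* = argmax D_i} (tie: smallest offset) with the
#' modal group at \code{i*} (tie: fixed group order polar < acidic < basic <
#' hydrophobic < aromatic). No split is proposed when the maximal pairwise
#' statistic does not exceed \code{chi2_cutoff}.
#'
#' @inheritParams dependence_scan
#' @param chi2_cutoff Splitting threshold on the pairwise statistic
#'   (default 34.3, the 16-df upper 0.005 point).
#' @return \code{NULL}, or a list with \code{position}, \code{group},
#'   \code{d_value} (the aggregate at the chosen position) and
#'   \code{max_chi2} (maximal pairwise statistic).
#' @export
choose_split <- function(fragments, scheme = default_group_scheme(), w = 5L,
                         chi2_cutoff = 34.3) {
  fragments <- as_fragments(fragments)
  scan <- dependence_scan(fragments, scheme, w)
  chi2 <- scan$chi2
  if (all(is.na(chi2)) || max(chi2, na.rm = TRUE) <= chi2_cutoff)
    return(NULL)
  offs <- setdiff(seq(-w, w), 0L)
  d <- vapply(offs, function(o) {
    sum(chi2[(scan$i == o | scan$j == o) & !is.na(chi2)])
  }, numeric(1))
  i_star <- offs[which.max(d)]  # which.max takes the first (smallest offset)
  fm <- fragment_matrix(fragments)
  g <- offset_groups(fm, i_star, w, scheme)
  counts <- table(g)  # ordered by GROUP_LEVELS, ties resolved by that order
  group <- names(counts)[which.max(counts)]
  list(position = i_star, group = group,
       d_value = max(d), max_chi2 = max(chi2, na.rm = TRUE))
}

#' Maximal dependence decomposition clustering of positive fragments
#'
#' Recursively partitions the fragment set: at each node the split of
#' \code{\link{choose_split}} divides members into those carrying the chosen
#' group at the chosen position and the complement. A node becomes a leaf
#' when it holds fewer than \code{min_size} members or no position pair shows
#' dependence above the cutoff. Leaves are labelled \code{OGT1..OGTk} in
#' depth-first order, with-branch first.
#'
#' @inheritParams choose_split
#' @param min_size Minimum cluster size eligible for further division
#'   (default 30).
#' @return An \code{mdd_node} tree; leaves carry \code{leaf_id} and member
#'   indices into the input fragment vector.
#' @export
mdd_cluster <- function(fragments, scheme = default_group_scheme(), w = 5L,
                        chi2_cutoff = 34.3, min_size = 30L) {
  fragments <- as_fragments(fragments)
  if (!length(fragments)) stop("no fragments to cluster")
  root <- mdd_split_node(seq_along(fragments), fragments, scheme, w,
                         chi2_cutoff, min_size)
  root <- assign_leaf_ids(root)$node
  attr(root, "fragments") <- fragments
  attr(root, "scheme") <- scheme
  attr(root, "w") <- w
  attr(root, "chi2_cutoff") <- chi2_cutoff
  attr(root, "min_size") <- min_size
  class(root) <- "mdd_node"
  root
}

mdd_split_node <- function(members, fragments, scheme, w, chi2_cutoff,
                           min_size) {
  node <- list(members = members, split_position = NULL, split_group = NULL,
               child_with = NULL, child_without = NULL, leaf_id = NULL)
  if (length(members) < max(min_size, 2L)) return(node)
  split <- choose_split(fragments[members], scheme, w, chi2_cutoff)
  if (is.null(split)) return(node)
  fm <- fragment_matrix(fragments[members])
  g <- offset_groups(fm, split$position, w, scheme)
  has <- !is.na(g) & g == split$group
  if (!any(has) || all(has)) return(node)  # degenerate; cannot partition
  node$split_position <- split$position
  node$split_group <- split$group
  node$max_chi2 <- split$max_chi2
  node$child_with <- mdd_split_node(members[has], fragments, scheme, w,
                                    chi2_cutoff, min_size)
  node$child_without <- mdd_split_node(members[!has], fragments, scheme, w,
                                       chi2_cutoff, min_size)
  node
}

assign_leaf_ids <- function(node, counter = 0L) {
  if (is.null(node$split_position)) {
    counter <- counter + 1L
    node$leaf_id <- paste0("OGT", counter)
    return(list(node = node, counter = counter))
  }
  res <- assign_leaf_ids(node$child_with, counter)
  node$child_with <- res$node
  res <- assign_leaf_ids(node$child_without, res$counter)
  node$child_without <- res$node
  list(node = node, counter = res$counter)
}

#' Leaves of an MDD tree
#'
#' @param tree Result of \code{\link{mdd_cluster}}.
#' @return Named list (by leaf id, in OGT1..OGTk order) of lists with
#'   \code{leaf_id}, \code{members} (indices) and \code{fragments}.
#' @export
mdd_leaves <- function(tree) {
  fragments <- attr(tree, "fragments")
  out <- list()
  walk <- function(node) {
    if (is.null(node$split_position)) {
      out[[node$leaf_id]] <<- list(leaf_id = node$leaf_id,
                                   members = node$members,
                                   fragments = fragments[node$members])
      return(invisible())
    }
    walk(node$child_with)
    walk(node$child_without)
  }
  walk(tree)
  out[order(as.integer(sub("^OGT", "", names(out))))]
}

#' @export
print.mdd_node <- function(x, ...) {
  cat("MDD tree over", length(attr(x, "fragments")), "fragments\n")
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is.null(node$split_position)) {
      cat(pad, node$leaf_id, " (n=", length(node$members), ")\n", sep = "")
    } else {
      cat(pad, "split: ", node$split_group, " @ ", node$split_position,
          " (n=", length(node$members), ")\n", sep = "")
      rec(node$child_with, indent + 1L)
      rec(node$child_without, indent + 1L)
    }
  }
  rec(x, 0L)
  invisible(x)
}

# plain-list rendering of the tree for JSON serialization
mdd_tree_to_list <- function(node, fragments = attr(node, "fragments"),
                             keep_fragments = TRUE) {
  if (is.null(node$split_position)) {
    out <- list(leaf_id = node$leaf_id, n = length(node$members))
    if (keep_fragments) out$fragments <- fragments[node$members]
    return(out)
  }
  list(split_position = node$split_position,
       split_group = node$split_group,
       n = length(node$members),
       child_with = mdd_tree_to_list(node$child_with, fragments, keep_fragments),
       child_without = mdd_tree_to_list(node$child_without, fragments,
                                        keep_fragments))
}

#' Serialize an MDD tree to JSON
#'
#' @param tree Result of \code{\link{mdd_cluster}}.
#' @param path Output path.
#' @param keep_fragments Include leaf member fragments (default TRUE).
#' @export
write_mdd_tree <- function(tree, path, keep_fragments = TRUE) {
  jsonlite::write_json(mdd_tree_to_list(tree, keep_fragments = keep_fragments),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
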