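#' Feature region of a mechanism label
#'
#' The region of a label is the set of signature columns carried by at
#' least one of its enzymes (a union, not an intersection: a label whose
#' enzymes fall into disjoint signature groups still has a well-defined,
#' composite region). The region decomposes into sub-regions via
#' [sub_subspaces()].
#'
#' @param matrix an [annotation_matrix()].
#' @param labels a [label_assignment()].
#' @param label a mechanism label present in `labels`.
#' @return A list of class `mech_region` with `label`, `features`
#'   (character vector of column identifiers), `sub_regions` (list of
#'   disjoint feature sets whose union is `features`) and `empty_enzymes`
#'   (identifiers of member enzymes carrying no signature at all).
#' @export
label_region <- function(matrix, labels, label) {
  members <- label_members(labels, label)
  cells <- unclass(matrix)[members, , drop = FALSE]
  features <- colnames(cells)[colSums(cells) > 0L]
  sub <- sub_subspaces(matrix, labels, label)
  structure(list(label = label,
                 features = features,
                 sub_regions = sub,
                 empty_enzymes = members[rowSums(cells) == 0L]),
            class = "mech_region")
}

label_members <- function(labels, label) {
  members <- names(labels)[vapply(labels, function(s) label %in% s,
                                  logical(1L))]
  if (length(members) == 0L) {
    stop(sprintf("unknown mechanism label: %s", label), call. = FALSE)
  }
  members
}

#' Disjoint sub-subspaces of a label's region
#'
#' Builds a graph on the label's enzymes with an edge whenever two
#' enzymes' signature sets intersect, and returns one feature set per
#' connected component (the union over the component's enzymes). Two or
#' more components indicate a composite region: the label is carried by
#' groups of enzymes with mutually non-overlapping signatures. Enzymes
#' carrying no signatures at all join no component and contribute no
#' sub-region.
#'
#' @inheritParams label_region
#' @return A list of disjoint, non-empty character vectors of column
#'   identifiers, ordered by first enzyme appearance.
#' @export
sub_subspaces <- function(matrix, labels, label) {
  members <- label_members(labels, label)
  cells <- unclass(matrix)[members, , drop = FALSE]
  nonempty <- rowSums(cells) > 0L
  cells <- cells[nonempty, , drop = FALSE]
  if (nrow(cells) == 0L) return(list())
  # adjacency: enzymes whose signature sets intersect share a component
  shared <- tcrossprod(cells) > 0L
  g <- igraph::graph_from_adjacency_matrix(shared, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  lapply(unique(comp), function(k) {
    sub <- cells[comp == k, , drop = FALSE]
    colnames(sub)[colSums(sub) > 0L]
  })
}

#' Pairwise region overlap report
#'
#' Scores every unordered pair of mechanism labels by the Jaccard index of
#' their regions' feature sets, and lists the completely overlapping pairs:
#' pairs of non-empty regions with identical feature sets (Jaccard exactly
#' 1). Such pairs are indistinguishable in the feature space, which bounds
#' what any annotation-based classifier can achieve. The Jaccard index of
#' two empty regions is reported as `NA` and never counts as complete
#' overlap.
#'
#' @param matrix an [annotation_matrix()].
#' @param labels a [label_assignment()] using at least two labels.
#' @param min_jaccard report only pairs with Jaccard index at or above
#'   this threshold (default 0: report all).
#' @return A list of class `overlap_report` with `pairwise` (a
#'   `data.frame` with columns `label_a`, `label_b`, `jaccard`,
#'   `complete`), `complete_pairs` (two-column character matrix) and
#'   `shared_features` (list keyed `"A|B"` holding each complete pair's
#'   common feature set), plus `empty_labels`.
#' @export
#'
#' @examples
#' sim <- generate_annotation(generator_config())
#' rep <- overlap_report(sim$matrix, sim$labels)
#' rep$complete_pairs
#' lengths(rep$shared_features)  # 4 shared signatures
overlap_report <- function(matrix, labels, min_jaccard = 0) {
  labs <- label_space(labels)
  if (length(labs) < 2L) {
    stop("overlap report needs at least two labels", call. = FALSE)
  }
  feats <- lapply(labs, function(lb) {
    members <- label_members(labels, lb)
    cells <- unclass(matrix)[members, , drop = FALSE]
    colnames(cells)[colSums(cells) > 0L]
  })
  names(feats) <- labs

  pairs <- utils::combn(labs, 2L)
  jac <- vapply(seq_len(ncol(pairs)), function(k) {
    jaccard_index(feats[[pairs[1L, k]]], feats[[pairs[2L, k]]])
  }, numeric(1L))
  complete <- !is.na(jac) & jac == 1
  pairwise <- data.frame(label_a = pairs[1L, ], label_b = pairs[2L, ],
                         jaccard = jac, complete = complete,
                         stringsAsFactors = FALSE)
  keep <- is.na(pairwise$jaccard) | pairwise$jaccard >= min_jaccard
  shared <- lapply(which(complete), function(k) feats[[pairs[1L, k]]])
  names(shared) <- paste(pairs[1L, complete], pairs[2L, complete], sep = "|")
  structure(list(pairwise = pairwise[keep, , drop = FALSE],
                 complete_pairs = cbind(label_a = pairs[1L, complete],
                                        label_b = pairs[2L, complete]),
                 shared_features = shared,
                 empty_labels = labs[lengths(feats) == 0L]),
            class = "overlap_report")
}

#' Jaccard index of two feature sets
#'
#' `|A intersect B| / |A union B|`; `NA` when both sets are empty.
#'
#' @param a,b character vectors (treated as sets).
#' @return A fraction in `[0, 1]`, or `NA`.
#' @export
jaccard_index <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0L) return(NA_real_)
  length(intersect(a, b)) / length(u)
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d pair(s), %d complete overlap(s)\n",
              nrow(x$pairwise), nrow(x$complete_pairs)))
  invisible(x)
}
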