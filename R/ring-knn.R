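#' Build a classification dictionary
#'
#' The dictionary is the classifier's memory: every training enzyme's
#' binary signature vector is stored together with its label set, and a
#' query is classified by looking up its closest stored point(s).
#'
#' @param matrix an [annotation_matrix()].
#' @param labels a [label_assignment()] covering every row of `matrix`.
#' @return A list of class `mech_dictionary`.
#' @export
dictionary <- function(matrix, labels) {
  missing <- setdiff(rownames(matrix), names(labels))
  if (length(missing) > 0L) {
    stop(sprintf("no label entry for enzyme '%s'", missing[1L]), call. = FALSE)
  }
  structure(list(matrix = matrix, labels = labels),
            class = "mech_dictionary")
}

#' Squared Euclidean distance between binary vectors
#'
#' On \eqn{\{0,1\}^L} the squared Euclidean distance equals the Hamming
#' distance: the number of positions at which the two vectors differ. It is
#' always a small non-negative integer for sparse annotation vectors.
#'
#' @param a,b binary vectors of equal length.
#' @return Non-negative integer.
#' @export
#'
#' @examples
#' squared_distance(c(0, 0, 0, 0), c(1, 1, 1, 1))  # 4
squared_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("length mismatch: %d vs %d", length(a), length(b)),
         call. = FALSE)
  }
  d <- as.integer(a) - as.integer(b)
  as.integer(sum(d * d))  # exact: entries are -1/0/1
}

# squared distances from one query vector to every dictionary row
row_distances <- function(query, cells) {
  if (length(query) != ncol(cells)) {
    stop(sprintf("query length %d does not match dictionary width %d",
                 length(query), ncol(cells)), call. = FALSE)
  }
  q <- as.integer(query)
  # |x - q|^2 = rowSums(x) + sum(q) - 2 x.q  on binary vectors
  as.integer(rowSums(cells) + sum(q) - 2L * drop(cells %*% q))
}

#' Ring of nearest neighbours
#'
#' Returns all dictionary rows tied at the minimum squared distance from
#' the query, in dictionary row order. Because annotation vectors are
#' sparse and integer-valued, ties at the minimum distance are common, and
#' the full equidistant ring (not an arbitrary single neighbour) is the
#' classification unit.
#'
#' @param query binary vector of length `ncol` of the dictionary matrix.
#' @param dict a [dictionary()].
#' @param exclude optional enzyme identifier to leave out (for
#'   leave-one-out evaluation).
#' @return A list with `members` (character vector of enzyme identifiers)
#'   and `distance` (integer).
#' @export
nearest_ring <- function(query, dict, exclude = NULL) {
  cells <- unclass(dict$matrix)
  if (!is.null(exclude)) {
    keep <- rownames(cells) != exclude
    if (!any(keep)) stop("dictionary is empty after exclusion", call. = FALSE)
    cells <- cells[keep, , drop = FALSE]
  }
  if (nrow(cells) == 0L) stop("dictionary is empty", call. = FALSE)
  d <- row_distances(query, cells)
  dmin <- min(d)
  list(members = rownames(cells)[d == dmin], distance = as.integer(dmin))
}

#' Ring voting over label sets
#'
#' Each ring member votes with its full label set; the most frequent
#' distinct label set wins. Ties between equally frequent label sets are
#' broken deterministically in favour of the set that is smallest by
#' cardinality, then first by lexicographic order of its sorted labels.
#'
#' @param members character vector of ring member identifiers.
#' @param labels a [label_assignment()].
#' @return Character vector: the winning label set (sorted).
#' @export
#'
#' @examples
#' la <- label_assignment(list(e1 = "A", e2 = "B", e3 = "B"))
#' ring_vote(c("e1", "e2", "e3"), la)  # "B"
ring_vote <- function(members, labels) {
  if (length(members) == 0L) stop("ring is empty", call. = FALSE)
  missing <- setdiff(members, names(labels))
  if (length(missing) > 0L) {
    stop(sprintf("no label entry for ring member '%s'", missing[1L]),
         call. = FALSE)
  }
  sets <- labels[members]
  keys <- vapply(sets, label_set_key, character(1L))
  tab <- table(keys)
  winners <- names(tab)[tab == max(tab)]
  strsplit(tie_break_sets(winners), ";", fixed = TRUE)[[1L]]
}

# deterministic tie-break over canonical ";"-joined label-set keys:
# smallest cardinality first, then lexicographic order
tie_break_sets <- function(keys) {
  card <- lengths(strsplit(keys, ";", fixed = TRUE))
  keys[order(card, keys)][1L]
}

#' Classify a query vector against a dictionary
#'
#' Finds the ring of nearest neighbours and assigns the label set that is
#' most common within the ring (see [ring_vote()]).
#'
#' @inheritParams nearest_ring
#' @return A [mech_prediction()] carrying the winning label set, the ring
#'   distance and the ring member identifiers.
#' @export
classify <- function(query, dict, exclude = NULL) {
  ring <- nearest_ring(query, dict, exclude = exclude)
  mech_prediction(labels = ring_vote(ring$members, dict$labels),
                  ring_distance = ring$distance,
                  ring_members = ring$members)
}

# per-label (binary relevance style) vote: labels carried by a strict
# majority of ring members; if no label reaches a majority, the labels with
# the maximum count are assigned
per_label_vote <- function(members, labels) {
  if (length(members) == 0L) stop("ring is empty", call. = FALSE)
  votes <- table(unlist(labels[members], use.names = FALSE))
  majority <- names(votes)[votes > length(members) / 2]
  if (length(majority) > 0L) return(sort(majority))
  sort(names(votes)[votes == max(votes)])
}

#' Leave-one-out evaluation of the ring classifier
#'
#' Each enzyme in turn is removed from the dictionary and classified
#' against the remaining rows; the per-enzyme outcomes and the overall
#' success rate are reported.
#'
#' @param dict a [dictionary()] with at least two rows.
#' @param criterion `"exact"` (success iff the predicted label set equals
#'   the true set) or `"overlap"` (success iff the sets share at least one
#'   label).
#' @param vote `"set"` (whole label sets vote; default) or `"per-label"`
#'   (each label votes individually, binary-relevance style).
#' @return A list of class `loo_report` with `per_enzyme` (a `data.frame`
#'   with columns `enzyme_id`, `true_labels`, `predicted_labels`,
#'   `ring_distance`, `ring_size`, `success`) and `success_rate`.
#' @export
#'
#' @examples
#' sim <- generate_annotation(generator_config())
#' rep <- loo_evaluate(dictionary(sim$matrix, sim$labels))
#' rep$success_rate
loo_evaluate <- function(dict, criterion = c("exact", "overlap"),
                         vote = c("set", "per-label")) {
  criterion <- match.arg(criterion)
  vote <- match.arg(vote)
  cells <- unclass(dict$matrix)
  n <- nrow(cells)
  if (n < 2L) stop("leave-one-out needs at least two rows", call. = FALSE)
  ids <- rownames(cells)

  # full pairwise squared distances in one integer-exact matrix product
  rs <- rowSums(cells)
  d2 <- outer(rs, rs, "+") - 2L * tcrossprod(cells)
  diag(d2) <- NA_integer_

  out <- vector("list", n)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    dmin <- min(di, na.rm = TRUE)
    members <- ids[!is.na(di) & di == dmin]
    pred <- if (vote == "set") ring_vote(members, dict$labels)
            else per_label_vote(members, dict$labels)
    truth <- dict$labels[[ids[i]]]
    success <- if (criterion == "exact") setequal(pred, truth)
               else length(intersect(pred, truth)) > 0L
    out[[i]] <- data.frame(enzyme_id = ids[i],
                           true_labels = label_set_key(truth),
                           predicted_labels = label_set_key(pred),
                           ring_distance = as.integer(dmin),
                           ring_size = length(members),
                           success = success,
                           stringsAsFactors = FALSE)
  }
  per_enzyme <- do.call(rbind, out)
  structure(list(per_enzyme = per_enzyme,
                 success_rate = mean(per_enzyme$success),
                 criterion = criterion, vote = vote),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf("<loo_report> n=%d criterion=%s vote=%s success_rate=%.4f\n",
              nrow(x$per_enzyme), x$criterion, x$vote, x$success_rate))
  invisible(x)
}
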