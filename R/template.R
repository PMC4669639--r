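#' Build a template library from a dictionary
#'
#' Collapses the dictionary's rows onto their distinct binary patterns.
#' Each template records every label set observed with that pattern and
#' the contributing enzyme identifiers, turning the annotation matrix into
#' a look-up table: a novel enzyme whose signature vector matches a
#' template inherits the template's candidate mechanisms.
#'
#' @param dict a [dictionary()].
#' @return A list of class `template_library` with components `patterns`
#'   (distinct-pattern matrix, one row per template), `label_sets` (list:
#'   per template, the distinct label sets observed, each a character
#'   vector) and `provenance` (list: per template, the contributing enzyme
#'   identifiers).
#' @export
#'
#' @examples
#' sim <- generate_annotation(generator_config())
#' lib <- build_templates(dictionary(sim$matrix, sim$labels))
#' nrow(lib$patterns)  # distinct signature patterns
build_templates <- function(dict) {
  cells <- unclass(dict$matrix)
  if (nrow(cells) == 0L) stop("dictionary is empty", call. = FALSE)
  key <- apply(cells, 1L, paste, collapse = "")
  first <- !duplicated(key)
  patterns <- cells[first, , drop = FALSE]
  rownames(patterns) <- NULL
  idx <- match(key, key[first])
  provenance <- split(rownames(cells), idx)
  label_sets <- lapply(provenance, function(ids) {
    sets <- dict$labels[ids]
    sets[!duplicated(vapply(sets, label_set_key, character(1L)))]
  })
  structure(list(patterns = patterns,
                 label_sets = unname(label_sets),
                 provenance = unname(provenance)),
            class = "template_library")
}

#' Match a query vector against a template library
#'
#' Computes the squared distance from the query to every template and
#' reports all candidate label sets within the distance threshold, sorted
#' by distance then by the deterministic label-set tie-break (cardinality,
#' then lexicographic). The verdict is `"exact"` when the best distance is
#' 0, `"none"` when it exceeds the threshold (the query enzyme may carry
#' none of the library's known mechanisms), and `"near"` otherwise. The
#' default threshold 0 makes matching a strict look-up.
#'
#' @param query binary vector of length `ncol(library$patterns)`.
#' @param library a [build_templates()] result.
#' @param threshold non-negative integer distance cut-off (default 0);
#'   `Inf` reports every template.
#' @return A list of class `match_result` with `verdict`, `best_distance`,
#'   `candidates` (a `data.frame` with columns `labels` (`";"`-joined),
#'   `distance`, `template`) and `threshold`.
#' @export
match_templates <- function(query, library, threshold = 0L) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  d <- row_distances(query, library$patterns)
  best <- min(d)
  verdict <- if (best == 0L) "exact" else if (best > threshold) "none"
             else "near"
  keep <- which(d <= threshold | d == best)  # best kept even under "none"
  cand <- do.call(rbind, lapply(keep, function(t) {
    keys <- vapply(library$label_sets[[t]], label_set_key, character(1L))
    data.frame(labels = keys, distance = d[t], template = t,
               stringsAsFactors = FALSE)
  }))
  card <- lengths(strsplit(cand$labels, ";", fixed = TRUE))
  cand <- cand[order(cand$distance, card, cand$labels), , drop = FALSE]
  rownames(cand) <- NULL
  if (verdict == "none") {
    cand <- cand[0L, , drop = FALSE]  # no candidate within threshold
  }
  structure(list(verdict = verdict, best_distance = as.integer(best),
                 candidates = cand,
                 threshold = threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> verdict=%s best_distance=%d candidates=%d\n",
              x$verdict, x$best_distance, nrow(x$candidates)))
  invisible(x)
}
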