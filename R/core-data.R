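#' Construct a binary annotation matrix
#'
#' An annotation matrix records, for each enzyme (row), the presence (1) or
#' absence (0) of each protein signature (column). It is the package's
#' realisation of the binary feature space \eqn{\{0,1\}^L}: rows are points,
#' the L columns are features.
#'
#' @param cells numeric/integer/logical matrix of 0/1 values.
#' @param row_ids character vector of unique enzyme identifiers
#'   (defaults to `rownames(cells)`).
#' @param col_ids character vector of unique signature identifiers
#'   (defaults to `colnames(cells)`).
#'
#' @return An integer matrix of class `annotation_matrix` with `dimnames`
#'   set to the identifiers.
#' @export
#'
#' @examples
#' m <- annotation_matrix(rbind(c(1, 0), c(0, 1)),
#'                        row_ids = c("E1", "E2"),
#'                        col_ids = c("IPR000001", "IPR000002"))
#' dim(m)
annotation_matrix <- function(cells, row_ids = rownames(cells),
                              col_ids = colnames(cells)) {
  cells <- as.matrix(cells)
  if (is.logical(cells)) storage.mode(cells) <- "integer"
  if (!is.numeric(cells)) {
    stop("annotation matrix cells must be numeric 0/1 values", call. = FALSE)
  }
  bad <- which(!(cells == 0L | cells == 1L), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-binary cell at row %d, column %d (value %s)",
                 bad[1L, 1L], bad[1L, 2L],
                 format(cells[bad[1L, , drop = FALSE]])), call. = FALSE)
  }
  storage.mode(cells) <- "integer"
  if (nrow(cells) < 1L || ncol(cells) < 1L) {
    stop("annotation matrix needs at least one row and one column",
         call. = FALSE)
  }
  row_ids <- as.character(row_ids)
  col_ids <- as.character(col_ids)
  if (length(row_ids) != nrow(cells) || length(col_ids) != ncol(cells)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(row_ids)) {
    stop(sprintf("duplicate enzyme identifier: %s",
                 row_ids[duplicated(row_ids)][1L]), call. = FALSE)
  }
  if (anyDuplicated(col_ids)) {
    stop(sprintf("duplicate signature identifier: %s",
                 col_ids[duplicated(col_ids)][1L]), call. = FALSE)
  }
  dimnames(cells) <- list(row_ids, col_ids)
  class(cells) <- c("annotation_matrix", class(cells))
  cells
}

#' Construct a label assignment
#'
#' Maps each enzyme identifier to its non-empty set of mechanism labels
#' (strings of the form `M0123`). Together the label sets define the class
#' space: the J distinct mechanism labels an enzyme can carry.
#'
#' @param assignment named list; names are enzyme identifiers, elements are
#'   character vectors of mechanism labels.
#'
#' @return A named list of class `label_assignment`; each element is a
#'   sorted character vector of unique labels.
#' @export
label_assignment <- function(assignment) {
  if (!is.list(assignment) || is.null(names(assignment)) ||
      any(names(assignment) == "")) {
    stop("assignment must be a fully named list", call. = FALSE)
  }
  if (anyDuplicated(names(assignment))) {
    stop("duplicate enzyme identifier in label assignment", call. = FALSE)
  }
  assignment <- lapply(assignment, function(x) sort(unique(as.character(x))))
  n <- lengths(assignment)
  if (any(n == 0L)) {
    stop(sprintf("enzyme '%s' has an empty label set",
                 names(assignment)[n == 0L][1L]), call. = FALSE)
  }
  class(assignment) <- c("label_assignment", class(assignment))
  assignment
}

#' All distinct mechanism labels used by an assignment
#'
#' @param labels a [label_assignment()].
#' @return Sorted character vector of distinct labels (size J).
#' @export
label_space <- function(labels) sort(unique(unlist(labels, use.names = FALSE)))

# canonical string form of a label set, used as a hash key everywhere
label_set_key <- function(set) paste(sort(unique(set)), collapse = ";")

#' Read an annotation matrix in the tabular exchange layout
#'
#' The layout is a UTF-8, tab-separated file: a header line
#' `enzyme_id <TAB> sig_1 ... sig_L <TAB> labels`, then one line per enzyme.
#' The first column holds the enzyme identifier, the last column its
#' mechanism label(s) joined by `";"`, and the L middle columns hold 0/1
#' signature presence calls. Row and column order are significant and are
#' preserved verbatim (block structure is an ordering property).
#'
#' @param path path to the TSV file.
#' @return A list with components `matrix` (an [annotation_matrix()]) and
#'   `labels` (a [label_assignment()]).
#' @export
#'
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' m <- annotation_matrix(rbind(c(1, 0), c(0, 1)),
#'                        row_ids = c("E1", "E2"), col_ids = c("s1", "s2"))
#' la <- label_assignment(list(E1 = "M0001", E2 = "M0002"))
#' write_matrix(m, la, tmp)
#' rt <- read_matrix(tmp)
#' stopifnot(identical(unclass(rt$matrix), unclass(m)))
read_matrix <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("matrix file does not exist: %s", path), call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(tab) < 3L) {
    stop("matrix file needs an identifier column, >=1 signature column and a label column",
         call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    stop("matrix file has no data rows", call. = FALSE)
  }
  ids <- tab[[1L]]
  lab_field <- tab[[ncol(tab)]]
  sig <- tab[, seq(2L, ncol(tab) - 1L), drop = FALSE]
  col_ids <- colnames(sig)
  cells <- matrix(0L, nrow(sig), ncol(sig))
  for (j in seq_len(ncol(sig))) {
    v <- sig[[j]]
    ok <- v %in% c("0", "1")
    if (!all(ok)) {
      i <- which(!ok)[1L]
      stop(sprintf("non-binary cell '%s' at data row %d, column '%s'",
                   v[i], i, col_ids[j]), call. = FALSE)
    }
    cells[, j] <- as.integer(v)
  }
  if (any(lab_field == "")) {
    stop(sprintf("empty label field for enzyme '%s'",
                 ids[which(lab_field == "")[1L]]), call. = FALSE)
  }
  mat <- annotation_matrix(cells, row_ids = ids, col_ids = col_ids)
  labs <- label_assignment(stats::setNames(strsplit(lab_field, ";", fixed = TRUE),
                                           ids))
  list(matrix = mat, labels = labs)
}

#' Write an annotation matrix in the tabular exchange layout
#'
#' Inverse of [read_matrix()]: emits the identifier column, the signature
#' columns and the `";"`-joined label column, preserving row and column
#' order. Multi-label sets are joined with `";"` and no spaces; a single
#' label is written bare.
#'
#' @param matrix an [annotation_matrix()].
#' @param labels a [label_assignment()] covering every row of `matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, labels, path) {
  row_ids <- rownames(matrix)
  missing <- setdiff(row_ids, names(labels))
  if (length(missing) > 0L) {
    stop(sprintf("no label entry for enzyme '%s'", missing[1L]), call. = FALSE)
  }
  con <- file(path, open = "wb")  # wb => LF endings on every platform
  on.exit(close(con))
  header <- paste(c("enzyme_id", colnames(matrix), "labels"), collapse = "\t")
  writeLines(header, con, sep = "\n", useBytes = TRUE)
  lab_field <- vapply(labels[row_ids], label_set_key, character(1L))
  if (nrow(matrix) > 0L) {
    body <- paste(row_ids,
                  apply(matrix, 1L, paste, collapse = "\t"),
                  lab_field, sep = "\t")
    writeLines(body, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Parse a class-size table
#'
#' A class-size table lists mechanism labels together with the number of
#' enzymes annotated with each, one `label<TAB>count` pair per line. The
#' packaged fixture ([class_sizes_default()]) transcribes the 71-mechanism
#' census that the synthetic-data generator reproduces by default.
#'
#' @param text character scalar (possibly multi-line) or character vector of
#'   lines.
#' @return A `data.frame` of class `class_size_table` with columns `label`
#'   and `count`, in input order.
#' @export
parse_class_sizes <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("class-size table is empty", call. = FALSE)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop(sprintf("malformed class-size line: '%s'",
                 lines[which(lengths(parts) != 2L)[1L]]), call. = FALSE)
  }
  label <- vapply(parts, `[[`, character(1L), 1L)
  count_chr <- vapply(parts, `[[`, character(1L), 2L)
  if (any(!grepl("^M[0-9]{4}$", label))) {
    stop(sprintf("malformed mechanism label: '%s'",
                 label[!grepl("^M[0-9]{4}$", label)][1L]), call. = FALSE)
  }
  if (anyDuplicated(label)) {
    stop(sprintf("duplicate mechanism label: %s",
                 label[duplicated(label)][1L]), call. = FALSE)
  }
  if (any(!grepl("^[0-9]+$", count_chr))) {
    stop(sprintf("malformed count: '%s'",
                 count_chr[!grepl("^[0-9]+$", count_chr)][1L]), call. = FALSE)
  }
  count <- as.integer(count_chr)
  if (any(count < 1L)) {
    stop(sprintf("count < 1 for label %s", label[count < 1L][1L]),
         call. = FALSE)
  }
  out <- data.frame(label = label, count = count, stringsAsFactors = FALSE)
  class(out) <- c("class_size_table", class(out))
  out
}

#' The packaged 71-mechanism class-size fixture
#'
#' Returns the class-size table shipped with the package: 71 mechanism
#' labels with per-label enzyme counts (all counts are at least 2; counts
#' sum to 247). This is the default configuration of the synthetic-data
#' generator.
#'
#' @return A `class_size_table` with 71 rows.
#' @export
#'
#' @examples
#' cs <- class_sizes_default()
#' nrow(cs)
#' cs$count[cs$label == "M0218"]
class_sizes_default <- function() {
  path <- system.file("extdata", "macie_class_sizes.tsv",
                      package = "mechmatch", mustWork = TRUE)
  parse_class_sizes(readLines(path))
}

#' Construct a prediction object
#'
#' @param labels non-empty character vector: the predicted label set.
#' @param ring_distance non-negative integer squared distance of the ring.
#' @param ring_members non-empty character vector of dictionary enzyme
#'   identifiers forming the ring of nearest neighbours.
#' @return A list of class `mech_prediction`.
#' @export
mech_prediction <- function(labels, ring_distance, ring_members) {
  if (length(labels) == 0L) stop("prediction label set is empty", call. = FALSE)
  if (length(ring_members) == 0L) stop("prediction ring is empty", call. = FALSE)
  if (ring_distance < 0) stop("ring distance must be >= 0", call. = FALSE)
  structure(list(labels = sort(unique(as.character(labels))),
                 ring_distance = as.integer(ring_distance),
                 ring_members = as.character(ring_members)),
            class = "mech_prediction")
}

#' @export
print.mech_prediction <- function(x, ...) {
  cat(sprintf("<mech_prediction> labels={%s} distance=%d ring=%d member(s)\n",
              label_set_key(x$labels), x$ring_distance,
              length(x$ring_members)))
  invisible(x)
}
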