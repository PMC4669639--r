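#' Configuration for the synthetic block-structured generator
#'
#' Describes the stylised world the generator emulates: each mechanism label
#' owns a contiguous block of signature columns and its enzymes carry
#' exactly that block; blocks of different labels are disjoint, except for
#' one designated pair of labels that share a single identical block (making
#' their enzymes indistinguishable in feature space), and one designated
#' composite label whose block is a union of disjoint sub-blocks (its
#' enzymes split across two or more mutually non-overlapping signature
#' sets). Optional symmetric bit-flip noise perturbs the clean matrix.
#'
#' @param class_sizes a `class_size_table` ([parse_class_sizes()]); defaults
#'   to the packaged 71-label fixture.
#' @param n_features total number of signature columns (default 321).
#' @param overlap_pair character vector of the two labels that completely
#'   overlap (default `c("M0348", "M0269")`), or `NULL` for none.
#' @param shared_width width of the shared block (default 4).
#' @param composite_label the label whose block splits into disjoint
#'   sub-blocks (default `"M0218"`), or `NULL` for none.
#' @param n_subblocks number of sub-blocks for the composite label
#'   (default 2).
#' @param noise_rate probability in `[0, 1]` that a cell is flipped
#'   (default 0).
#' @param shuffle_columns if `TRUE`, emit the columns in a seeded random
#'   order instead of grouped by planted block; used to create inputs for
#'   block-structure recovery.
#' @param seed integer seed driving noise and column shuffling.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(class_sizes = class_sizes_default(),
                             n_features = 321L,
                             overlap_pair = c("M0348", "M0269"),
                             shared_width = 4L,
                             composite_label = "M0218",
                             n_subblocks = 2L,
                             noise_rate = 0,
                             shuffle_columns = FALSE,
                             seed = 0L) {
  stopifnot(inherits(class_sizes, "class_size_table"))
  labels <- class_sizes$label
  if (!is.null(overlap_pair)) {
    if (length(overlap_pair) != 2L || overlap_pair[1L] == overlap_pair[2L]) {
      stop("overlap_pair must name two distinct labels", call. = FALSE)
    }
    if (!all(overlap_pair %in% labels)) {
      stop("overlap_pair labels must appear in class_sizes", call. = FALSE)
    }
  }
  if (!is.null(composite_label)) {
    if (!composite_label %in% labels) {
      stop("composite_label must appear in class_sizes", call. = FALSE)
    }
    if (composite_label %in% overlap_pair) {
      stop("composite_label must be distinct from the overlap pair",
           call. = FALSE)
    }
    if (n_subblocks < 2L) stop("n_subblocks must be >= 2", call. = FALSE)
  }
  if (shared_width < 1L) stop("shared_width must be >= 1", call. = FALSE)
  if (noise_rate < 0 || noise_rate > 1) {
    stop("noise_rate must lie in [0, 1]", call. = FALSE)
  }
  structure(list(class_sizes = class_sizes,
                 n_features = as.integer(n_features),
                 overlap_pair = overlap_pair,
                 shared_width = as.integer(shared_width),
                 composite_label = composite_label,
                 n_subblocks = as.integer(n_subblocks),
                 noise_rate = noise_rate,
                 shuffle_columns = isTRUE(shuffle_columns),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Allocate signature-column blocks to mechanism labels
#'
#' Deterministically partitions the `n_features` columns into per-label
#' blocks: the overlap pair shares a single block of exactly
#' `shared_width` columns, every other label gets its own block, and the
#' composite label's block is split into `n_subblocks` disjoint non-empty
#' sub-blocks. Every block starts at its minimum feasible width (1 column,
#' or `n_subblocks` for the composite, or `shared_width` for the shared
#' block); the remaining column budget is distributed round-robin in
#' class-table order so the widths always sum to `n_features` exactly.
#'
#' @param config a [generator_config()].
#' @return A list of class `planted_structure` with components
#'   `block_of_label` (named list: label -> character vector of column
#'   identifiers), `sub_blocks` (for the composite label, list of disjoint
#'   column-identifier sets) and `col_ids` (all column identifiers in
#'   planted block order).
#' @export
allocate_blocks <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  labels <- config$class_sizes$label
  pair <- config$overlap_pair
  comp <- config$composite_label

  # one allocation unit per distinct block; the pair collapses onto one unit
  unit_of_label <- stats::setNames(seq_along(labels), labels)
  if (!is.null(pair)) {
    unit_of_label[pair[2L]] <- unit_of_label[pair[1L]]
  }
  units <- sort(unique(unit_of_label))
  n_units <- length(units)

  min_width <- rep(1L, n_units)
  names(min_width) <- labels[units]
  if (!is.null(pair)) min_width[labels[unit_of_label[pair[1L]]]] <- config$shared_width
  if (!is.null(comp)) min_width[comp] <- config$n_subblocks
  required <- sum(min_width)
  if (config$n_features < required) {
    stop(sprintf("infeasible feature budget: n_features=%d but at least %d columns are required",
                 config$n_features, required), call. = FALSE)
  }

  width <- min_width
  spare <- config$n_features - required
  if (spare > 0L) {
    # round-robin in class-table order; the shared block keeps width
    # shared_width so the planted complete overlap stays exactly 4 wide
    growable <- which(names(width) != if (is.null(pair)) "" else labels[unit_of_label[pair[1L]]])
    if (length(growable) == 0L) growable <- seq_len(n_units)
    idx <- growable[((seq_len(spare) - 1L) %% length(growable)) + 1L]
    add <- tabulate(idx, nbins = n_units)
    width <- width + add
  }

  col_ids <- sprintf("IPR%06d", seq_len(config$n_features))
  ends <- cumsum(width)
  starts <- ends - width + 1L
  block_of_unit <- lapply(seq_len(n_units),
                          function(i) col_ids[starts[i]:ends[i]])
  names(block_of_unit) <- names(width)

  block_of_label <- lapply(labels, function(lb) {
    block_of_unit[[labels[unit_of_label[lb]]]]
  })
  names(block_of_label) <- labels

  sub_blocks <- NULL
  if (!is.null(comp)) {
    cols <- block_of_label[[comp]]
    cut <- sort((seq_along(cols) - 1L) %% config$n_subblocks)
    sub_blocks <- split(cols, cut)
    names(sub_blocks) <- NULL
  }

  structure(list(block_of_label = block_of_label,
                 sub_blocks = sub_blocks,
                 col_ids = col_ids),
            class = "planted_structure")
}

#' Generate a synthetic annotation matrix with planted block structure
#'
#' Creates one single-label enzyme row per unit of each class count. Before
#' noise, each enzyme's row is 1 exactly on its label's block columns (for
#' the composite label, exactly on its assigned sub-block's columns) and 0
#' elsewhere; the overlap-pair labels share one block, so their enzymes'
#' rows are identical. Output is deterministic given the config (including
#' its seed).
#'
#' @param config a [generator_config()].
#' @return A list with components `matrix` ([annotation_matrix()]),
#'   `labels` ([label_assignment()]) and `structure` (the
#'   `planted_structure` from [allocate_blocks()], augmented with
#'   `subblock_assignment`, a named integer vector mapping each composite
#'   enzyme to its sub-block index).
#' @export
#'
#' @examples
#' sim <- generate_annotation(generator_config())
#' dim(sim$matrix)   # 247 x 321
generate_annotation <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  planted <- allocate_blocks(config)
  cs <- config$class_sizes
  n <- sum(cs$count)
  row_label <- rep(cs$label, cs$count)
  row_ids <- sprintf("SYN%04d", seq_len(n))

  cells <- matrix(0L, n, config$n_features,
                  dimnames = list(row_ids, planted$col_ids))
  col_index <- stats::setNames(seq_len(config$n_features), planted$col_ids)

  subblock_assignment <- integer(0)
  comp <- config$composite_label
  for (lb in cs$label) {
    rows <- which(row_label == lb)
    if (!is.null(comp) && lb == comp) {
      # split composite enzymes as evenly as possible across sub-blocks
      k <- config$n_subblocks
      assign <- sort(((seq_along(rows) - 1L) %% k) + 1L)
      subblock_assignment <- stats::setNames(assign, row_ids[rows])
      for (i in seq_along(rows)) {
        cells[rows[i], col_index[planted$sub_blocks[[assign[i]]]]] <- 1L
      }
    } else {
      cells[rows, col_index[planted$block_of_label[[lb]]]] <- 1L
    }
  }

  if (config$shuffle_columns) {
    perm <- with_seed(config$seed, sample.int(config$n_features))
    cells <- cells[, perm, drop = FALSE]
  }

  mat <- annotation_matrix(cells)
  if (config$noise_rate > 0) {
    mat <- add_noise(mat, config$noise_rate, config$seed)
  }
  labs <- label_assignment(stats::setNames(as.list(row_label), row_ids))
  planted$subblock_assignment <- subblock_assignment
  list(matrix = mat, labels = labs, structure = planted)
}

#' Flip matrix cells with independent probability
#'
#' Symmetric bit-flip noise: each cell is independently complemented with
#' probability `noise_rate`. The input matrix is not modified; the result
#' is deterministic given the seed.
#'
#' @param matrix an [annotation_matrix()].
#' @param noise_rate flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A new [annotation_matrix()] of the same shape.
#' @export
add_noise <- function(matrix, noise_rate, seed = 0L) {
  if (noise_rate < 0 || noise_rate > 1) {
    stop("noise_rate must lie in [0, 1]", call. = FALSE)
  }
  if (noise_rate == 0) return(matrix)
  flip <- with_seed(seed, stats::runif(length(matrix)) < noise_rate)
  out <- unclass(matrix)
  out[flip] <- 1L - out[flip]
  annotation_matrix(out)
}

# evaluate expr under a temporary RNG state; restores the caller's state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
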