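# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (elementwise loops, boolean closure) so they share no
# code path with the implementation they check.

# position-by-position mismatch count
oracle_sq_dist <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- 0L
  for (i in seq_along(a)) if (a[i] != b[i]) n <- n + 1L
  n
}

# argmin set by exhaustive scan with the oracle distance
oracle_ring <- function(query, cells) {
  d <- vapply(seq_len(nrow(cells)),
              function(i) oracle_sq_dist(query, cells[i, ]), integer(1L))
  list(members = rownames(cells)[d == min(d)], distance = min(d))
}

# transitive closure of the pairwise intersection relation via repeated
# boolean matrix squaring; returns component id per row of cells
oracle_components <- function(cells) {
  n <- nrow(cells)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- i == j || any(cells[i, ] == 1L & cells[j, ] == 1L)
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      k <- k + 1L
      comp[adj[i, ] > 0] <- k
    }
  }
  comp
}

# Jaccard by exhaustive element enumeration
oracle_jaccard <- function(a, b) {
  u <- unique(c(a, b))
  if (length(u) == 0L) return(NA_real_)
  inter <- 0L
  for (x in u) if ((x %in% a) && (x %in% b)) inter <- inter + 1L
  inter / length(u)
}

# random binary annotation matrix with ids
random_annotation <- function(n, l, density = 0.3, seed = 1L) {
  set.seed(seed)
  annotation_matrix(matrix(as.integer(stats::runif(n * l) < density), n, l),
                    row_ids = sprintf("E%03d", seq_len(n)),
                    col_ids = sprintf("S%03d", seq_len(l)))
}

random_labels <- function(row_ids, labels = c("M0001", "M0002", "M0003"),
                          seed = 1L) {
  set.seed(seed)
  label_assignment(stats::setNames(as.list(sample(labels, length(row_ids),
                                                  replace = TRUE)), row_ids))
}

# two disjoint-block labels, `per` identical enzymes each: the minimal
# perfectly separable world
two_block_fixture <- function(per = 2L) {
  cells <- rbind(matrix(rep(c(1L, 1L, 0L, 0L), per), per, byrow = TRUE),
                 matrix(rep(c(0L, 0L, 1L, 1L), per), per, byrow = TRUE))
  ids <- sprintf("e%d", seq_len(2L * per))
  m <- annotation_matrix(cells, row_ids = ids,
                         col_ids = sprintf("s%d", 1:4))
  la <- label_assignment(stats::setNames(
    as.list(rep(c("M0001", "M0002"), each = per)), ids))
  list(matrix = m, labels = la)
}

# minimal binary PPM (P6) reader for pixel-exact heatmap checks
read_ppm <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  nl <- which(raw == as.raw(10L))
  magic <- rawToChar(raw[seq_len(nl[1L] - 1L)])
  stopifnot(magic == "P6")
  dims <- as.integer(strsplit(rawToChar(raw[(nl[1L] + 1L):(nl[2L] - 1L)]),
                              " ")[[1L]])
  maxval <- as.integer(rawToChar(raw[(nl[2L] + 1L):(nl[3L] - 1L)]))
  stopifnot(maxval == 255L)
  px <- as.integer(raw[(nl[3L] + 1L):length(raw)])
  list(width = dims[1L], height = dims[2L],
       pixels = matrix(px, ncol = 3L, byrow = TRUE))  # rows: R,G,B per pixel
}

default_sim <- function(...) generate_annotation(generator_config(...))
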