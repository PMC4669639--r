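test_that("squared_distance equals the brute-force mismatch count", {
  expect_identical(squared_distance(c(1, 0, 1), c(1, 0, 1)), 0L)
  expect_identical(squared_distance(rep(0, 4), rep(1, 4)), 4L)
  expect_error(squared_distance(c(1, 0), c(1, 0, 1)), "length mismatch")

  set.seed(11)
  for (k in seq_len(200L)) {
    a <- as.integer(runif(321) < 0.2)
    b <- as.integer(runif(321) < 0.2)
    expect_identical(squared_distance(a, b), oracle_sq_dist(a, b))
  }
})

test_that("squared_distance satisfies the metric axioms (property)", {
  set.seed(12)
  for (k in seq_len(100L)) {
    l <- sample(3:40, 1L)
    x <- as.integer(runif(l) < 0.5)
    y <- as.integer(runif(l) < 0.5)
    z <- as.integer(runif(l) < 0.5)
    dxy <- squared_distance(x, y)
    expect_gte(dxy, 0L)
    expect_identical(dxy == 0L, identical(x, y))
    expect_identical(dxy, squared_distance(y, x))
    expect_lte(dxy, squared_distance(x, z) + squared_distance(z, y))
  }
})

test_that("nearest_ring returns the full argmin set (brute-force oracle)", {
  m <- random_annotation(30L, 12L, seed = 21L)
  dict <- dictionary(m, random_labels(rownames(m), seed = 21L))
  set.seed(22)
  for (k in seq_len(50L)) {
    q <- as.integer(runif(12) < 0.4)
    got <- nearest_ring(q, dict)
    want <- oracle_ring(q, unclass(m))
    expect_identical(got$members, want$members)
    expect_identical(got$distance, want$distance)
  }
})

test_that("nearest_ring handles exclusion, ties and degenerate dictionaries", {
  cells <- rbind(e1 = c(1L, 0L, 0L), e2 = c(0L, 1L, 0L), e3 = c(0L, 0L, 1L))
  colnames(cells) <- c("s1", "s2", "s3")
  dict <- dictionary(annotation_matrix(cells),
                     label_assignment(list(e1 = "M0001", e2 = "M0002",
                                           e3 = "M0003")))
  hit <- nearest_ring(c(1L, 0L, 0L), dict)
  expect_identical(hit$members, "e1")
  expect_identical(hit$distance, 0L)

  # all-zero query is at distance 1 from each one-hot row: 3-member ring
  tie <- nearest_ring(c(0L, 0L, 0L), dict)
  expect_identical(tie$members, c("e1", "e2", "e3"))
  expect_identical(tie$distance, 1L)

  excl <- nearest_ring(c(1L, 0L, 0L), dict, exclude = "e1")
  expect_identical(excl$distance, 2L)

  one <- dictionary(annotation_matrix(cells[1L, , drop = FALSE]),
                    label_assignment(list(e1 = "M0001")))
  expect_error(nearest_ring(c(1L, 0L, 0L), one, exclude = "e1"),
               "empty after exclusion")
})

test_that("nearest_ring is invariant under dictionary row permutation", {
  m <- random_annotation(25L, 10L, seed = 31L)
  la <- random_labels(rownames(m), seed = 31L)
  set.seed(32)
  perm <- sample(nrow(m))
  shuffled <- annotation_matrix(unclass(m)[perm, , drop = FALSE])
  for (k in seq_len(20L)) {
    q <- as.integer(runif(10) < 0.4)
    a <- nearest_ring(q, dictionary(m, la))
    b <- nearest_ring(q, dictionary(shuffled, la))
    expect_setequal(a$members, b$members)
    expect_identical(a$distance, b$distance)
  }
})

test_that("ring_vote picks the most common label set with documented ties", {
  la <- label_assignment(list(e1 = "A", e2 = "B", e3 = "B",
                              e4 = c("A", "B"), e5 = "A"))
  expect_identical(ring_vote(c("e1", "e2", "e3"), la), "B")
  expect_identical(ring_vote("e4", la), c("A", "B"))
  # 2 x {A} vs 2 x {B}: tie -> smallest cardinality (equal) then
  # lexicographic -> {A}
  expect_identical(ring_vote(c("e1", "e5", "e2", "e3"), la), "A")
  # {A,B} vs {A}: tie -> smaller set {A}
  expect_identical(ring_vote(c("e4", "e1"), la), "A")
  expect_error(ring_vote(c("e1", "zz"), la), "no label entry")
})

test_that("classify composes ring search and voting", {
  fix <- two_block_fixture(per = 2L)
  dict <- dictionary(fix$matrix, fix$labels)
  pred <- classify(c(1L, 1L, 0L, 0L), dict)
  expect_s3_class(pred, "mech_prediction")
  expect_identical(pred$labels, "M0001")
  expect_identical(pred$ring_distance, 0L)

  # planted complete overlap: query of a pair-A row sees a 4-member ring
  sim <- default_sim()
  lab <- vapply(sim$labels, paste, character(1L), collapse = ";")
  a_row <- names(sim$labels)[lab == "M0348"][1L]
  pred <- classify(unclass(sim$matrix)[a_row, ],
                   dictionary(sim$matrix, sim$labels))
  expect_identical(pred$ring_distance, 0L)
  expect_length(pred$ring_members, 4L)

  # 1-row dictionary returns that row's label set whatever the query
  one <- dictionary(annotation_matrix(matrix(c(1L, 0L), 1L,
                                             dimnames = list("e1", c("a", "b")))),
                    label_assignment(list(e1 = c("M0009", "M0002"))))
  expect_identical(classify(c(0L, 1L), one)$labels, c("M0002", "M0009"))
})

test_that("loo_evaluate matches hand-simulated outcomes", {
  # two disjoint labels, 2 identical enzymes each: perfect
  fix <- two_block_fixture(per = 2L)
  rep <- loo_evaluate(dictionary(fix$matrix, fix$labels))
  expect_identical(rep$success_rate, 1)

  # a singleton label with a unique block must fail its own LOO round:
  # hand simulation: e5 excluded -> nearest rows are all four two_block
  # rows (distance 4 = its 2 block columns + their 2), vote tie
  # {M0001} vs {M0002} -> lexicographic winner M0001 != M0003
  cells <- rbind(unclass(fix$matrix), e5 = c(0L, 0L, 0L, 0L))
  cells["e5", ] <- 0L
  cells <- cbind(cells, s5 = c(0L, 0L, 0L, 0L, 1L), s6 = c(0L, 0L, 0L, 0L, 1L))
  la <- label_assignment(c(unclass(fix$labels), list(e5 = "M0003")))
  rep <- loo_evaluate(dictionary(annotation_matrix(cells), la))
  expect_identical(rep$per_enzyme$success,
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(rep$success_rate, 4 / 5)
  expect_identical(rep$per_enzyme$predicted_labels[5L], "M0001")

  # overlap criterion counts partial matches
  ov <- loo_evaluate(dictionary(annotation_matrix(cells), la),
                     criterion = "overlap")
  expect_equal(ov$success_rate, 4 / 5)

  expect_error(loo_evaluate(dictionary(
    annotation_matrix(matrix(1L, 1L, 1L, dimnames = list("e", "s"))),
    label_assignment(list(e = "M0001")))), "at least two rows")
})

test_that("per-label voting differs from set voting where designed to", {
  # ring {A}, {A,B}, {B}: set vote ties -> {A}; per-label vote: A and B
  # each on 2/3 of members -> both assigned
  cells <- rbind(e1 = c(1L, 0L), e2 = c(1L, 0L), e3 = c(1L, 0L))
  colnames(cells) <- c("s1", "s2")
  la <- label_assignment(list(e1 = "A", e2 = c("A", "B"), e3 = "B"))
  expect_identical(ring_vote(c("e1", "e2", "e3"), la), "A")
  expect_identical(mechmatch:::per_label_vote(c("e1", "e2", "e3"), la),
                   c("A", "B"))
})

test_that("LOO errors on noiseless planted data stay in the overlap pair", {
  sim <- default_sim()
  rep <- loo_evaluate(dictionary(sim$matrix, sim$labels))
  fails <- rep$per_enzyme[!rep$per_enzyme$success, ]
  expect_identical(nrow(fails), 4L)
  expect_setequal(fails$true_labels, c("M0348", "M0269"))
  expect_equal(rep$success_rate, (247 - 4) / 247)
})
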