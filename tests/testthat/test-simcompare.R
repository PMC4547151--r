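test_that("copair_count sums within-cluster pairs", {
  expect_equal(copair_count(cr_from_labels(c("A", "A", "B", "B"))), 2)
  expect_equal(copair_count(cr_from_labels(letters[1:5])), 0)
  r <- cr_from_labels(c(rep("A", 3), rep("B", 4), "C"))
  expect_equal(copair_count(r), 9)
  expect_equal(copair_count(r), length(oracle_pair_set(r)))
  # noise pairs counted by default, excludable on request
  rn <- cr_from_labels(c("A", "A", "N", "N", "N"), noise_label = "N")
  expect_equal(copair_count(rn), 4)
  expect_equal(copair_count(rn, include_noise = FALSE), 1)
})

test_that("f_measure matches hand-computed and oracle values", {
  ids <- sprintf("i%03d", 1:4)
  a <- cr_from_labels(c("x", "x", "y", "y"), "a", ids)
  b <- cr_from_labels(c("p", "q", "p", "q"), "b", ids)
  expect_equal(f_measure(a, a), 1.0)
  expect_equal(f_measure(a, b), 0.0)      # no agreed pairs
  a2 <- cr_from_labels(c("x", "x", "x", "y"), "a2", ids)
  b2 <- cr_from_labels(c("p", "p", "q", "q"), "b2", ids)
  # |Pa|=3, |Pb|=2, agreed=1 -> F = 0.4
  expect_equal(f_measure(a2, b2), 0.4)
  expect_equal(f_measure(b2, a2), 0.4)    # symmetric
  expect_equal(oracle_f_measure(a2, b2), 0.4)
  # all-singleton edge cases
  s <- cr_from_labels(letters[1:4], "s", ids)
  expect_equal(f_measure(s, s), 1.0)      # both pair sets empty
  expect_equal(f_measure(s, a), 0.0)      # exactly one empty
})

test_that("f_measure errors on differing item sets unless restricted", {
  a <- cr_from_labels(c("x", "x"), "a", c("g1", "g2"))
  b <- cr_from_labels(c("x", "x", "y"), "b", c("g1", "g2", "g3"))
  expect_error(f_measure(a, b), "g3")
  expect_equal(f_measure(a, b, restrict = TRUE), 1.0)
})

test_that("noise-cluster pairs are included by default and excludable", {
  ids <- sprintf("i%d", 1:6)
  a <- cr_from_labels(c("A", "A", "A", "N", "N", "N"), "a", ids,
                      noise_label = "N")
  b <- cr_from_labels(c("A", "A", "A", "N", "N", "A"), "b", ids,
                      noise_label = "N")
  expect_equal(f_measure(a, b), oracle_f_measure(a, b))
  expect_equal(f_measure(a, b, include_noise = FALSE),
               oracle_f_measure(a, b, include_noise = FALSE))
  expect_false(f_measure(a, b) == f_measure(a, b, include_noise = FALSE))
})

test_that("f_measure agrees with the pair-enumeration oracle on random pairs", {
  set.seed(1234)
  for (trial in 1:60) {
    n <- sample(3:40, 1)
    ids <- sprintf("i%03d", seq_len(n))
    a <- cr_from_labels(sample(max(2, n %/% 3), n, replace = TRUE),
                        "a", ids)
    b <- cr_from_labels(sample(max(2, n %/% 4), n, replace = TRUE),
                        "b", ids)
    expect_equal(f_measure(a, b), oracle_f_measure(a, b),
                 tolerance = 1e-12)
    expect_true(f_measure(a, b) >= 0 && f_measure(a, b) <= 1)
  }
})

test_that("similarity_matrix is symmetric with unit diagonal", {
  res <- random_instance(30, 5, seed = 3)
  sm <- similarity_matrix(res)
  expect_equal(unclass(sm), t(unclass(sm)), tolerance = 1e-12)
  expect_equal(unname(diag(sm)), rep(1, 5))
  expect_true(all(sm >= 0 & sm <= 1))
  # entries match per-pair f_measure calls
  expect_equal(sm[1, 2], f_measure(res[[1]], res[[2]]))
  expect_equal(sm[3, 5], f_measure(res[[3]], res[[5]]))
  # two copies of one result -> all-ones matrix
  dup <- res[[1]]; dup$result_id <- "copy"
  sm2 <- similarity_matrix(list(res[[1]], dup))
  expect_equal(unclass(sm2), matrix(1, 2, 2,
                                    dimnames = dimnames(sm2)))
})

test_that("centroid correlation matches the textbook formula", {
  expect_equal(centroid_correlation(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(centroid_correlation(c(1, 2, 3), c(3, 2, 1)), -1.0)
  x <- c(1, 2, 4); y <- c(2, 2, 5)
  byhand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(centroid_correlation(x, y), byhand, tolerance = 1e-12)
  expect_warning(z <- centroid_correlation(c(1, 1, 1), c(1, 2, 3)),
                 "zero-variance")
  expect_equal(z, 0)
  expect_error(centroid_correlation(1, 2), "at least 2")
})

test_that("stable_groups computes the meet of the partitions", {
  ids <- sprintf("i%d", 1:5)
  a <- cr_from_labels(c("x", "x", "x", "y", "y"), "a", ids)
  b <- cr_from_labels(c("p", "p", "q", "q", "q"), "b", ids)
  sgs <- stable_groups(list(a, b))
  expect_equal(canon_groups(sgs$groups),
               canon_groups(list(c("i1", "i2"), "i3", c("i4", "i5"))))
  # single result: groups are its clusters
  s1 <- stable_groups(list(a))
  expect_equal(canon_groups(s1$groups), canon_groups(unname(a$clusters)))
  # meet with the all-singletons partition is all singletons
  s <- cr_from_labels(ids, "s", ids)
  expect_true(all(lengths(stable_groups(list(a, s))$groups) == 1))
  expect_error(stable_groups(list()), "at least one")
})

test_that("stable_groups ordering, refinement and signatures hold", {
  set.seed(55)
  res <- random_instance(40, 4, seed = 55)
  sgs <- stable_groups(res)
  sz <- lengths(sgs$groups)
  expect_true(all(diff(sz) <= 0))               # descending size
  expect_equal(sum(sz), 40L)                    # partition
  # refinement: every group sits inside one cluster of every result
  for (g in sgs$groups) for (r in res)
    expect_equal(length(unique(r$assignment[g])), 1L)
  # distinct groups have distinct signatures
  expect_false(anyDuplicated(sgs$signatures) > 0)
  # adding a result never coarsens the meet
  extra <- random_instance(40, 1, seed = 99)
  extra[[1]]$result_id <- "R99"
  more <- c(res, extra)
  expect_gte(length(stable_groups(more)$groups), length(sgs$groups))
})

test_that("stable_groups equals the brute-force signature oracle", {
  set.seed(10)
  for (trial in 1:40) {
    n <- sample(5:50, 1)
    nres <- sample(2:5, 1)
    res <- random_instance(n, nres, seed = 1000 + trial)
    sgs <- stable_groups(res)
    expect_equal(canon_groups(sgs$groups),
                 canon_groups(oracle_stable_groups(res)))
  }
})

test_that("group filtering and histogram are consistent", {
  sizes <- c(5, 3, 1, 1)
  groups <- split(sprintf("i%d", 1:10), rep(1:4, times = sizes))
  sgs <- structure(list(groups = unname(groups),
                        signatures = sprintf("s%d", 1:4),
                        result_ids = "r",
                        visible = rep(TRUE, 4)),
                   class = "stable_group_set")
  f <- filter_groups(sgs, min_size = 2)
  expect_equal(sum(f$visible), 2L)
  expect_equal(length(f$groups), 4L)            # partition untouched
  expect_equal(group_histogram(sgs),
               stats::setNames(c(2L, 1L, 1L), c("1", "3", "5")))
  # sum of size * count equals the item universe
  h <- group_histogram(sgs)
  expect_equal(sum(as.integer(names(h)) * h), 10L)
  expect_error(filter_groups(sgs, min_size = 3, max_size = 2), "min_size")
  # identity filter
  expect_true(all(filter_groups(sgs, 1, Inf)$visible))
})
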