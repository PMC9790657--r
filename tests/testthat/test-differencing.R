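test_that("difference matrices compose first differences", {
  expect_equal(difference_matrix(3, 1), rbind(c(-1, 1, 0), c(0, -1, 1)))
  expect_equal(difference_matrix(4, 2), rbind(c(1, -2, 1, 0), c(0, 1, -2, 1)))
  expect_equal(difference_matrix(5, 0), diag(5))
  d <- rnorm(8)
  expect_equal(drop(difference_matrix(8, 1) %*% d), diff(d))
  expect_equal(drop(difference_matrix(8, 2) %*% d), diff(d, differences = 2))
  expect_error(difference_matrix(3, 3), "r")
})

test_that("minimum-norm recovery inverts differencing orthogonally", {
  expect_equal(recover_levels(c(1, 1), 1), c(-1, 0, 1))
  expect_equal(recover_levels(rep(0, 6), 2), rep(0, 8))
  set.seed(1)
  for (i in 1:50) {
    K <- sample(3:30, 1)
    r <- sample(1:2, 1)
    if (r >= K) next
    g <- rnorm(K - r)
    d <- recover_levels(g, r)
    D <- difference_matrix(K, r)
    expect_equal(drop(D %*% d), g, tolerance = 1e-12)
    # orthogonal to the null space of D (spanned by polynomials of degree < r)
    N <- sapply(seq_len(r) - 1, function(p) seq_len(K)^p)
    expect_lt(max(abs(crossprod(N, d))) / max(1, max(abs(d))), 1e-8)
  }
})

test_that("anchored recovery satisfies its anchoring equations exactly", {
  expect_equal(recover_levels(c(1, 1), 1, anchor_sets(1L)), c(0, 1, 2))
  set.seed(2)
  for (i in 1:50) {
    K <- sample(4:30, 1)
    g <- rnorm(K - 2)
    kstar <- sample(K, 1)
    d <- recover_levels(g, 2, anchor_sets(kstar, seq_len(K - 1)))
    expect_equal(drop(difference_matrix(K, 2) %*% d), g, tolerance = 1e-12)
    expect_lt(abs(d[kstar]), 1e-10)
    expect_lt(abs(sum(diff(d))), 1e-10)
    # RW(1) sum-to-zero mode
    g1 <- rnorm(K - 1)
    d1 <- recover_levels(g1, 1, anchor_sets(seq_len(K)))
    expect_equal(drop(difference_matrix(K, 1) %*% d1), g1, tolerance = 1e-12)
    expect_lt(abs(sum(d1)), 1e-10)
  }
})

test_that("difference-then-recover is the identity on the constrained subspace", {
  set.seed(3)
  K <- 12
  D <- difference_matrix(K, 2)
  # a delta already orthogonal to null(D)
  d0 <- recover_levels(rnorm(K - 2), 2)
  expect_equal(recover_levels(drop(D %*% d0), 2), d0, tolerance = 1e-10)
})

test_that("malformed anchoring constraints are rejected", {
  expect_error(recover_levels(rnorm(3), 2, anchor_sets(1L)), "index sets")
  expect_error(anchor_sets(0L), "positive integer")
  expect_error(recover_levels(rnorm(4), 1, anchor_sets(6L)), "beyond")
})
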