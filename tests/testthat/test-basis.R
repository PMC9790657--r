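test_that("identity basis is the identity", {
  B <- build_basis(basis_spec("identity"), 1:10)
  expect_equal(unclass(B)[1:10, 1:10], diag(10))
})

test_that("cubic B-spline basis has the expected size and partition of unity", {
  B <- build_basis(basis_spec("bspline"), times = 1:26, span = c(1, 26))
  # 25 units at spacing 2.5 -> 10 interior intervals + degree 3
  expect_equal(ncol(B), 13)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-10)
  expect_equal(qr(B)$rank, ncol(B))
  expect_error(build_basis(basis_spec("bspline", knot_spacing = 30), 1:10),
               "shorter")
})

test_that("extending the basis appends columns without touching old ones", {
  B <- build_basis(basis_spec("bspline"), times = 1:20, span = c(1, 20))
  B2 <- extend_basis(B, times = 1:30, to_time = 30)
  expect_gt(attr(B2, "K_added"), 0)
  expect_equal(ncol(B2), ncol(B) + attr(B2, "K_added"))
  expect_identical(unclass(B2)[1:20, seq_len(ncol(B))], unclass(B)[, ])
  expect_lt(max(abs(rowSums(B2) - 1)), 1e-10)
})
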