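# Compositional core: closure, compositional means, SBP bases, ilr.

test_that("closure divides by the row total and rejects non-positive parts", {
  p <- close_composition(c(1270, 18, 51))
  expect_equal(unname(round(p, 4)), c(0.9485, 0.0134, 0.0381))
  expect_equal(sum(p), 1)
  expect_equal(unname(close_composition(c(1, 1, 1))), rep(1 / 3, 3))
  m <- close_composition(random_parts(20))
  expect_equal(rowSums(m), rep(1, 20))
  expect_error(close_composition(c(0, 1, 1)), "positive")
})

test_that("compositional mean closes geometric means and rescales by a total", {
  # published descriptives: geometric means and mean totals -> minutes/week
  cs <- compositional_mean(matrix(c(1270, 18, 51), 1,
                                  dimnames = list(NULL, DT_PARTS)),
                           total_scale = 1724)
  expect_equal(round(cs$minutes_wk), c(1635, 23, 66))
  long_bl <- compositional_mean(matrix(c(1162, 18, 69), 1,
                                       dimnames = list(NULL, DT_PARTS)),
                                total_scale = 1612)
  expect_equal(round(long_bl$minutes_wk), c(1500, 23, 89))

  const <- matrix(5, 4, 3, dimnames = list(NULL, DT_PARTS))
  expect_equal(compositional_mean(const, total_scale = 300)$minutes_wk,
               rep(100, 3))

  # agrees with a direct per-part geometric mean oracle on random data
  x <- random_parts(50, seed = 4)
  cm <- compositional_mean(x, total_scale = 1000)
  gm <- apply(x, 2, function(col) exp(mean(log(col))))
  expect_equal(cm$proportion, unname(gm / sum(gm)), tolerance = 1e-12)
})

test_that("SBP contrast matrices are orthonormal with the balance normalisation", {
  b <- default_basis()
  expect_equal(b$V[1, ], c(screen = sqrt(2 / 3), walking = -sqrt(1 / 6),
                           sportdiy = -sqrt(1 / 6)))
  expect_equal(b$V[2, ], c(screen = 0, walking = sqrt(1 / 2),
                           sportdiy = -sqrt(1 / 2)))
  for (basis in pivot_bases()) {
    expect_equal(basis$V %*% t(basis$V), diag(2), tolerance = 1e-12)
  }
  # malformed partitions rejected
  expect_error(sbp_contrast_matrix(list(list(num = "screen", den = "walking"))),
               "binary splits")
  expect_error(sbp_contrast_matrix(list(
    list(num = "screen", den = "walking"),
    list(num = "walking", den = "sportdiy"))), "sequential binary partition")
})

test_that("ilr transform matches the balance formula and is scale invariant", {
  z <- ilr_transform(c(screen = 1270, walking = 18, sportdiy = 51))
  expect_equal(unname(round(z[1, ], 4)), c(3.0502, -0.7364))
  # hand formula oracle
  expect_equal(unname(z[1, 1]), sqrt(2 / 3) * log(1270 / sqrt(18 * 51)),
               tolerance = 1e-12)
  expect_equal(unname(z[1, 2]), sqrt(1 / 2) * log(18 / 51), tolerance = 1e-12)

  expect_equal(unname(ilr_transform(c(7, 7, 7))[1, ]), c(0, 0))

  x <- random_parts(30, seed = 2)
  k <- exp(stats::runif(30, -3, 3))
  expect_equal(ilr_transform(x * k), ilr_transform(x),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(ilr_transform(cbind(x[, 1:2], sportdiy = 0)), "positive")
})

test_that("ilr inverse round-trips to the closed composition", {
  x <- random_parts(40, seed = 3)
  z <- ilr_transform(x)
  expect_equal(ilr_inverse(z), close_composition(x), tolerance = 1e-10)

  expect_equal(unname(ilr_inverse(c(0, 0), total_scale = 300)[1, ]),
               rep(100, 3))

  z0 <- ilr_transform(c(screen = 1270, walking = 18, sportdiy = 51))
  back <- ilr_inverse(z0, total_scale = 1339)
  expect_equal(unname(back[1, ]), c(1270, 18, 51), tolerance = 1e-8)

  other <- pivot_bases()$walking
  expect_error(ilr_inverse(z0, basis = other), "different balance basis")
})

test_that("pivot bases isolate each part and are rotations of one another", {
  bases <- pivot_bases()
  for (p in DT_PARTS) {
    v1 <- bases[[p]]$V[1, ]
    expect_gt(v1[p], 0)
    expect_true(all(v1[setdiff(DT_PARTS, p)] < 0))
  }
  x <- random_parts(10, seed = 9)
  zs <- lapply(bases, function(b) ilr_transform(x, b))
  # isometry: identical Gram matrices across the three coordinate sets
  for (z in zs[-1]) {
    expect_equal(tcrossprod(zs[[1]]), tcrossprod(z), tolerance = 1e-10)
  }
  # explicit rotation between bases
  R <- bases$screen$V %*% t(bases$walking$V)
  expect_equal(R %*% t(R), diag(2), tolerance = 1e-12)
  expect_equal(zs$screen %*% R, zs$walking, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("balances are equivariant under part permutation and subcompositionally coherent", {
  x <- random_parts(15, seed = 5)
  perm <- c("walking", "screen", "sportdiy")
  b_orig <- default_basis()
  b_perm <- sbp_contrast_matrix(
    list(list(num = "screen", den = c("walking", "sportdiy")),
         list(num = "walking", den = "sportdiy")),
    parts = perm)
  expect_equal(ilr_transform(x, b_orig), ilr_transform(x[, perm], b_perm),
               tolerance = 1e-12, ignore_attr = TRUE)

  # walking:sportdiy balance identical in the 3-part composition and in the
  # re-closed 2-part subcomposition
  b2 <- sbp_contrast_matrix(list(list(num = "walking", den = "sportdiy")),
                            parts = c("walking", "sportdiy"))
  sub <- close_composition(x[, c("walking", "sportdiy")])
  expect_equal(ilr_transform(x)[, 2], ilr_transform(sub, b2)[, 1],
               tolerance = 1e-10, ignore_attr = TRUE)
})
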