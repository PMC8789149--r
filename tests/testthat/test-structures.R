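test_that("closed-form structures match their printed parameterization", {
  expect_equal(prec_structure("ar1", 3),
               matrix(c(1, .7, .49, .7, 1, .7, .49, .7, 1), 3, 3))
  expect_equal(prec_structure("ar1", 3, component = 2),
               0.75 ^ abs(outer(1:3, 1:3, "-")))

  circ <- prec_structure("circle", 4)
  expect_equal(diag(circ), rep(2, 4))
  expect_equal(circ[cbind(1:3, 2:4)], rep(1, 3))
  expect_equal(circ[1, 4], 0.45)
  expect_equal(circ, t(circ))

  expect_equal(prec_structure("star", 3),
               matrix(c(1, .1, .1, .1, 1, 0, .1, 0, 1), 3, 3))

  ar2 <- prec_structure("ar2", 10)
  expect_equal(diag(ar2), rep(0.1, 10))
  expect_equal(ar2[1, 2], 0.05)
  expect_equal(ar2[1, 3], 0.025)
  expect_equal(ar2[1, 4], 0)

  band2 <- prec_structure("band", 10, component = 2)
  expect_equal(band2[1, 2], 0.7)
  expect_equal(band2[6, 10], 0.9)
  expect_equal(band2[1, 6], 0)
  expect_equal(diag(band2), rep(1, 10))
})

test_that("positive-definite repair follows the eigenvalue rule", {
  expect_identical(ensure_positive_definite(diag(2), 0.05), diag(2))
  expect_equal(ensure_positive_definite(matrix(0, 3, 3), 0.05),
               diag(0.05, 3))
  expect_error(ensure_positive_definite(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")

  # star component 2 as printed is indefinite; the repaired diagonal is
  # 1 + |gamma_min| + margin, verified against a direct eigen oracle
  raw <- matrix(c(1, 2.1, 2.1, 2.1, 1, 0, 2.1, 0, 1), 3, 3)
  gmin <- min(eigen(raw, symmetric = TRUE)$values)
  expect_lt(gmin, 0)
  expect_equal(gmin, 1 - 2.1 * sqrt(2), tolerance = 1e-12)
  repaired <- prec_structure("star", 3, component = 2)
  expect_equal(diag(repaired), rep(1 + abs(gmin) + 0.05, 3))
  expect_equal(repaired[1, 2], 2.1)
})

test_that("invalid dimensions are rejected", {
  expect_error(prec_structure("band", 9), "even")
  expect_error(prec_structure("cluster", 7), "even")
  expect_error(prec_structure("circle", 2), "at least 3")
  expect_error(prec_structure("sparse80", 10), "seed")
})

test_that("every structure is symmetric and admits a Cholesky factor", {
  for (st in all_structures) for (comp in 1:2) {
    M <- prec_structure(st, 10, comp, seed = 42)
    expect_true(isSymmetric(M, tol = 1e-12), info = paste(st, comp))
    expect_no_error(chol(M))
  }
})

test_that("generation is seed-reproducible and closed forms ignore the seed", {
  for (st in c("sparse80", "sparse40", "scalefree")) {
    expect_identical(prec_structure(st, 10, 1, seed = 5),
                     prec_structure(st, 10, 1, seed = 5))
    expect_false(identical(prec_structure(st, 10, 1, seed = 5),
                           prec_structure(st, 10, 1, seed = 6)))
  }
  for (st in c("ar1", "ar2", "band", "cluster", "star", "circle")) {
    expect_identical(prec_structure(st, 10, 1, seed = 5),
                     prec_structure(st, 10, 1, seed = 99))
  }
})

test_that("sparse structures respect their sparsity caps and share support", {
  for (spec in list(list(st = "sparse80", cap = 0.8),
                    list(st = "sparse40", cap = 0.4))) {
    for (seed in 1:5) {
      M1 <- prec_structure(spec$st, 40, 1, seed = seed)
      M2 <- prec_structure(spec$st, 40, 2, seed = seed)
      off1 <- M1[upper.tri(M1)]
      zero_frac <- mean(off1 == 0)
      # realized zero fraction tracks the stated cap to within 5
      # percentage points
      expect_gte(zero_frac, spec$cap - 0.05)
      expect_lte(zero_frac, spec$cap + 0.05)
      expect_identical(M1[upper.tri(M1)] == 0, M2[upper.tri(M2)] == 0)
    }
  }
})

test_that("scale-free component 2 is an exact multiple with shared support", {
  M1 <- prec_structure("scalefree", 12, 1, seed = 3)
  M2 <- prec_structure("scalefree", 12, 2, seed = 3)
  expect_identical(M2, 2 * M1)
  M3 <- prec_structure("scalefree", 12, 2, seed = 3,
                       scalefree_multiplier = 3.5)
  expect_identical(M3, 3.5 * M1)
  # a preferential-attachment tree has exactly p - 1 edges
  expect_equal(sum(M1[upper.tri(M1)] != 0), 11)
})

test_that("true differential network is the exact difference with support", {
  th1 <- prec_structure("ar1", 3)
  dn_same <- true_diffnet(th1, th1)
  expect_equal(dn_same$delta, matrix(0, 3, 3))
  expect_equal(sum(dn_same$adjacency), 0)

  th2 <- prec_structure("ar1", 3, component = 2)
  dn <- true_diffnet(th1, th2)
  expect_equal(dn$delta, th2 - th1)
  expect_equal(dn$delta[1, 2], 0.05)
  expect_true(all(dn$adjacency[upper.tri(dn$adjacency)] == 1))

  swapped <- true_diffnet(th2, th1)
  expect_equal(swapped$delta, -dn$delta)
  expect_identical(swapped$adjacency, dn$adjacency)

  expect_error(true_diffnet(th1, diag(4)), "dimension")
})

test_that("Gaussian sampling is seeded and consistent with the precision", {
  expect_identical(rggm(20, diag(3), seed = 1), rggm(20, diag(3), seed = 1))

  Y <- rggm(1e5, diag(4), seed = 2)
  expect_lt(max(abs(cov(Y) - diag(4))), 0.05)

  theta <- prec_structure("ar1", 3)
  Y <- rggm(1e5, theta, seed = 3)
  prec_mle <- solve(cov(Y))
  expect_lt(max(abs(prec_mle - theta)), 0.1)
})
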