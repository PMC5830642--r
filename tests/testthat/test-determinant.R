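test_that("brute-force determinant summary handles canonical cases", {
  id5 <- sym_matrix(diag(5L) * SYM_ONE)
  expect_equal(det_fields(det_summary_bruteforce(id5)),
               c(T = 1, n1 = 5, nbar = 0, ndbl = 0))
  # structurally singular: an all-zero column kills every term
  M <- sym_matrix(matrix(SYM_DBL, 4L, 4L))
  M[, 2L] <- SYM_ZERO
  expect_equal(det_summary_bruteforce(M)$T, 0)
  # single-sensor matrix of the 5D circadian model
  O <- build_matrix(fixture_model("goldbeter5d")$jacobian, "x5^5")
  expect_equal(det_fields(det_summary_bruteforce(O)),
               c(T = 1, n1 = 2, nbar = 0, ndbl = 3))
  expect_error(det_summary_bruteforce(sym_matrix(matrix(1L, 9L, 9L))),
               "d <= 8")
})

test_that("subset-recursion summary agrees with the brute-force oracle", {
  for (seed in 1:120) {
    d <- 2L + (seed %% 5L)  # 2..6
    M <- random_symbol_matrix(d, density = stats::runif(1, 0.2, 0.9),
                              seed = seed)
    expect_equal(det_fields(det_summary(M)),
                 det_fields(det_summary_bruteforce(M)),
                 info = paste("seed", seed))
  }
})

test_that("identical rows contribute separate terms (no deduplication)", {
  M <- sym_matrix(rbind(c(SYM_DBL, SYM_DBL, SYM_DBL),
                        c(SYM_DBL, SYM_DBL, SYM_DBL),
                        c(SYM_ONE, SYM_ONE, SYM_ONE)))
  s <- det_summary(M)
  expect_equal(s$T, 6)  # all 3! assignments survive
  expect_equal(det_fields(s), det_fields(det_summary_bruteforce(M)))
  expect_equal(s$n1 + s$nbar + s$ndbl, 3 * s$T)
})

test_that("coefficient reproduces the published summary examples", {
  eta_of <- function(M) observability_coefficient(det_summary(M))
  J <- fixture_model("goldbeter5d")$jacobian
  # (T=1, N1=2, Ndbl=3): rational condition lifts Nbar to 3, D = 8
  r <- eta_of(build_matrix(J, "x5^5"))
  expect_equal(r$D, 8)
  expect_equal(r$eta_num / r$eta_den, 2 / 8 + 3 / 64 + 3 / 512)
  expect_equal(r$eta_2dp, 0.30)
  # (T=1, N1=4, Ndbl=1): D = 6
  r <- eta_of(build_matrix(J, "x2^2 x3^2 x5"))
  expect_equal(r$D, 6)
  expect_equal(r$eta_2dp, 0.70)
  # all-linear single term: exactly 1
  r <- eta_of(build_matrix(J, "x2^2 x3 x5^2"))
  expect_identical(r$eta, 1)
  expect_identical(r$eta_num, r$eta_den)
  # empty determinant: 0
  r <- eta_of(build_matrix(J, "x1^2 x5^3"))
  expect_identical(r$eta, 0)
})

test_that("exact rounding is half away from zero at the second decimal", {
  # x1 x5^4 gives exactly 163/343 = 0.47522...; and the classic boundary:
  # a single term with N1=3, Nbar=2 has eta = 3/5 + 2/25 = 0.68 exactly
  r <- coefficient_for(fixture_model("goldbeter5d"), "x1 x5^4")
  expect_equal(r$eta_num, 163)
  expect_equal(r$eta_den, 343)
  expect_equal(r$eta_2dp, 0.48)
  M <- sym_matrix(diag(c(1L, 1L, 1L, 2L, 2L)))
  r <- observability_coefficient(det_summary(M))
  expect_equal(r$eta, 0.68)
  expect_equal(r$eta_2dp, 0.68)
})

test_that("eta lies in [0,1], hitting 1 only for all-linear terms", {
  for (seed in 1:60) {
    d <- sample(2:6, 1L)
    M <- random_symbol_matrix(d, density = stats::runif(1, 0.2, 1),
                              weights = stats::runif(3), seed = seed + 500L)
    s <- det_summary(M)
    r <- observability_coefficient(s)
    expect_gte(r$eta, 0)
    expect_lte(r$eta, 1)
    expect_identical(r$eta == 1, s$T >= 1 && s$nbar == 0 && s$ndbl == 0)
  }
})

test_that("eta is invariant under row permutation", {
  for (seed in 1:25) {
    d <- sample(3:7, 1L)
    M <- random_symbol_matrix(d, density = 0.5, seed = seed + 900L)
    P <- sym_matrix(unclass(M)[sample(d), , drop = FALSE])
    expect_equal(det_fields(det_summary(M)), det_fields(det_summary(P)))
  }
})

test_that("eta is invariant under whole-model variable relabeling", {
  for (seed in 1:15) {
    d <- sample(3:6, 1L)
    M <- random_symbol_matrix(d, density = 0.6, seed = seed + 1300L)
    perm <- sample(d)  # new index a <-> old variable perm[a]
    M2 <- sym_matrix(unclass(M)[perm, perm, drop = FALSE])
    m <- sample(seq_len(max(1L, d - 1L)), 1L)
    vars <- sort(sample(d, m))
    counts <- as.integer(stats::rmultinom(1L, d - m, rep(1, m))) + 1L
    c1 <- measurement_config(vars, counts)
    c2 <- measurement_config(match(vars, perm), counts)
    e1 <- observability_coefficient(det_summary(build_matrix(M, c1)))
    e2 <- observability_coefficient(det_summary(build_matrix(M2, c2)))
    expect_equal(e1$eta, e2$eta, info = paste("seed", seed))
  }
})

test_that("degrading one symbol of a single-term determinant lowers eta", {
  etas <- vapply(c(SYM_ONE, SYM_BAR, SYM_DBL), function(w) {
    M <- sym_matrix(diag(c(1L, 1L, 1L, 1L, w)))
    observability_coefficient(det_summary(M))$eta
  }, numeric(1))
  expect_true(all(diff(etas) < 0))
  expect_equal(round(etas, 2L), c(1, 0.84, 0.70))
})

test_that("end-to-end coefficients respect the model dimension contract", {
  g <- fixture_model("goldbeter5d")
  expect_error(coefficient_for(g, measurement_config(1L, 4L)), "dimension")
  r <- coefficient_for(g, "x1 x5^4")
  expect_equal(attr(r, "config_string"), "x1 x5^4")
})
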