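test_that("circadian 5D fixture classifies to its known symbolic Jacobian", {
  m <- fixture_model("goldbeter5d")
  expect_equal(m$d, 5L)
  expect_sym_equal(m$jacobian, jac5d_expected)
  expect_true(all(paste0("x", 1:5) == m$variables))
})

test_that("cell-cycle 13D fixture classifies to its known symbolic Jacobian", {
  m <- fixture_model("dna13d")
  expect_equal(m$d, 13L)
  expect_sym_equal(m$jacobian, jac13d_expected)
})

test_that("9D convection Jacobian is derived from the equations", {
  m <- fixture_model("rayleigh_benard9d")
  expect_sym_equal(m$jacobian, jac9d_derived_expected)
  # the historical hand-typed matrix differs at known entries
  p <- fixture_model("rayleigh_benard9d", jacobian = "printed")
  expect_null(p$rhs)
  expect_identical(p$jacobian[7L, 6L], SYM_ONE)   # derived: 0
  expect_identical(p$jacobian[8L, 5L], SYM_ZERO)  # derived: 1b
  expect_identical(p$jacobian[8L, 6L], SYM_BAR)   # derived: 0
  expect_identical(m$jacobian[7L, 6L], SYM_ZERO)
  expect_identical(m$jacobian[8L, 5L], SYM_BAR)
  expect_identical(m$jacobian[8L, 6L], SYM_ZERO)
})

test_that("entry classification follows the four-way rule", {
  vars5 <- paste0("x", 1:5)
  # partial of the mRNA equation w.r.t. nuclear protein: rational in x5
  expect_identical(
    classify_entry("-4*vs*KI^4*x5^3/(KI^4 + x5^4)^2", "x5", vars5),
    SYM_DBL
  )
  expect_identical(classify_entry("k1", "x4", vars5), SYM_ONE)
  # rational whose denominator does not involve the probe variable
  vars13 <- paste0("x", 1:13)
  expect_identical(
    classify_entry("kc*beta*(1 - x12)/(Kmc + 1 - x12)", "x8", vars13),
    SYM_BAR
  )
  expect_identical(classify_entry("0", "x1", vars5), SYM_ZERO)
  expect_identical(classify_entry("2*x1*x2", "x1", vars5), SYM_BAR)
})

test_that("classification cancels common factors before the denominator test", {
  # (x1*x2)/(x2*(K + x1)) reduces to x1/(K + x1): constant in x2,
  # rational in x1 -- despite x2 appearing in the raw denominator
  vars <- c("x1", "x2")
  expect_identical(
    classify_entry("(x1*x2)/(x2*(K + x1))", "x2", vars), SYM_BAR)
  expect_identical(
    classify_entry("(x1*x2)/(x2*(K + x1))", "x1", vars), SYM_DBL)
})

test_that("classification is invariant under nonzero parameter rescaling", {
  vars <- paste0("x", 1:3)
  exprs <- c("k1", "x2*x3", "x1/(K + x1)", "x2/( (K + x3)^2 )")
  for (e in exprs) {
    for (xj in vars) {
      expect_identical(
        classify_entry(sprintf("c0*(%s)", e), xj, vars),
        classify_entry(e, xj, vars),
        info = paste(e, xj)
      )
    }
  }
})

test_that("non-rational vector fields are rejected", {
  expect_error(system_model(c("x1", "x2"),
                            rhs = c("exp(x1)", "x1 - x2")),
               "non-rational")
  expect_error(system_model(c("x1", "x2"),
                            rhs = c("x1^0.5", "x1 - x2")),
               "integer powers")
})

test_that("model documents parse with the free-name parameter rule", {
  doc <- "
name: toy
variables: [u, v]
equations:
  - \"k1*v - u\"
  - \"-k2*v + u*v\"
"
  m <- parse_model(doc)
  expect_equal(m$d, 2L)
  expect_true(all(c("k1", "k2") %in% m$parameters))
  expect_sym_equal(m$jacobian, tokmat(c("1 1", "1b 1b")))
})

test_that("jacobian-only documents parse without right-hand sides", {
  doc <- "
name: toy
variables: [x1, x2]
jacobian:
  - [\"1\", \"0\"]
  - [\"0\", \"1\"]
"
  m <- parse_model(doc)
  expect_null(m$rhs)
  expect_sym_equal(m$jacobian, sym_matrix(diag(2L) * SYM_ONE))
})

test_that("schema violations fail loudly", {
  expect_error(parse_model("
variables: [x1, x1]
equations: [\"x1\", \"x1\"]
"), "duplicate")
  expect_error(parse_model("
variables: [x1, x2]
jacobian:
  - [\"1\"]
  - [\"0\"]
"), "jacobian")
  expect_error(system_model(c("x1", "x2"), rhs = c("x1 +* x2", "x1")),
               "malformed expression")
  expect_error(system_model(c("x1", "x2")), "either")
  expect_error(fixture_model("nope"), "arg")
})

test_that("linearization keeps sparsity and erases nonlinearity", {
  m <- fixture_model("dna13d")
  expect_sym_equal(linearize_symbols(m$jacobian), jac13d_linear_expected)
  z <- sym_matrix(matrix(SYM_ZERO, 3L, 3L))
  expect_sym_equal(linearize_symbols(z), z)
  one_dbl <- sym_matrix(matrix(c(SYM_DBL, SYM_ZERO, SYM_ZERO, SYM_ZERO),
                               2L, 2L))
  expect_sym_equal(linearize_symbols(one_dbl),
                   sym_matrix(matrix(c(SYM_ONE, SYM_ZERO, SYM_ZERO,
                                       SYM_ZERO), 2L, 2L)))
})
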