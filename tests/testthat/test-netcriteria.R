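test_that("linear out-strength matches the fixture walkthroughs", {
  expect_identical(linear_out_strength(jac5d_expected),
                   c(1L, 0L, 0L, 1L, 1L))
  s13 <- linear_out_strength(jac13d_expected)
  expect_identical(s13, c(1L, 0L, 0L, 2L, 0L, 0L, 0L, 1L, 2L, 2L,
                          0L, 0L, 0L))
  # the convection system: x9 feeds two equations linearly (the
  # published walkthrough under-counted it as 1)
  s9 <- linear_out_strength(jac9d_derived_expected)
  expect_identical(s9, c(1L, 0L, 1L, 0L, 0L, 0L, 1L, 1L, 2L))
  # diagonal entries never count
  expect_identical(linear_out_strength(sym_matrix(diag(3L) * SYM_ONE)),
                   rep(0L, 3L))
})

test_that("non-measured in-strength matches the fixture walkthroughs", {
  s <- nonmeasured_in_strength(jac9d_derived_expected, c(1L, 3L, 7L, 8L, 9L))
  expect_identical(unname(s[c(1L, 3L, 7L, 8L, 9L)]), c(3L, 3L, 5L, 5L, 4L))
  s <- nonmeasured_in_strength(jac13d_expected, c(1L, 4L, 8L, 9L, 10L))
  expect_identical(unname(s[9L]), 0L)
  expect_identical(unname(s[c(1L, 4L, 8L, 10L)]), rep(2L, 4L))
  # a variable with no couplings from the candidate set scores zero
  M <- sym_matrix(diag(3L) * SYM_DBL)
  expect_identical(unname(nonmeasured_in_strength(M, c(2L, 3L))[1L]), 0L)
  expect_error(nonmeasured_in_strength(M, integer(0)), "non-empty")
})

test_that("exclusive pairs are mutually and solely linearly coupled", {
  sig5 <- linear_out_strength(jac5d_expected)
  expect_equal(exclusive_pairs(jac5d_expected, which(sig5 > 0L), sig5),
               matrix(c(4L, 5L), 1L, dimnames = list(NULL, c("i", "j"))),
               ignore_attr = TRUE)
  sig9 <- linear_out_strength(jac9d_derived_expected)
  p9 <- exclusive_pairs(jac9d_derived_expected, which(sig9 > 0L), sig9)
  expect_equal(nrow(p9), 2L)
  expect_true(all(p9 == rbind(c(1L, 7L), c(3L, 8L))))
  expect_false(9L %in% p9)  # x9 has strength 2, in no pair
  sig13 <- linear_out_strength(jac13d_expected)
  p13 <- exclusive_pairs(jac13d_expected, which(sig13 > 0L), sig13)
  expect_true(all(p13 == c(1L, 8L)))
})

test_that("5D preselection branches on the tied exclusive pair", {
  rep5 <- preselect(fixture_model("goldbeter5d"))
  expect_identical(rep5$essential, c(2L, 3L))
  sets <- sensor_sets(rep5)
  expect_equal(length(sets), 2L)
  expect_true(any(vapply(sets, identical, logical(1), c(2L, 3L, 4L))))
  expect_true(any(vapply(sets, identical, logical(1), c(2L, 3L, 5L))))
})

test_that("9D preselection removes x7, x8, x9 with a single branch", {
  rep9 <- preselect(fixture_model("rayleigh_benard9d"))
  expect_identical(rep9$essential, c(2L, 4L, 5L, 6L))
  expect_equal(length(rep9$branches), 1L)
  expect_identical(rep9$branches[[1L]]$removed, c(7L, 8L, 9L))
  expect_identical(rep9$branches[[1L]]$sensors, 1:6)
})

test_that("13D preselection cannot resolve the x1/x8 tie", {
  rep13 <- preselect(fixture_model("dna13d"))
  sets <- sensor_sets(rep13)
  expect_equal(length(sets), 2L)
  ess <- c(2L, 3L, 5L, 6L, 7L, 11L, 12L, 13L)
  expect_identical(rep13$essential, ess)
  expect_true(any(vapply(sets, identical, logical(1), sort(c(ess, 1L)))))
  expect_true(any(vapply(sets, identical, logical(1), sort(c(ess, 8L)))))
  for (br in rep13$branches) {
    expect_true(all(c(4L, 9L, 10L) %in% br$removed))
  }
})

test_that("sensor sets contain all essentials and one of each pair", {
  for (name in c("goldbeter5d", "rayleigh_benard9d", "dna13d")) {
    rep_ <- preselect(fixture_model(name))
    for (br in rep_$branches) {
      expect_true(all(rep_$essential %in% br$sensors))
      if (nrow(rep_$exclusive_pairs)) {
        for (r in seq_len(nrow(rep_$exclusive_pairs))) {
          pair <- rep_$exclusive_pairs[r, ]
          expect_equal(sum(pair %in% br$removed), 1L)
        }
      }
    }
  }
})

test_that("a candidate unseen by any measured equation is retained", {
  # x1 feeds only x2's equation; both x1 and x2 are removal candidates,
  # so dropping both would leave x1 invisible -- it must be retained
  J <- tokmat(c("1 0 0",
                "1 1 0",
                "0 1 1"))
  m <- system_model(paste0("x", 1:3), jacobian = J)
  rep_ <- preselect(m)
  br <- rep_$branches[[1L]]
  expect_identical(br$removed, 2L)
  expect_identical(br$sensors, c(1L, 3L))
  expect_false(br$reachable[["x1"]])
})
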