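test_that("configuration counts match the closed form", {
  expect_equal(count_configs(5L), 125)
  expect_equal(count_configs(9L), 24309)
  expect_equal(count_configs(2L), 2)
  expect_equal(count_configs(13L), 5200299)
  expect_error(count_configs(1L), "at least 2")
  expect_error(count_configs(5L, 3L, 2L), "invalid range")
})

test_that("enumeration is exhaustive, unique and canonical", {
  cfgs <- enumerate_configs(5L)
  expect_equal(length(cfgs), 125L)
  strs <- vapply(cfgs, format_config, character(1))
  expect_false(anyDuplicated(strs) > 0L)
  expect_true(all(vapply(cfgs, `[[`, numeric(1), "total") == 5))
  # d = 3, exactly two sensors: 3 pairs x 2 derivative placements
  cfgs32 <- enumerate_configs(3L, search_spec(m_min = 2L, m_max = 2L))
  expect_equal(length(cfgs32), 6L)
  # forbidding a variable prunes the sets that contain it
  cfgs_f <- enumerate_configs(3L, search_spec(m_min = 2L, m_max = 2L,
                                              forbidden = 1L))
  expect_equal(length(cfgs_f), 2L)
  expect_true(all(vapply(cfgs_f, function(cf)
    identical(cf$vars, c(2L, 3L)), logical(1))))
})

test_that("enumeration cardinality equals the closed form on random ranges", {
  set.seed(42)
  for (case in 1:40) {
    d <- sample(2:8, 1L)
    m1 <- pick1(seq_len(d - 1L))
    m2 <- pick1(m1:(d - 1L))
    n <- length(enumerate_configs(d, search_spec(m_min = m1, m_max = m2)))
    expect_equal(n, count_configs(d, m1, m2), info = paste(d, m1, m2))
  }
})

test_that("only two completions of the preselected 5D sensor sets are full", {
  g <- fixture_model("goldbeter5d")
  res <- lapply(list(c(2L, 3L, 4L), c(2L, 3L, 5L)), function(set) {
    evaluate_configs(g, search_spec(
      m_min = 3L, m_max = 3L, required = set,
      forbidden = setdiff(1:5, set), retain_all = TRUE))
  })
  all_rows <- do.call(rbind, lapply(res, as.data.frame))
  expect_equal(nrow(all_rows), 12L)  # 6 derivative placements per set
  full <- all_rows[all_rows$eta == 1, ]
  expect_equal(sort(full$config), c("x2^2 x3 x4^2", "x2^2 x3 x5^2"))
})

test_that("leave-one-out full observability needs a linear out-coupling", {
  # eta = 1 at (excluded j, derivative i) exactly when J[i, j] is linear:
  # the unit rows force a single determinant term, whose only non-direct
  # factor is J[i, j] itself
  for (name in c("goldbeter5d", "rayleigh_benard9d")) {
    m <- fixture_model(name)
    scan <- leave_one_out_scan(m)
    J <- m$jacobian
    pred <- mapply(function(j, i) J[i, j] == SYM_ONE,
                   scan$excluded, scan$derivative)
    expect_identical(scan$eta == 1, unname(pred), info = name)
  }
})

test_that("reduced search results are a subset of the exhaustive search", {
  g <- fixture_model("goldbeter5d")
  spec <- search_spec(min_eta = 0, retain_all = TRUE)
  full <- as.data.frame(evaluate_configs(g, spec))
  red <- as.data.frame(reduced_search(g, spec = spec))
  expect_true(all(red$config %in% full$config))
  merged <- merge(red, full, by = "config")
  expect_equal(merged$eta.x, merged$eta.y)
  expect_lt(nrow(red), nrow(full))
})

test_that("9D reduced search at m = 6 finds full observability only from
           the preselected sensors", {
  m9 <- fixture_model("rayleigh_benard9d")
  res <- reduced_search(m9, spec = search_spec(m_min = 6L, m_max = 6L,
                                               min_eta = 1))
  expect_gt(nrow(res), 0L)
  expect_true(all(res$eta == 1))
  for (cfg in res$config) {
    vars <- parse_config(cfg, m9$variables)$vars
    expect_identical(vars, 1:6)
  }
})

test_that("rankings are ordered by eta, then sensor count, then name", {
  g <- fixture_model("goldbeter5d")
  res <- evaluate_configs(g, search_spec(min_eta = 0, retain_all = TRUE))
  expect_equal(nrow(res), 125L)
  expect_true(all(diff(res$eta) <= 0))
  ties <- split(seq_len(nrow(res)), res$eta)
  for (idx in ties) {
    expect_true(all(diff(res$m[idx]) >= 0))
  }
  expect_identical(attr(res, "evaluated"), 125L)
})
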