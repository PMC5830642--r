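# Reference symbol matrices for the bundled models, frozen from the
# published equations (the 9D one from independent hand differentiation
# of the convection equations).

tokmat <- function(rows) {
  sym_matrix(do.call(rbind, lapply(rows, function(r)
    strsplit(trimws(r), "\\s+")[[1L]])))
}

jac5d_expected <- tokmat(c(
  "1bb 0   0   0   1bb",
  "1   1bb 1bb 0   0",
  "0   1bb 1bb 1bb 0",
  "0   0   1bb 1bb 1",
  "0   0   0   1   1"
))

jac9d_derived_expected <- tokmat(c(
  "1  1b 1b 1b 1b 0  1  0  0",
  "1b 1b 0  1b 1b 0  0  0  1",
  "1b 1b 1  1b 1b 0  0  1  0",
  "0  1b 1b 1b 1b 0  0  0  1",
  "0  1b 0  1b 1  0  0  0  0",
  "0  1b 0  1b 0  1  0  0  1b",
  "1  0  0  1b 1b 0  1  1b 1b",
  "0  1b 1  0  1b 0  1b 1  1b",
  "0  1b 0  1b 0  1b 1b 1b 1"
))

jac13d_expected <- tokmat(c(
  "1b 1b  0  1 0   0   0   1  0 0 0   0   0",
  "1b 1bb 1b 1 0   0   0   1b 1 1 0   0   1b",
  "0  1b  1b 0 0   0   0   0  1 0 0   0   0",
  "1b 1b  0  1 0   0   0   0  0 0 0   0   0",
  "1b 0   0  0 1bb 0   0   1b 0 0 0   0   0",
  "1b 0   0  0 0   1bb 0   1b 0 0 0   0   0",
  "1b 0   0  0 0   0   1bb 1b 0 0 0   0   0",
  "1  1b  0  0 0   0   0   1b 0 1 0   0   0",
  "0  1b  1b 0 0   0   0   0  1 0 0   0   0",
  "0  1b  0  0 0   0   0   1b 0 1 0   0   0",
  "0  0   0  0 1b  0   0   0  0 0 1bb 0   0",
  "1b 0   0  0 0   0   0   1b 0 0 0   1bb 0",
  "0  0   0  0 0   0   0   0  0 0 0   0   1"
))

jac13d_linear_expected <- tokmat(c(
  "1 1 0 1 0 0 0 1 0 0 0 0 0",
  "1 1 1 1 0 0 0 1 1 1 0 0 1",
  "0 1 1 0 0 0 0 0 1 0 0 0 0",
  "1 1 0 1 0 0 0 0 0 0 0 0 0",
  "1 0 0 0 1 0 0 1 0 0 0 0 0",
  "1 0 0 0 0 1 0 1 0 0 0 0 0",
  "1 0 0 0 0 0 1 1 0 0 0 0 0",
  "1 1 0 0 0 0 0 1 0 1 0 0 0",
  "0 1 1 0 0 0 0 0 1 0 0 0 0",
  "0 1 0 0 0 0 0 1 0 1 0 0 0",
  "0 0 0 0 1 0 0 0 0 0 1 0 0",
  "1 0 0 0 0 0 0 1 0 0 0 1 0",
  "0 0 0 0 0 0 0 0 0 0 0 0 1"
))

# strip class/attrs for bare-matrix comparison
symbols_of <- function(M) {
  out <- unclass(M)
  attributes(out) <- list(dim = dim(out))
  out
}

expect_sym_equal <- function(a, b) {
  expect_identical(symbols_of(a), symbols_of(b))
}

det_fields <- function(s) unlist(s[c("T", "n1", "nbar", "ndbl")])

# size-safe sampling of one element (sample() misreads length-1 vectors)
pick1 <- function(x) x[sample.int(length(x), 1L)]
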