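# Internal exact arithmetic for classifying Jacobian entries.
#
# Partial derivatives of a rational vector field are held as ratios of
# multivariate polynomials in the state variables, with parameters replaced
# by deterministic nonzero residues modulo a prime. All coefficient
# arithmetic is done modulo .POLY_PRIME, which keeps zero tests exact
# (no floating-point cancellation) while staying inside the exactly
# representable double range: the prime is < 2^25 so products fit in 2^53.
# Classification repeats the whole pipeline under two independent parameter
# assignments ("salts") and keeps the more severe outcome, so an accidental
# cancellation for one unlucky assignment cannot demote a symbol.

.POLY_PRIME <- 33554393  # prime, 2^25 - 39

.mod <- function(x) x %% .POLY_PRIME

# modular exponentiation by squaring
.mod_pow <- function(base, e) {
  base <- .mod(base)
  r <- 1
  while (e > 0) {
    if (e %% 2 == 1) r <- .mod(r * base)
    base <- .mod(base * base)
    e <- e %/% 2
  }
  r
}

# modular inverse via Fermat (prime modulus)
.mod_inv <- function(a) {
  a <- .mod(a)
  if (a == 0) stop("division by zero residue in modular arithmetic")
  .mod_pow(a, .POLY_PRIME - 2)
}

# A polynomial in nv variables: list(e = nterms x nv exponent matrix,
# c = numeric coefficient vector of residues). Zero polynomial: 0 terms.
.p_make <- function(e, c) {
  keep <- c != 0
  list(e = e[keep, , drop = FALSE], c = c[keep])
}

.p_zero <- function(nv) {
  list(e = matrix(0L, nrow = 0L, ncol = nv), c = numeric(0))
}

.p_const <- function(val, nv) {
  val <- .mod(val)
  if (val == 0) return(.p_zero(nv))
  list(e = matrix(0L, nrow = 1L, ncol = nv), c = val)
}

.p_var <- function(j, nv) {
  e <- matrix(0L, nrow = 1L, ncol = nv)
  e[1L, j] <- 1L
  list(e = e, c = 1)
}

.p_is_zero <- function(p) length(p$c) == 0L

# combine duplicate exponent rows
.p_norm <- function(p) {
  if (length(p$c) <= 1L) return(.p_make(p$e, p$c))
  key <- apply(p$e, 1L, paste, collapse = ",")
  c2 <- vapply(split(p$c, key), function(v) .mod(sum(v)), numeric(1))
  first <- !duplicated(key)
  e2 <- p$e[first, , drop = FALSE]
  c2 <- c2[match(key[first], names(c2))]
  .p_make(e2, unname(c2))
}

.p_add <- function(a, b) {
  .p_norm(list(e = rbind(a$e, b$e), c = c(a$c, b$c)))
}

.p_neg <- function(a) {
  list(e = a$e, c = .mod(-a$c))
}

.p_sub <- function(a, b) .p_add(a, .p_neg(b))

.p_scale <- function(a, k) {
  k <- .mod(k)
  if (k == 0) return(.p_zero(ncol(a$e)))
  list(e = a$e, c = .mod(a$c * k))
}

.p_mul <- function(a, b) {
  na <- length(a$c); nb <- length(b$c)
  if (na == 0L || nb == 0L) return(.p_zero(ncol(a$e)))
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  e <- a$e[ia, , drop = FALSE] + b$e[ib, , drop = FALSE]
  .p_norm(list(e = e, c = .mod(a$c[ia] * b$c[ib])))
}

.p_pow <- function(a, k) {
  nv <- ncol(a$e)
  r <- .p_const(1, nv)
  while (k > 0L) {
    if (k %% 2L == 1L) r <- .p_mul(r, a)
    a <- .p_mul(a, a)
    k <- k %/% 2L
  }
  r
}

.p_deriv <- function(a, j) {
  keep <- a$e[, j] > 0L
  if (!any(keep)) return(.p_zero(ncol(a$e)))
  e <- a$e[keep, , drop = FALSE]
  c <- .mod(a$c[keep] * e[, j])
  e[, j] <- e[, j] - 1L
  .p_norm(list(e = e, c = c))
}

# Restrict to variable j: substitute residues `vals` for the others and
# return the univariate coefficient vector (degree 0 upward).
.p_restrict <- function(a, j, vals) {
  if (length(a$c) == 0L) return(numeric(0))
  others <- setdiff(seq_len(ncol(a$e)), j)
  scale <- rep(1, length(a$c))
  for (k in others) {
    ek <- a$e[, k]
    if (any(ek > 0L)) {
      pk <- vapply(ek, function(e) .mod_pow(vals[k], e), numeric(1))
      scale <- .mod(scale * pk)
    }
  }
  co <- .mod(a$c * scale)
  degs <- a$e[, j]
  out <- numeric(max(degs) + 1L)
  for (i in seq_along(co)) {
    out[degs[i] + 1L] <- .mod(out[degs[i] + 1L] + co[i])
  }
  while (length(out) > 0L && out[length(out)] == 0) out <- out[-length(out)]
  out
}

.u_deg <- function(u) length(u) - 1L

# univariate remainder modulo the prime
.u_rem <- function(a, b) {
  db <- .u_deg(b)
  if (db < 0L) stop("polynomial division by zero")
  inv_lead <- .mod_inv(b[length(b)])
  while (.u_deg(a) >= db && length(a) > 0L) {
    da <- .u_deg(a)
    f <- .mod(a[length(a)] * inv_lead)
    idx <- (da - db) + seq_along(b)
    a[idx] <- .mod(a[idx] - f * b)
    while (length(a) > 0L && a[length(a)] == 0) a <- a[-length(a)]
  }
  a
}

.u_gcd <- function(a, b) {
  while (length(b) > 0L) {
    r <- .u_rem(a, b)
    a <- b
    b <- r
  }
  if (length(a) == 0L) return(a)
  .mod(a * .mod_inv(a[length(a)]))  # monic
}

# Degree in variable j of num/den of the *reduced* rational a/b, probed at
# `trials` generic specializations of the other variables. A degenerate
# specialization can only enlarge the cancelled factor (shrink the reduced
# degrees), so the maximum over trials is reported.
.r_reduced_degrees <- function(num, den, j, nv, rng, trials = 3L) {
  best <- c(num = -1L, den = -1L)
  done <- 0L
  guard <- 0L
  while (done < trials && guard < 20L) {
    guard <- guard + 1L
    vals <- .rng_residues(rng, nv)
    un <- .p_restrict(num, j, vals)
    ud <- .p_restrict(den, j, vals)
    if (length(ud) == 0L) next  # denominator vanished: retry
    done <- done + 1L
    if (length(un) == 0L) {
      best["den"] <- max(best["den"], 0L)
      best["num"] <- max(best["num"], 0L)
      next
    }
    g <- .u_gcd(un, ud)
    dn <- .u_deg(un) - .u_deg(g)
    dd <- .u_deg(ud) - .u_deg(g)
    best["num"] <- max(best["num"], dn)
    best["den"] <- max(best["den"], dd)
  }
  if (done == 0L) stop("could not find a non-degenerate specialization")
  best
}

# Small deterministic linear-congruential stream, independent of R's RNG,
# so that classification never perturbs (or depends on) the session seed.
.rng_new <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- (seed %% 2147483647) + 1
  env
}

.rng_next <- function(rng) {
  # Park-Miller minimal standard generator
  rng$state <- (rng$state * 48271) %% 2147483647
  rng$state
}

.rng_residues <- function(rng, n) {
  vapply(seq_len(n), function(i) (.rng_next(rng) %% (.POLY_PRIME - 7)) + 3,
         numeric(1))
}

# Deterministic nonzero residue for a parameter name under a given salt.
.param_residue <- function(name, salt) {
  h <- salt * 7919 + 1
  for (code in utf8ToInt(name)) {
    h <- .mod(h * 131 + code * 977 + salt)
  }
  if (h < 2) h <- h + 2
  h
}

# ---- expression -> rational form ------------------------------------------

# Rational form: list(num = poly, den = poly). Built by recursion over the
# R expression AST. `var_index` maps state-variable names to 1..nv;
# any other name is treated as a constant parameter.
.rat_const <- function(val, nv) list(num = .p_const(val, nv),
                                     den = .p_const(1, nv))

.rat_add <- function(a, b) {
  list(num = .p_add(.p_mul(a$num, b$den), .p_mul(b$num, a$den)),
       den = .p_mul(a$den, b$den))
}

.rat_neg <- function(a) list(num = .p_neg(a$num), den = a$den)

.rat_mul <- function(a, b) {
  list(num = .p_mul(a$num, b$num), den = .p_mul(a$den, b$den))
}

.rat_div <- function(a, b) {
  if (.p_is_zero(b$num)) {
    stop("division by an expression that is identically zero", call. = FALSE)
  }
  list(num = .p_mul(a$num, b$den), den = .p_mul(a$den, b$num))
}

.rat_pow <- function(a, k) {
  if (k < 0L) {
    a <- list(num = a$den, den = a$num)
    k <- -k
  }
  list(num = .p_pow(a$num, k), den = .p_pow(a$den, k))
}

.rat_deriv <- function(a, j) {
  num <- .p_sub(.p_mul(.p_deriv(a$num, j), a$den),
                .p_mul(a$num, .p_deriv(a$den, j)))
  list(num = num, den = .p_mul(a$den, a$den))
}

# Literal numbers may be decimal; map c = a/10^k to a * inv(10^k) mod p.
.literal_residue <- function(x) {
  if (x == round(x)) return(.mod(x))
  for (k in 1:9) {
    scaled <- x * 10^k
    if (abs(scaled - round(scaled)) < 1e-9) {
      return(.mod(.mod(round(scaled)) * .mod_inv(.mod_pow(10, k))))
    }
  }
  stop("numeric literal ", x, " is not a short decimal; use a ratio instead",
       call. = FALSE)
}

.expr_to_rational <- function(expr, var_index, salt, param_env) {
  nv <- length(var_index)
  rec <- function(e) {
    if (is.numeric(e)) {
      return(.rat_const(.literal_residue(e), nv))
    }
    if (is.name(e)) {
      nm <- as.character(e)
      j <- unname(var_index[nm])
      if (!is.na(j)) {
        return(list(num = .p_var(j, nv), den = .p_const(1, nv)))
      }
      if (!is.null(param_env)) param_env$seen <- union(param_env$seen, nm)
      return(.rat_const(.param_residue(nm, salt), nv))
    }
    if (!is.call(e)) {
      stop("unsupported construct in expression: ", deparse(e), call. = FALSE)
    }
    op <- as.character(e[[1L]])
    if (op == "(") return(rec(e[[2L]]))
    if (op == "+" && length(e) == 2L) return(rec(e[[2L]]))
    if (op == "-" && length(e) == 2L) return(.rat_neg(rec(e[[2L]])))
    if (op == "+") return(.rat_add(rec(e[[2L]]), rec(e[[3L]])))
    if (op == "-") return(.rat_add(rec(e[[2L]]), .rat_neg(rec(e[[3L]]))))
    if (op == "*") return(.rat_mul(rec(e[[2L]]), rec(e[[3L]])))
    if (op == "/") return(.rat_div(rec(e[[2L]]), rec(e[[3L]])))
    if (op == "^") {
      k <- e[[3L]]
      if (!is.numeric(k) || k != round(k)) {
        stop("only integer powers are supported in rational models, got: ",
             deparse(e), call. = FALSE)
      }
      return(.rat_pow(rec(e[[2L]]), as.integer(k)))
    }
    stop("non-rational construct `", op, "` in expression: ", deparse(e),
         "; only +, -, *, /, ^ over variables, parameters and numbers ",
         "are supported", call. = FALSE)
  }
  rec(expr)
}

# ---- classification --------------------------------------------------------

# Classify a derivative rational r = num/den with respect to variable j:
#   ZERO if identically zero; DBL if the reduced denominator depends on x_j;
#   ONE if constant in every state variable; BAR otherwise.
.classify_rational <- function(r, j, nv, salt) {
  num <- .p_norm(r$num)
  den <- .p_norm(r$den)
  if (.p_is_zero(num)) return(SYM_ZERO)
  rng <- .rng_new(salt * 1000003 + j)
  degs_j <- .r_reduced_degrees(num, den, j, nv, rng)
  if (degs_j[["num"]] == 0L && degs_j[["den"]] == 0L) {
    # constant in x_j; still need the other variables for ONE vs BAR
    other_const <- TRUE
    for (k in setdiff(seq_len(nv), j)) {
      dk <- .r_reduced_degrees(num, den, k, nv, rng)
      if (dk[["num"]] > 0L || dk[["den"]] > 0L) {
        other_const <- FALSE
        break
      }
    }
    return(if (other_const) SYM_ONE else SYM_BAR)
  }
  if (degs_j[["den"]] > 0L) return(SYM_DBL)
  SYM_BAR
}
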