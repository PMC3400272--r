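# Sparse multivariate polynomials and rational functions with exact
# (integer-valued double) coefficients.
#
# This small symbolic layer backs the exact parts of the reduction calculus:
# solving quasi-steady-state / quasi-equilibrium conditions in closed form,
# proving symbolic equality of reduced rates, and carrying effective
# parameters as monomials of the original rate constants. Polynomials are
# term lists; a term is list(c = coefficient, p = named integer exponent
# vector over symbol names). Rational functions are num/den pairs; equality
# is decided by cross-multiplication, so no GCD simplification is needed.

.term_key <- function(p) {
  if (length(p) == 0) return("t:1")
  o <- order(names(p))
  paste0("t:", paste(names(p)[o], p[o], sep = "^", collapse = "*"))
}

.clean_pow <- function(p) {
  p <- p[p != 0]
  if (length(p) == 0) return(stats::setNames(numeric(0), character(0)))
  p[order(names(p))]
}

#' Construct a sparse polynomial from a list of terms
#' @param terms list of list(c=coefficient, p=named exponent vector)
#' @return an object of class \code{spoly}
#' @export
sp_poly <- function(terms) {
  tab <- new.env(parent = emptyenv())
  for (t in terms) {
    if (t$c == 0) next
    p <- .clean_pow(t$p)
    k <- .term_key(p)
    cur <- tab[[k]]
    if (is.null(cur)) tab[[k]] <- list(c = t$c, p = p)
    else tab[[k]]$c <- cur$c + t$c
  }
  out <- list()
  for (k in ls(tab)) {
    t <- tab[[k]]
    if (abs(t$c) > 0) out[[length(out) + 1L]] <- t
  }
  # canonical order: by key
  if (length(out) > 1) {
    keys <- vapply(out, function(t) .term_key(t$p), "")
    out <- out[order(keys)]
  }
  structure(out, class = "spoly")
}

#' @export
sp_const <- function(x) sp_poly(list(list(c = x, p = numeric(0))))

#' @export
sp_var <- function(name, pow = 1) sp_poly(list(list(c = 1, p = stats::setNames(pow, name))))

#' Polynomial from a single monomial
#' @export
sp_mono <- function(coef, powers) sp_poly(list(list(c = coef, p = powers)))

#' @export
sp_is_zero <- function(p) length(p) == 0

#' @export
sp_add <- function(a, b) sp_poly(c(unclass(a), unclass(b)))

#' @export
sp_neg <- function(a) {
  structure(lapply(unclass(a), function(t) { t$c <- -t$c; t }), class = "spoly")
}

#' @export
sp_sub <- function(a, b) sp_add(a, sp_neg(b))

#' @export
sp_mul <- function(a, b) {
  terms <- list()
  for (ta in unclass(a)) for (tb in unclass(b)) {
    p <- ta$p
    for (nm in names(tb$p)) p[nm] <- (if (nm %in% names(p)) p[nm] else 0) + tb$p[nm]
    terms[[length(terms) + 1L]] <- list(c = ta$c * tb$c, p = p)
  }
  sp_poly(terms)
}

#' @export
sp_scale <- function(a, x) {
  if (x == 0) return(sp_poly(list()))
  structure(lapply(unclass(a), function(t) { t$c <- t$c * x; t }), class = "spoly")
}

#' @export
sp_pow <- function(a, n) {
  stopifnot(n >= 0, n == round(n))
  out <- sp_const(1)
  for (i in seq_len(n)) out <- sp_mul(out, a)
  out
}

#' Evaluate a polynomial at named numeric values
#' @export
sp_eval <- function(p, vals) {
  s <- 0
  for (t in unclass(p)) {
    v <- t$c
    for (nm in names(t$p)) {
      if (!nm %in% names(vals)) stop("no value for symbol ", nm)
      v <- v * vals[[nm]]^t$p[[nm]]
    }
    s <- s + v
  }
  s
}

#' Symbols occurring in a polynomial
#' @export
sp_vars <- function(p) {
  unique(unlist(lapply(unclass(p), function(t) names(t$p)), use.names = FALSE))
}

#' Degree of a polynomial in one symbol
#' @export
sp_degree <- function(p, var) {
  if (sp_is_zero(p)) return(-Inf)
  max(vapply(unclass(p), function(t) if (var %in% names(t$p)) t$p[[var]] else 0, 0))
}

#' Coefficient polynomials with respect to one symbol
#'
#' Returns list of spoly, element d+1 = coefficient of var^d.
#' @export
sp_coeffs_in <- function(p, var) {
  d <- max(0, sp_degree(p, var))
  out <- replicate(d + 1, list(), simplify = FALSE)
  for (t in unclass(p)) {
    e <- if (var %in% names(t$p)) t$p[[var]] else 0
    q <- t$p[setdiff(names(t$p), var)]
    out[[e + 1]] <- c(out[[e + 1]], list(list(c = t$c, p = q)))
  }
  lapply(out, sp_poly)
}

#' Substitute a polynomial for a symbol
#' @export
sp_subst <- function(p, var, q) {
  cf <- sp_coeffs_in(p, var)
  out <- sp_poly(list())
  qe <- sp_const(1)
  for (d in seq_along(cf)) {
    out <- sp_add(out, sp_mul(cf[[d]], qe))
    qe <- sp_mul(qe, q)
  }
  out
}

#' Polynomial equality (coefficient-wise, relative tolerance for round-off)
#' @export
sp_equal <- function(a, b, tol = 1e-9) {
  d <- sp_sub(a, b)
  if (sp_is_zero(d)) return(TRUE)
  scale <- max(c(vapply(unclass(a), function(t) abs(t$c), 0),
                 vapply(unclass(b), function(t) abs(t$c), 0), 1))
  all(vapply(unclass(d), function(t) abs(t$c), 0) <= tol * scale)
}

#' @export
format.spoly <- function(x, ...) {
  if (sp_is_zero(x)) return("0")
  s <- vapply(unclass(x), function(t) {
    mono <- if (length(t$p) == 0) "" else
      paste(vapply(seq_along(t$p), function(i) {
        if (t$p[i] == 1) names(t$p)[i] else paste0(names(t$p)[i], "^", t$p[i])
      }, ""), collapse = "*")
    co <- t$c
    if (mono == "") return(as.character(co))
    if (co == 1) mono else if (co == -1) paste0("-", mono) else paste0(co, "*", mono)
  }, "")
  out <- s[1]
  for (i in seq_along(s)[-1]) {
    out <- if (startsWith(s[i], "-")) paste0(out, " - ", substring(s[i], 2))
           else paste0(out, " + ", s[i])
  }
  out
}

#' @export
print.spoly <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

## ---- rational functions -------------------------------------------------

#' Construct a rational function num/den from two polynomials
#' @export
srat <- function(num, den = sp_const(1)) {
  if (sp_is_zero(den)) stop("zero denominator")
  structure(list(num = num, den = den), class = "srat")
}

#' @export
as_srat <- function(x) {
  if (inherits(x, "srat")) return(x)
  if (inherits(x, "spoly")) return(srat(x))
  if (is.numeric(x) && length(x) == 1) return(srat(sp_const(x)))
  stop("cannot coerce to srat")
}

#' @export
r_add <- function(a, b) {
  a <- as_srat(a); b <- as_srat(b)
  srat(sp_add(sp_mul(a$num, b$den), sp_mul(b$num, a$den)), sp_mul(a$den, b$den))
}

#' @export
r_neg <- function(a) { a <- as_srat(a); srat(sp_neg(a$num), a$den) }

#' @export
r_sub <- function(a, b) r_add(a, r_neg(b))

#' @export
r_mul <- function(a, b) {
  a <- as_srat(a); b <- as_srat(b)
  srat(sp_mul(a$num, b$num), sp_mul(a$den, b$den))
}

#' @export
r_div <- function(a, b) {
  a <- as_srat(a); b <- as_srat(b)
  if (sp_is_zero(b$num)) stop("division by zero rational")
  srat(sp_mul(a$num, b$den), sp_mul(a$den, b$num))
}

#' @export
r_is_zero <- function(a) sp_is_zero(as_srat(a)$num)

#' Rational-function equality via cross-multiplication
#' @export
r_equal <- function(a, b, tol = 1e-9) {
  a <- as_srat(a); b <- as_srat(b)
  sp_equal(sp_mul(a$num, b$den), sp_mul(b$num, a$den), tol = tol)
}

#' @export
r_eval <- function(a, vals) {
  a <- as_srat(a)
  sp_eval(a$num, vals) / sp_eval(a$den, vals)
}

#' Substitute a rational function for a symbol in a polynomial
#'
#' Returns the srat p(var -> r). Clears denominators: if p has degree d in
#' var, result = sum_e coef_e * num^e * den^(d-e) / den^d.
#' @export
sp_subst_rat <- function(p, var, r) {
  r <- as_srat(r)
  cf <- sp_coeffs_in(p, var)
  d <- length(cf) - 1
  num <- sp_poly(list())
  for (e in 0:d) {
    num <- sp_add(num, sp_mul(cf[[e + 1]], sp_mul(sp_pow(r$num, e), sp_pow(r$den, d - e))))
  }
  srat(num, sp_pow(r$den, d))
}

#' @export
r_subst <- function(a, var, r) {
  a <- as_srat(a)
  n <- sp_subst_rat(a$num, var, r)
  d <- sp_subst_rat(a$den, var, r)
  r_div(n, d)
}

#' @export
format.srat <- function(x, ...) {
  if (length(x$den) == 1 && length(x$den[[1]]$p) == 0 && x$den[[1]]$c == 1)
    return(format(x$num))
  paste0("(", format(x$num), ") / (", format(x$den), ")")
}

#' @export
print.srat <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
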