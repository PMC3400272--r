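# Exact linear algebra over the rationals for small integer matrices.
#
# Stoichiometric kernels (conservation laws, species pools, reaction routes)
# must be exact: a floating-point nullspace cannot certify b %*% S == 0.
# Entries are stored in doubles but every intermediate value is an integer or
# a reduced fraction, so arithmetic is exact well below 2^53.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

.gcd_vec <- function(v) {
  v <- abs(v[v != 0])
  if (length(v) == 0) return(1)
  Reduce(.gcd2, v)
}

.lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  abs(a / .gcd2(a, b) * b)
}

# Reduced row echelon form of an integer matrix over Q.
# Returns list(num, den, pivots) with num/den the RREF entries as reduced
# fractions (den > 0).
.rref_rat <- function(M) {
  stopifnot(is.matrix(M))
  if (any(M != round(M))) stop("matrix must have integer entries")
  n <- nrow(M); m <- ncol(M)
  N <- matrix(as.numeric(M), n, m)
  D <- matrix(1, n, m)
  reduce_entry <- function(i, j) {
    if (N[i, j] == 0) { D[i, j] <<- 1; return(invisible()) }
    g <- .gcd2(N[i, j], D[i, j])
    N[i, j] <<- N[i, j] / g; D[i, j] <<- D[i, j] / g
    if (D[i, j] < 0) { N[i, j] <<- -N[i, j]; D[i, j] <<- -D[i, j] }
    invisible()
  }
  pivots <- integer(0)
  row <- 1
  for (col in seq_len(m)) {
    if (row > n) break
    pr <- which(N[row:n, col] != 0)
    if (length(pr) == 0) next
    pr <- pr[1] + row - 1
    if (pr != row) { N[c(pr, row), ] <- N[c(row, pr), ]; D[c(pr, row), ] <- D[c(row, pr), ] }
    # normalize pivot row to leading 1
    pn <- N[row, col]; pd <- D[row, col]
    for (j in seq_len(m)) {
      if (N[row, j] != 0) {
        N[row, j] <- N[row, j] * pd
        D[row, j] <- D[row, j] * pn
        reduce_entry(row, j)
      }
    }
    # eliminate column in all other rows
    for (i in seq_len(n)) {
      if (i == row || N[i, col] == 0) next
      fn <- N[i, col]; fd <- D[i, col]
      for (j in seq_len(m)) {
        if (N[row, j] == 0) next
        # entry_ij <- entry_ij - f * pivotrow_j
        an <- N[i, j]; ad <- D[i, j]
        bn <- fn * N[row, j]; bd <- fd * D[row, j]
        N[i, j] <- an * bd - bn * ad
        D[i, j] <- ad * bd
        reduce_entry(i, j)
      }
    }
    pivots <- c(pivots, col)
    row <- row + 1
  }
  list(num = N, den = D, pivots = pivots)
}

#' Rank of an integer matrix (exact)
#'
#' @param M integer matrix.
#' @return integer rank computed by exact rational elimination.
#' @keywords internal
int_rank <- function(M) {
  if (length(M) == 0 || nrow(M) == 0 || ncol(M) == 0) return(0L)
  length(.rref_rat(M)$pivots)
}

#' Integer basis of the (right) nullspace of an integer matrix
#'
#' Computes an exact basis of \{x : M x = 0\} by rational Gaussian
#' elimination, with denominators cleared so that each basis vector is a
#' primitive integer vector (entries coprime). Signs are normalized so the
#' majority of nonzero entries is positive (falling back to a positive first
#' entry).
#'
#' @param M integer matrix (may have 0 rows or columns).
#' @return integer matrix whose columns span the nullspace (0 columns if trivial).
#' @export
nullspace_int <- function(M) {
  if (is.null(M) || length(M) == 0 || ncol(M) == 0)
    return(matrix(0, max(0L, if (is.matrix(M)) ncol(M) else 0L), 0))
  m <- ncol(M)
  if (nrow(M) == 0) return(diag(1, m))
  rr <- .rref_rat(M)
  piv <- rr$pivots
  free <- setdiff(seq_len(m), piv)
  if (length(free) == 0) return(matrix(0, m, 0))
  B <- matrix(0, m, length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    x_num <- numeric(m); x_den <- rep(1, m)
    x_num[f] <- 1
    for (i in seq_along(piv)) {
      # pivot row i: x_piv[i] = - entry(i, f) * x_f
      x_num[piv[i]] <- -rr$num[i, f]
      x_den[piv[i]] <- rr$den[i, f]
    }
    l <- Reduce(.lcm2, x_den[x_num != 0], accumulate = FALSE)
    if (is.null(l) || l == 0) l <- 1
    v <- x_num * (l / x_den)
    v <- v / .gcd_vec(v)
    B[, k] <- v
  }
  B <- apply(B, 2, .normalize_sign)
  if (!is.matrix(B)) B <- matrix(B, m, length(free))
  B
}

.normalize_sign <- function(v) {
  nz <- v[v != 0]
  if (length(nz) == 0) return(v)
  if (sum(nz < 0) > sum(nz > 0)) v <- -v
  else if (sum(nz < 0) == sum(nz > 0) && nz[1] < 0) v <- -v
  v
}

#' Integer basis of the left nullspace \{b : b M = 0\}
#'
#' @param M integer matrix.
#' @return integer matrix whose columns are the basis vectors b.
#' @export
left_nullspace_int <- function(M) {
  nullspace_int(t(M))
}

# Try to make kernel vectors non-negative by adding small integer multiples of
# other basis vectors; used for conservation laws where non-negative
# combinations are the chemically meaningful form.
.prefer_nonneg <- function(B) {
  if (ncol(B) <= 1) return(B)
  for (i in seq_len(ncol(B))) {
    v <- B[, i]
    if (all(v >= 0)) next
    for (j in seq_len(ncol(B))) {
      if (j == i) next
      for (k in c(1, 2, 3, -1, -2, -3)) {
        w <- v + k * B[, j]
        if (all(w <= 0)) w <- -w
        if (all(w >= 0) && any(w != 0)) {
          w <- w / .gcd_vec(w)
          B[, i] <- w
          break
        }
      }
      if (all(B[, i] >= 0)) break
    }
  }
  B
}
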