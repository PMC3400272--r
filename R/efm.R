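# Elementary flux modes of a (fast) stoichiometric matrix.
#
# A mode is a support-minimal integer vector gamma with S gamma = 0 and
# gamma_j >= 0 for irreversible reactions j. Two algorithms are provided:
# an exhaustive support enumeration (exact, used up to 12 reactions and as
# the cross-check oracle) and the classical tableau / double-description
# iteration on the flux cone for larger systems. All kernel computations are
# exact integer arithmetic.

#' Elementary flux modes of an integer stoichiometric matrix
#'
#' @param S integer matrix (species x reactions).
#' @param reversible logical vector per reaction (FALSE = irreversible, the
#'   mode coefficient must be non-negative).
#' @param method \code{"auto"} (exhaustive up to 12 reactions, tableau
#'   above), \code{"exhaustive"} or \code{"tableau"}.
#' @return integer matrix whose columns are the modes, each primitive
#'   (coprime entries); modes supported only on reversible reactions are
#'   returned in one orientation (first nonzero entry positive).
#' @export
elementary_flux_modes <- function(S, reversible = rep(FALSE, ncol(S)),
                                  method = c("auto", "exhaustive", "tableau")) {
  method <- match.arg(method)
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  r <- ncol(S)
  stopifnot(length(reversible) == r)
  if (r == 0) return(matrix(0L, 0, 0))
  if (method == "auto") method <- if (r <= 12) "exhaustive" else "tableau"
  modes <- switch(method,
                  exhaustive = .efm_exhaustive(S, reversible),
                  tableau = .efm_tableau(S, reversible))
  if (length(modes) == 0) return(matrix(0L, r, 0))
  modes <- unique(t(modes))
  t(modes)
}

.sign_fix <- function(v, reversible) {
  nz <- which(v != 0)
  if (length(nz) == 0) return(NULL)
  irr <- nz[!reversible[nz]]
  if (length(irr)) {
    s <- sign(v[irr])
    if (all(s < 0)) v <- -v
    else if (any(s < 0)) return(NULL)  # infeasible signs
  } else if (v[nz[1]] < 0) v <- -v
  v
}

.efm_exhaustive <- function(S, reversible) {
  r <- ncol(S)
  found <- list()
  found_supports <- list()
  is_minimal <- function(sup) {
    for (fs in found_supports) if (all(fs %in% sup)) return(FALSE)
    TRUE
  }
  for (size in 1:r) {
    combs <- utils::combn(r, size, simplify = FALSE)
    for (J in combs) {
      if (!is_minimal(J)) next
      sub <- S[, J, drop = FALSE]
      ker <- nullspace_int(sub)
      if (ncol(ker) != 1) next
      v <- ker[, 1]
      if (any(v == 0)) next  # kernel vector must have full support on J
      g <- integer(r); g[J] <- v
      g <- .sign_fix(g, reversible)
      if (is.null(g)) next
      found[[length(found) + 1L]] <- g
      found_supports[[length(found_supports) + 1L]] <- J
    }
  }
  if (length(found) == 0) return(matrix(0L, r, 0))
  do.call(cbind, found)
}

# tableau / double description on the cone {gamma : S gamma = 0, gamma_I >= 0};
# reversible reactions are split into forward and backward parts, the
# resulting extreme rays mapped back and futile two-cycles discarded
.efm_tableau <- function(S, reversible) {
  r <- ncol(S)
  rev_idx <- which(reversible)
  Ssplit <- cbind(S, -S[, rev_idx, drop = FALSE])
  nsplit <- ncol(Ssplit)
  rays <- diag(1, nsplit)
  for (row in seq_len(nrow(Ssplit))) {
    a <- as.numeric(Ssplit[row, ] %*% rays)
    zero <- which(abs(a) == 0)
    pos <- which(a > 0); neg <- which(a < 0)
    newr <- rays[, zero, drop = FALSE]
    if (length(pos) && length(neg)) {
      combos <- list()
      for (p in pos) for (q in neg) {
        v <- a[p] * rays[, q] - a[q] * rays[, p]
        v <- v / .gcd_vec(v)
        combos[[length(combos) + 1L]] <- v
      }
      cm <- do.call(cbind, combos)
      keep <- rep(TRUE, ncol(cm))
      sup <- lapply(seq_len(ncol(cm)), function(j) which(cm[, j] != 0))
      all_sup <- c(lapply(seq_len(ncol(newr)), function(j) which(newr[, j] != 0)), sup)
      off <- ncol(newr)
      for (j in seq_len(ncol(cm))) {
        for (k in seq_along(all_sup)) {
          if (k == off + j) next
          if (!keep[max(0, k - off)] && k > off) next
          if (all(all_sup[[k]] %in% sup[[j]]) && length(all_sup[[k]]) < length(sup[[j]])) {
            keep[j] <- FALSE; break
          }
        }
      }
      newr <- cbind(newr, cm[, keep, drop = FALSE])
    }
    rays <- newr
    if (ncol(rays) == 0) break
  }
  if (ncol(rays) == 0) return(matrix(0L, r, 0))
  out <- list()
  seen <- character(0)
  for (j in seq_len(ncol(rays))) {
    v <- rays[, j]
    g <- v[seq_len(r)]
    if (length(rev_idx)) g[rev_idx] <- g[rev_idx] - v[(r + 1):nsplit]
    if (all(g == 0)) next  # futile split cycle
    g <- g / .gcd_vec(g)
    g <- .sign_fix(g, reversible)
    if (is.null(g)) next
    key <- paste(g, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- g
  }
  if (length(out) == 0) return(matrix(0L, r, 0))
  m <- do.call(cbind, out)
  # final support-minimality filter (splitting can produce non-minimal rays)
  sup <- lapply(seq_len(ncol(m)), function(j) which(m[, j] != 0))
  keep <- rep(TRUE, ncol(m))
  for (j in seq_along(sup)) for (k in seq_along(sup)) {
    if (j == k || !keep[j]) next
    if (all(sup[[k]] %in% sup[[j]]) && length(sup[[k]]) < length(sup[[j]]))
      keep[j] <- FALSE
  }
  m[, keep, drop = FALSE]
}
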