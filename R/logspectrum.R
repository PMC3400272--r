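# Overflow-safe spectral and trajectory computations for strongly multiscale
# monomolecular networks.
#
# With constants spanning many tens of decades, dense eigensolvers lose every
# eigenvalue below ~1e-16 * ||K||. Two tools avoid this:
#  * the characteristic polynomial of the kinetic matrix computed exactly-in-
#    structure by enumerating directed out-forests (all coefficients are sums
#    of positive edge-weight products, so there is no cancellation), held as
#    log-coefficients, with roots located by the Newton polygon and polished
#    by Newton iteration carried out entirely in log space;
#  * a stiff integration of dc/dt = K c in logarithmic time, which resolves
#    relaxation cascades spread over arbitrarily many decades.

.logsumexp_signed <- function(logs, signs) {
  keep <- is.finite(logs)
  logs <- logs[keep]; signs <- signs[keep]
  if (length(logs) == 0) return(list(log = -Inf, sign = 1))
  m <- max(logs)
  s <- sum(signs * exp(logs - m))
  if (s == 0) return(list(log = -Inf, sign = 1))
  list(log = m + log(abs(s)), sign = sign(s))
}

# log-coefficients of det(lambda I - K) for the kinetic matrix of a
# monomolecular digraph, via the matrix-forest theorem: the coefficient of
# lambda^d is the sum over spanning out-forests with n-d edges of the product
# of their constants (weights of -K's Laplacian).
.charpoly_log <- function(nodes, edges) {
  n <- length(nodes)
  out_edges <- stats::setNames(replicate(n, list(), simplify = FALSE), nodes)
  for (e in edges) out_edges[[e$from]][[length(out_edges[[e$from]]) + 1L]] <- e
  acc <- rep(-Inf, n + 1)  # acc[d+1] = logsum of forest weights with n-d edges
  nacc <- integer(n + 1)
  bufs <- replicate(n + 1, numeric(0), simplify = FALSE)
  choice <- integer(n)  # 0 = no out-edge
  recurse <- function(i, nxt, logw, nedges) {
    if (i > n) {
      # acyclic check of the chosen functional subgraph
      color <- stats::setNames(integer(n), nodes)
      for (s in nodes) {
        if (color[s] != 0L) next
        path <- character(0); u <- s
        while (!is.na(u) && color[u] == 0L) { color[u] <- 1L; path <- c(path, u); u <- nxt[u] }
        if (!is.na(u) && color[u] == 1L) return(invisible())
        color[path] <- 2L
      }
      d <- n - nedges
      bufs[[d + 1]][length(bufs[[d + 1]]) + 1L] <<- logw
      return(invisible())
    }
    u <- nodes[i]
    nxt[u] <- NA_character_
    recurse(i + 1, nxt, logw, nedges)
    for (e in out_edges[[u]]) {
      nxt[u] <- e$to
      recurse(i + 1, nxt, logw + e$logk, nedges + 1L)
    }
    invisible()
  }
  nxt0 <- stats::setNames(rep(NA_character_, n), nodes)
  recurse(1L, nxt0, 0, 0L)
  vapply(seq_len(n + 1), function(j) .logsumexp_signed(bufs[[j]], rep(1, length(bufs[[j]])))$log, 0)
}

# evaluate p(-x) and its x-derivative in log space at x = exp(lx);
# la[d+1] = log coefficient of lambda^d, sign of lambda^d term at -x is (-1)^d
.poly_eval_neg_log <- function(la, lx) {
  d <- seq_along(la) - 1
  v <- .logsumexp_signed(la + d * lx, (-1)^d)
  dd <- d[-1]
  dv <- .logsumexp_signed(la[-1] + log(dd) + (dd - 1) * lx, (-1)^dd)
  list(v = v, dv = dv)
}

#' Eigenvalues of a multiscale monomolecular network, any magnitude
#'
#' Computes all eigenvalues of the kinetic matrix through the characteristic
#' polynomial (assembled by directed-forest enumeration, cancellation-free)
#' with Newton-polygon root location and log-space Newton polishing. Designed
#' for totally separated constants, where the eigenvalue magnitudes are the
#' slopes of the polygon and each root is simple; it resolves eigenvalues far
#' below the reach of dense floating-point eigensolvers.
#'
#' @param g a \code{labeled_digraph} or \code{reduced_linear}.
#' @return numeric vector of eigenvalues sorted decreasingly (zeros first,
#'   then increasingly negative).
#' @export
eigenvalues_separated <- function(g) {
  la <- .charpoly_log(g$nodes, g$edges)
  n <- length(g$nodes)
  nzero <- 0L
  while (nzero < n && !is.finite(la[nzero + 1])) nzero <- nzero + 1L
  la_red <- la[(nzero + 1):(n + 1)]  # factor out lambda^nzero
  m <- length(la_red) - 1
  if (m == 0) return(rep(0, nzero))
  # Newton polygon: upper concave hull of (d, la_red[d+1])
  pts_d <- which(is.finite(la_red)) - 1
  pts_v <- la_red[pts_d + 1]
  hull <- 1L
  for (i in seq_along(pts_d)[-1]) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      s1 <- (pts_v[b] - pts_v[a]) / (pts_d[b] - pts_d[a])
      s2 <- (pts_v[i] - pts_v[b]) / (pts_d[i] - pts_d[b])
      if (s2 >= s1) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  lroots <- numeric(0)
  for (j in seq_along(hull)[-1]) {
    a <- hull[j - 1]; b <- hull[j]
    slope <- (pts_v[a] - pts_v[b]) / (pts_d[b] - pts_d[a])
    lroots <- c(lroots, rep(slope, pts_d[b] - pts_d[a]))
  }
  roots <- vapply(lroots, function(lx) {
    for (it in 1:60) {
      ev <- .poly_eval_neg_log(la_red, lx)
      if (!is.finite(ev$v$log)) break
      step <- ev$v$sign * ev$dv$sign * exp(ev$v$log - ev$dv$log - lx)
      # p(-x): d/dlx of p = x * dp/dx; newton in lx
      step <- max(min(step, 0.5), -0.5)
      lx <- lx - step
      if (abs(step) < 1e-14) break
    }
    -exp(lx)
  }, 0)
  sort(c(rep(0, nzero), roots), decreasing = TRUE)
}

#' Multiscale-safe solution of linear kinetics at arbitrary horizons
#'
#' Computes c(t) = expm(K t) c0 per time point by scaling and squaring. For a
#' compartmental kinetic matrix, expm(K t/2^s) is entrywise non-negative with
#' unit column sums on closed networks, and repeated squaring multiplies
#' non-negative matrices without cancellation, so the result stays entrywise
#' accurate even when the relaxation cascade spans a hundred decades of time
#' (where dense eigensolvers and stiff steppers both fail).
#'
#' @param g a \code{labeled_digraph} or \code{reduced_linear}.
#' @param c0 initial concentrations (defaults to the network's).
#' @param times non-negative time grid.
#' @return a \code{crn_trajectory}.
#' @export
linear_solution_multiscale <- function(g, c0 = NULL, times) {
  K <- kinetic_matrix(g)
  if (is.null(c0)) c0 <- g$initial[g$nodes]
  if (!is.null(names(c0))) c0 <- c0[g$nodes]
  c0 <- as.numeric(c0)
  conc <- t(vapply(times, function(t) {
    if (t == 0) return(c0)
    as.numeric(.expm_mat(K, t) %*% c0)
  }, numeric(nrow(K))))
  colnames(conc) <- g$nodes
  structure(list(times = times, conc = conc, method = "expm-squaring"),
            class = "crn_trajectory")
}
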