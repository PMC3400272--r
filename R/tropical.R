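# Tropicalization of polynomial vector fields.
#
# The tropicalization replaces every balance polynomial P_i(c) by its
# dominant monomial in absolute value: dc_i/dt = s_i exp(max_a(log|a| +
# <log c, alpha>)). The locus where two or more monomials tie is the tropical
# manifold; crossing it switches the active monomial field, and arcs where
# both one-sided fields point toward the manifold carry Filippov sliding
# modes. Monomials sharing an exponent vector are collapsed (signed
# coefficient sum) before taking the max, so tie equations match the pruned
# binomial conditions of the QSS/QE analysis.

#' Tropical (max-plus) polynomial from a signed monomial list
#'
#' @param monomials list of records with fields \code{sign}, \code{coef},
#'   \code{spe} (named exponent vector); monomials with identical exponents
#'   are collapsed by summing signed coefficients.
#' @param vars variable names (default: union of exponent names).
#' @return object of class \code{trop_poly}: exponent matrix \code{E},
#'   log-coefficients \code{logc}, signs, and provenance labels.
#' @export
trop_poly <- function(monomials, vars = NULL) {
  if (is.null(vars)) {
    vars <- unique(unlist(lapply(monomials, function(m) names(m$spe))))
  }
  key <- vapply(monomials, function(m) {
    e <- m$spe[vars]; e[is.na(e)] <- 0
    paste(e, collapse = ",")
  }, "")
  E <- NULL; logc <- numeric(0); sgn <- numeric(0); labels <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    co <- sum(vapply(monomials[idx], function(m) m$sign * m$coef, 0))
    if (abs(co) < 1e-300) next
    e <- monomials[[idx[1]]]$spe[vars]; e[is.na(e)] <- 0
    names(e) <- vars
    E <- rbind(E, e)
    logc <- c(logc, log(abs(co)))
    sgn <- c(sgn, sign(co))
    labels[[length(labels) + 1L]] <- lapply(monomials[idx], function(m)
      list(reaction = m$reaction, dir = m$dir, par = m$par, sign = m$sign, coef = m$coef))
  }
  if (is.null(E)) E <- matrix(0, 0, length(vars), dimnames = list(NULL, vars))
  rownames(E) <- NULL
  structure(list(E = E, logc = logc, sign = sgn, labels = labels, vars = vars),
            class = "trop_poly")
}

#' @export
print.trop_poly <- function(x, ...) {
  cat("Tropical polynomial with", length(x$logc), "monomials over",
      paste(x$vars, collapse = ", "), "\n")
  for (i in seq_along(x$logc)) {
    e <- x$E[i, ]
    mono <- paste(ifelse(e[e != 0] == 1, names(e)[e != 0],
                         paste0(names(e)[e != 0], "^", e[e != 0])), collapse = "*")
    cat(sprintf("  %s%.4g%s\n", ifelse(x$sign[i] < 0, "-", "+"), exp(x$logc[i]),
                ifelse(mono == "", "", paste0("*", mono))))
  }
  invisible(x)
}

#' Tropicalize a polynomial vector field
#'
#' @param field a \code{crn_rhs}.
#' @return object of class \code{trop_system}: per-species \code{trop_poly}
#'   over the full species list.
#' @export
tropicalize <- function(field) {
  polys <- lapply(field$species, function(i) trop_poly(field$monomials[[i]], vars = field$species))
  names(polys) <- field$species
  structure(list(species = field$species, polys = polys), class = "trop_system")
}

#' @export
print.trop_system <- function(x, ...) {
  cat("Tropicalized system over", length(x$species), "species\n")
  for (i in x$species)
    cat(sprintf("  d%s/dt: max over %d monomials\n", i, length(x$polys[[i]]$logc)))
  invisible(x)
}

#' Dominant monomial of a tropical polynomial at a point
#'
#' @param tp a \code{trop_poly}.
#' @param conc positive named concentration vector.
#' @param tol absolute tolerance on log-values for tie detection.
#' @return list: \code{index} of the argmax monomial, \code{value} (signed
#'   monomial value), \code{log_value}, \code{sign}, \code{ties} (indices
#'   within tol of the max; length > 1 iff the point lies on the manifold).
#' @export
dominant_monomial <- function(tp, conc, tol = 1e-9) {
  if (length(tp$logc) == 0) return(list(index = NA_integer_, value = 0,
                                        log_value = -Inf, sign = 1, ties = integer(0)))
  u <- log(pmax(conc[tp$vars], 1e-300))
  vals <- tp$logc + as.numeric(tp$E %*% u)
  i <- which.max(vals)
  list(index = i, value = tp$sign[i] * exp(vals[i]), log_value = vals[i],
       sign = tp$sign[i], ties = which(vals >= vals[i] - tol))
}

#' Evaluate the tropicalized vector field
#'
#' @param sys a \code{trop_system}.
#' @param conc positive concentration vector.
#' @return named vector dc/dt with each component equal to the signed
#'   dominant monomial of its balance polynomial.
#' @export
eval_tropical <- function(sys, conc) {
  stats::setNames(vapply(sys$species, function(i) {
    dominant_monomial(sys$polys[[i]], conc)$value
  }, 0), sys$species)
}

## ---- 2D tropical manifold ----------------------------------------------

#' Tropical manifold (curve) of a polynomial in two effective variables
#'
#' Computes the vertices, segments and rays where at least two monomials tie
#' for the maximum, in log coordinates. Each edge records the tying monomial
#' pair and its endpoints (infinite for rays).
#'
#' @param tp a \code{trop_poly} whose exponents vary in exactly two variables.
#' @param tol tolerance for feasibility comparisons.
#' @return object of class \code{trop_manifold_2d}: \code{vars} (the two
#'   coordinates), \code{edges} (data.frame: i, j, x1, y1, x2, y2, type),
#'   \code{vertices} (matrix).
#' @export
tropical_manifold_2d <- function(tp, tol = 1e-9) {
  varying <- which(apply(tp$E, 2, function(col) length(unique(col)) > 1))
  if (length(varying) == 0)
    stop("degenerate manifold: all monomials share one exponent vector")
  if (length(varying) > 2)
    stop("polynomial has more than two effective variables: ",
         paste(tp$vars[varying], collapse = ", "))
  v2 <- tp$vars[varying]
  if (length(varying) == 1) v2 <- c(v2, setdiff(tp$vars, v2)[1])
  E <- tp$E[, v2, drop = FALSE]
  m <- length(tp$logc)
  edges <- NULL
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j <= i) next
    d <- E[i, ] - E[j, ]
    if (all(d == 0)) next
    h <- tp$logc[j] - tp$logc[i]
    u0 <- h * d / sum(d^2)
    w <- c(-d[2], d[1]) / sqrt(sum(d^2))
    lo <- -Inf; hi <- Inf; feasible <- TRUE
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      dk <- E[i, ] - E[k, ]
      gk <- tp$logc[k] - tp$logc[i]
      a <- sum(dk * u0); b <- sum(dk * w)
      # need a + t b >= gk
      if (abs(b) < 1e-12) {
        if (a < gk - tol) { feasible <- FALSE; break }
      } else if (b > 0) lo <- max(lo, (gk - a) / b)
      else hi <- min(hi, (gk - a) / b)
    }
    if (!feasible || lo > hi + tol) next
    p1 <- u0 + (if (is.finite(lo)) lo else -1) * w
    p2 <- u0 + (if (is.finite(hi)) hi else 1) * w
    type <- if (is.finite(lo) && is.finite(hi)) "segment"
            else if (!is.finite(lo) && !is.finite(hi)) "line" else "ray"
    edges <- rbind(edges, data.frame(i = i, j = j,
      x1 = if (is.finite(lo)) p1[1] else -Inf, y1 = if (is.finite(lo)) p1[2] else -Inf,
      x2 = if (is.finite(hi)) p2[1] else Inf, y2 = if (is.finite(hi)) p2[2] else Inf,
      ux = u0[1], uy = u0[2], wx = w[1], wy = w[2],
      lo = lo, hi = hi, type = type, stringsAsFactors = FALSE))
  }
  verts <- NULL
  if (!is.null(edges)) {
    pts <- rbind(
      as.matrix(edges[is.finite(edges$lo), c("x1", "y1"), drop = FALSE]),
      stats::setNames(as.matrix(edges[is.finite(edges$hi), c("x2", "y2"), drop = FALSE]),
                      NULL))
    if (!is.null(pts) && nrow(pts) > 0) {
      key <- paste(round(pts[, 1], 6), round(pts[, 2], 6))
      verts <- pts[!duplicated(key), , drop = FALSE]
      colnames(verts) <- v2
    }
  }
  structure(list(vars = v2, edges = edges, vertices = verts, poly = tp),
            class = "trop_manifold_2d")
}

#' @export
print.trop_manifold_2d <- function(x, ...) {
  ne <- if (is.null(x$edges)) 0 else nrow(x$edges)
  nv <- if (is.null(x$vertices)) 0 else nrow(x$vertices)
  cat("Tropical curve in (", paste0("log ", x$vars, collapse = ", "), "): ",
      ne, " edges (", sum(x$edges$type == "ray"), " rays), ", nv,
      " vertices\n", sep = "")
  invisible(x)
}

#' Count dominance cells of 2D tropical polynomials on a grid
#'
#' Colors a log-coordinate grid by the argmax monomial of each polynomial and
#' counts the distinct joint dominance patterns; a brute-force check of the
#' planar subdivision induced by the tropical curves.
#'
#' @param tps list of \code{trop_poly} over the same two variables.
#' @param box list(lower, upper) in log coordinates (length-2 each).
#' @param n grid resolution per axis.
#' @return list: \code{n_cells}, \code{patterns} (table of pattern counts).
#' @export
trop_cells_grid <- function(tps, box, n = 201) {
  vr <- tps[[1]]$vars
  g1 <- seq(box$lower[1], box$upper[1], length.out = n)
  g2 <- seq(box$lower[2], box$upper[2], length.out = n)
  pat <- character(n * n)
  idx <- 1
  for (u in g1) for (v in g2) {
    conc <- stats::setNames(exp(c(u, v)), vr[1:2])
    if (length(tps[[1]]$vars) > 2)
      conc <- c(conc, stats::setNames(rep(1, length(tps[[1]]$vars) - 2),
                                      setdiff(tps[[1]]$vars, vr[1:2])))
    pat[idx] <- paste(vapply(tps, function(tp) dominant_monomial(tp, conc)$index, 0L),
                      collapse = "/")
    idx <- idx + 1
  }
  tab <- table(pat)
  list(n_cells = length(tab), patterns = tab)
}

## ---- sliding modes ------------------------------------------------------

#' Sliding surface between two monomials of one species' polynomial
#'
#' The tie hyperplane \{u : <u, a_i - a_j> = log|c_j| - log|c_i|\} in log
#' coordinates, oriented so that monomial i dominates on the positive side.
#'
#' @param sys a \code{trop_system}.
#' @param species species id whose polynomial supplies the pair.
#' @param pair integer vector of two monomial indices.
#' @return object of class \code{sliding_surface}.
#' @export
sliding_surface <- function(sys, species, pair) {
  tp <- sys$polys[[species]]
  n <- tp$E[pair[1], ] - tp$E[pair[2], ]
  offset <- tp$logc[pair[2]] - tp$logc[pair[1]]
  if (all(n == 0)) stop("the two monomials share an exponent vector; no surface")
  structure(list(species = species, pair = pair, normal = n, offset = offset,
                 sys = sys), class = "sliding_surface")
}

# signed tie function g(u); zero on the surface, positive where pair[1] dominates
.surface_g <- function(s, u) sum(s$normal * u) - s$offset

# tropicalized field in log coordinates du/dt = P_trop(exp u) / exp(u_i),
# optionally forcing the dominant monomial of one species
.trop_field_log <- function(sys, u, force_species = NULL, force_index = NULL,
                            floor_log = log(1e-30)) {
  conc <- exp(pmax(u, floor_log))
  f <- numeric(length(sys$species))
  names(f) <- sys$species
  for (si in seq_along(sys$species)) {
    sp <- sys$species[si]
    tp <- sys$polys[[sp]]
    if (length(tp$logc) == 0) { f[si] <- 0; next }
    if (!is.null(force_species) && sp %in% force_species) {
      k <- force_index[[match(sp, force_species)]]
      lv <- tp$logc[k] + sum(tp$E[k, ] * log(conc))
      f[si] <- tp$sign[k] * exp(lv - u[si])
    } else {
      dm <- dominant_monomial(tp, conc)
      f[si] <- dm$sign * exp(dm$log_value - u[si])
    }
  }
  f
}

#' Test the Filippov sliding condition on a surface point
#'
#' True when both one-sided tropicalized fields point toward the surface:
#' <n+, f+> < 0 and <n-, f-> < 0 with n+ = -n- the interior normals. The
#' one-sided fields are evaluated geometrically, at points displaced off the
#' surface along its normal, so species whose polynomials share the same tie
#' hyperplane switch consistently.
#'
#' @param s a \code{sliding_surface}.
#' @param x positive concentration vector on the surface (within tolerance).
#' @param tol log-offset used to evaluate the one-sided fields.
#' @return logical.
#' @export
sliding_test <- function(s, x, tol = 1e-6) {
  u <- log(x[s$sys$species])
  if (abs(.surface_g(s, u)) > max(10 * tol, 1e-6))
    warning("point is not on the sliding surface (|g| = ",
            format(abs(.surface_g(s, u))), ")")
  u <- u - .surface_g(s, u) * s$normal / sum(s$normal^2)
  nhat <- s$normal / sqrt(sum(s$normal^2))
  fp <- .trop_field_log(s$sys, u + tol * nhat)
  fm <- .trop_field_log(s$sys, u - tol * nhat)
  gp <- sum(s$normal * fp)   # growth of g on the + side
  gm <- sum(s$normal * fm)
  (gp < 0) && (gm > 0)
}

#' Detect candidate fast constraints from sliding modes
#'
#' Enumerates every 2-monomial tie hyperplane of every species' polynomial,
#' samples it inside a log-coordinate region, and keeps the surfaces where
#' the Filippov sliding condition holds; these are the tropical signatures of
#' QSS species / QE reactions.
#'
#' @param sys a \code{trop_system}.
#' @param region list(lower, upper): named log-coordinate bounds per species.
#' @param nsample points sampled per surface.
#' @param frac fraction of sampled points that must slide (default 0.5).
#' @param seed seed for the sampling.
#' @return data.frame: species, i, j, equation, n_sampled, n_sliding, sliding.
#' @export
detect_fast_constraints <- function(sys, region, nsample = 10, frac = 0.5, seed = 1) {
  out <- NULL
  sps <- sys$species
  lower <- region$lower[sps]; upper <- region$upper[sps]
  rng <- .with_seed(seed, matrix(stats::runif(nsample * 50 * length(sps)),
                                 ncol = length(sps)))
  for (sp in sps) {
    tp <- sys$polys[[sp]]
    m <- length(tp$logc)
    if (m < 2) next
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (all(tp$E[i, ] == tp$E[j, ])) next
      s <- sliding_surface(sys, sp, c(i, j))
      # sample: draw points in the box, project the coordinate with the
      # largest normal component onto the surface, keep points in the box
      kvar <- which.max(abs(s$normal))
      pts <- 0L; slid <- 0L
      on_arm <- 0L
      for (row in seq_len(nrow(rng))) {
        if (on_arm >= nsample) break
        u <- lower + rng[row, ] * (upper - lower)
        u[kvar] <- u[kvar] - .surface_g(s, u) / s$normal[kvar]
        if (u[kvar] < lower[kvar] - 1e-12 || u[kvar] > upper[kvar] + 1e-12) next
        # the hyperplane belongs to the tropical manifold only where the
        # pair is jointly dominant; sample the sliding test on that arm
        ties <- dominant_monomial(tp, stats::setNames(exp(u), sps), tol = 1e-6)$ties
        if (!all(c(i, j) %in% ties)) next
        on_arm <- on_arm + 1L
        if (sliding_test(s, stats::setNames(exp(u), sps))) slid <- slid + 1L
      }
      pts <- on_arm
      if (pts == 0) next
      out <- rbind(out, data.frame(
        species = sp, i = i, j = j, equation = .tie_equation(tp, i, j),
        n_sampled = pts, n_sliding = slid,
        sliding = slid >= frac * pts, stringsAsFactors = FALSE))
    }
  }
  out
}

.tie_equation <- function(tp, i, j) {
  side <- function(k) {
    e <- tp$E[k, ]; e <- e[e != 0]
    mono <- paste(ifelse(e == 1, names(e), paste0(names(e), "^", e)), collapse = "*")
    co <- format(exp(tp$logc[k]), digits = 4)
    if (mono == "") co else paste0(co, "*", mono)
  }
  paste(side(i), "=", side(j))
}
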