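# QSS/QE rewriting of non-linear reaction networks.
#
# The fast part of the network is summarized by a fast stoichiometric matrix
# S^f (rows = QSS species, or columns = QE reactions). Exact integer kernels
# of S^f give the rewriting blocks: species pools (left kernel, QE) and
# reaction routes / elementary modes (right kernel, QSS). The algebraic fast
# conditions are solved symbolically (closed form up to quadratics) and the
# new rates are fixed by matching the net production of every terminal
# species to the unreduced model. Every coefficient of the new rates is
# tracked as a monomial (or a named rational composite) of the original
# parameters.

#' Fast stoichiometric matrix of a QSS or QE subsystem
#'
#' @param net a \code{crn}.
#' @param mode \code{"qss"} (fast species) or \code{"qe"} (fast reactions).
#' @param fast_set character vector of species ids (QSS) or reaction ids (QE).
#' @return object of class \code{fast_subsystem}: matrix \code{Sf} with
#'   dimnames, the mode, the fast set, and the excluded zero rows/columns.
#' @export
fast_stoichiometry <- function(net, mode = c("qss", "qe"), fast_set) {
  mode <- match.arg(mode)
  if (length(fast_set) == 0) stop("empty fast set")
  S <- stoichiometric_matrix(net)
  rxids <- colnames(S)
  if (mode == "qss") {
    bad <- setdiff(fast_set, rownames(S))
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    Sf <- S[fast_set, , drop = FALSE]
    zero_cols <- colnames(Sf)[colSums(Sf != 0) == 0]
    Sf <- Sf[, colSums(Sf != 0) > 0, drop = FALSE]
    excluded <- zero_cols
  } else {
    bad <- setdiff(fast_set, rxids)
    if (length(bad)) stop("unknown reactions: ", paste(bad, collapse = ", "))
    Sf <- S[, fast_set, drop = FALSE]
    zero_rows <- rownames(Sf)[rowSums(Sf != 0) == 0]
    Sf <- Sf[rowSums(Sf != 0) > 0, , drop = FALSE]
    excluded <- zero_rows
  }
  irr <- stats::setNames(!vapply(net$reactions, `[[`, TRUE, "reversible"),
                         vapply(net$reactions, `[[`, "", "id"))
  structure(list(Sf = Sf, mode = mode, fast_set = fast_set,
                 excluded = excluded, irreversible = irr, net = net),
            class = "fast_subsystem")
}

#' @export
print.fast_subsystem <- function(x, ...) {
  cat("Fast subsystem (", toupper(x$mode), "): S^f is ", nrow(x$Sf), " x ",
      ncol(x$Sf), "; excluded ", length(x$excluded), " zero ",
      if (x$mode == "qss") "columns" else "rows", "\n", sep = "")
  print(x$Sf)
  invisible(x)
}

#' Species pools of a QE fast subsystem
#'
#' Integer basis of the left kernel of S^f (conservation laws of the fast
#' subsystem), extended by the species not touched by the fast reactions,
#' with the conservation laws of the full network projected out; the
#' survivors are the slow variables of the QE reduction.
#'
#' @param fs a \code{fast_subsystem} in QE mode.
#' @param full_laws conservation-law basis of the full network, as returned
#'   by [conservation_laws()] (matrix species x laws).
#' @return list: \code{pools} (matrix species x pools over the full species
#'   list), \code{labels}, \code{all_candidates}.
#' @export
species_pools <- function(fs, full_laws = NULL) {
  stopifnot(fs$mode == "qe")
  if (is.null(full_laws)) full_laws <- conservation_laws(fs$net)
  ids <- fs$net$species$id
  K <- left_nullspace_int(fs$Sf)
  K <- .prefer_nonneg(K)
  cand <- list()
  if (ncol(K)) for (j in seq_len(ncol(K))) {
    v <- stats::setNames(numeric(length(ids)), ids)
    v[rownames(fs$Sf)] <- K[, j]
    cand[[length(cand) + 1L]] <- v
  }
  # kernel-derived pools first (ordered by support size), then the species
  # untouched by the fast reactions: a genuine fast-conservation pool is
  # preferred as the slow variable over an equivalent untouched species
  cand <- cand[order(vapply(cand, function(v) sum(v != 0), 0))]
  for (sp in fs$excluded) {
    v <- stats::setNames(numeric(length(ids)), ids)
    v[sp] <- 1
    cand[[length(cand) + 1L]] <- v
  }
  span <- if (is.null(full_laws) || ncol(full_laws) == 0)
    matrix(0, length(ids), 0) else full_laws
  kept <- list()
  for (v in cand) {
    aug <- cbind(span, v)
    if (int_rank(aug) > int_rank(span)) {
      kept[[length(kept) + 1L]] <- v
      span <- aug
    }
  }
  pools <- if (length(kept)) do.call(cbind, kept) else matrix(0, length(ids), 0)
  rownames(pools) <- ids
  labels <- vapply(seq_len(ncol(pools)), function(j) {
    nz <- which(pools[, j] != 0)
    paste(ifelse(pools[nz, j] == 1, ids[nz], paste0(pools[nz, j], "*", ids[nz])),
          collapse = "+")
  }, "")
  colnames(pools) <- labels
  all_cand <- if (length(cand)) do.call(cbind, cand) else matrix(0, length(ids), 0)
  rownames(all_cand) <- ids
  list(pools = pools, labels = labels, all_candidates = all_cand)
}

#' Reaction routes (elementary modes) of a QSS fast subsystem
#'
#' Support-minimal integer vectors gamma with S^f gamma = 0, non-negative on
#' irreversible reactions: the pooled reactions of the QSS reduction. Each
#' route reports its net stoichiometry, terminal species (net produced or
#' consumed) and intermediate species (touched but conserved).
#'
#' @param fs a \code{fast_subsystem} in QSS mode.
#' @param method passed to [elementary_flux_modes()].
#' @return list of routes: \code{gamma} (named over the full reaction list),
#'   \code{net_stoich}, \code{terminals}, \code{intermediates}.
#' @export
qss_routes <- function(fs, method = "auto") {
  stopifnot(fs$mode == "qss")
  rx_in <- colnames(fs$Sf)
  modes <- elementary_flux_modes(fs$Sf, reversible = !fs$irreversible[rx_in],
                                 method = method)
  S <- stoichiometric_matrix(fs$net)
  m <- stoich_matrices(fs$net)
  routes <- list()
  if (ncol(modes)) for (j in seq_len(ncol(modes))) {
    gamma <- stats::setNames(numeric(ncol(S)), colnames(S))
    gamma[rx_in] <- modes[, j]
    nu <- as.numeric(S %*% gamma)
    names(nu) <- rownames(S)
    touched <- rownames(S)[rowSums((m$alpha + m$beta)[, gamma != 0, drop = FALSE] != 0) > 0]
    routes[[length(routes) + 1L]] <- list(
      gamma = gamma, net_stoich = nu,
      terminals = names(nu)[nu != 0],
      intermediates = setdiff(touched, names(nu)[nu != 0]))
  }
  routes
}

## ---- symbolic fast conditions ------------------------------------------

#' Quadratic root of a fast condition, kept symbolically
#'
#' Represents the root \code{(b -/+ sqrt(b^2 - 4 a c)) / (2 a)} of
#' \code{a x^2 - b x + c = 0} (note the sign convention: for fast binding
#' equilibria a, b, c are all positive and the "minus" branch is the root
#' continuous in the vanishing-displacement limit, lying between 0 and the
#' smaller conserved total).
#'
#' @param a,b,c \code{spoly}/\code{srat} coefficients.
#' @param var the solved species.
#' @param branch \code{"minus"} (default) or \code{"plus"}.
#' @return object of class \code{quad_root}.
#' @export
quad_root <- function(a, b, c, var, branch = "minus") {
  structure(list(a = as_srat(a), b = as_srat(b), c = as_srat(c),
                 var = var, branch = branch), class = "quad_root")
}

#' @export
format.quad_root <- function(x, ...) {
  sprintf("[%s] root of (%s)*%s^2 - (%s)*%s + (%s) = 0",
          x$branch, format(x$a), x$var, format(x$b), x$var, format(x$c))
}

#' @export
print.quad_root <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Evaluate a symbolic expression at named parameter/species values
#'
#' @param expr an \code{srat}, \code{spoly}, \code{quad_root} or scaled root.
#' @param vals named numeric values.
#' @return numeric.
#' @export
eval_sym <- function(expr, vals) {
  if (inherits(expr, "spoly")) return(sp_eval(expr, vals))
  if (inherits(expr, "srat")) return(r_eval(expr, vals))
  if (inherits(expr, "quad_root")) {
    a <- r_eval(expr$a, vals); b <- r_eval(expr$b, vals); c <- r_eval(expr$c, vals)
    disc <- sqrt(max(b^2 - 4 * a * c, 0))
    if (expr$branch == "minus") (b - disc) / (2 * a) else (b + disc) / (2 * a)
  } else if (inherits(expr, "scaled_expr")) {
    r_eval(expr$coef, vals) * eval_sym(expr$expr, vals)
  } else stop("cannot evaluate expression of class ", paste(class(expr), collapse = "/"))
}

#' Small-parameter limit of a quadratic fast-condition root
#'
#' For a root of a x^2 - b x + c = 0 whose constant term c vanishes with the
#' parameter (c = O(p)), the "minus" branch has the leading-order limit
#' c / b|_{p=0}; this is the classical low-enzyme limit of binding
#' equilibria.
#'
#' @param root a \code{quad_root}.
#' @param param the vanishing parameter symbol.
#' @return an \code{srat} for the leading-order root.
#' @export
limit_small_parameter <- function(root, param) {
  stopifnot(inherits(root, "quad_root"), root$branch == "minus")
  c0 <- r_subst(root$c, param, sp_const(0))
  if (!sp_is_zero(c0$num) && !sp_equal(c0$num, sp_const(0)))
    stop("constant term does not vanish with ", param, "; no simple limit")
  b0 <- r_subst(root$b, param, sp_const(0))
  if (sp_is_zero(b0$num)) stop("linear term vanishes at ", param, " = 0")
  r_div(root$c, b0)
}

#' Solve QSS or QE fast conditions symbolically
#'
#' QSS: solves P_i = 0 for every fast species i. QE: solves forward rate =
#' backward rate for every fast reaction, for the species in
#' \code{solve_for}. Substitutions (e.g. eliminating species through
#' conservation totals) are applied first. Equations linear in one unknown
#' are eliminated in closed form and substituted into the rest; one final
#' quadratic is solved as a symbolic \code{quad_root} with the branch
#' continuous in the vanishing-displacement limit.
#'
#' @param field a \code{crn_rhs} of the network.
#' @param fs a \code{fast_subsystem}.
#' @param substitutions named list species -> \code{spoly}/\code{srat}
#'   applied before solving (conservation-law eliminations).
#' @param solve_for species to solve for (default: the QSS fast set).
#' @return named list of solutions (\code{srat} or \code{quad_root}).
#' @export
solve_fast_conditions <- function(field, fs, substitutions = list(),
                                  solve_for = NULL) {
  net <- fs$net
  if (is.null(solve_for))
    solve_for <- if (fs$mode == "qss") fs$fast_set
                 else stop("QE mode needs an explicit solve_for")
  eqs <- list()
  if (fs$mode == "qss") {
    for (i in fs$fast_set) eqs[[i]] <- srat(rhs_spoly(field, i))
  } else {
    m <- stoich_matrices(net)
    for (rid in fs$fast_set) {
      rx <- Filter(function(r) r$id == rid, net$reactions)[[1]]
      if (!rx$reversible) stop("QE reaction ", rid, " is irreversible")
      fwd <- sp_const(1); bwd <- sp_const(1)
      kf <- if (!is.null(rx$kf_par)) rx$kf_par else stop("reaction ", rid, " has no symbolic constant")
      kr <- if (!is.null(rx$kr_par)) rx$kr_par else stop("reaction ", rid, " has no symbolic backward constant")
      fwd <- sp_mono(1, c(kf, rx$reactants))
      bwd <- sp_mono(1, c(kr, rx$products))
      eqs[[rid]] <- srat(sp_sub(fwd, bwd))
    }
  }
  for (nm in names(substitutions)) {
    sub <- as_srat(substitutions[[nm]])
    eqs <- lapply(eqs, function(e) r_subst(e, nm, sub))
  }
  unsolved <- solve_for
  sols <- list()
  progress <- TRUE
  while (length(unsolved) && progress) {
    progress <- FALSE
    for (v in unsolved) {
      degs <- vapply(eqs, function(e) sp_degree(e$num, v), 0)
      cand <- which(is.finite(degs) & degs == 1)
      if (length(cand)) {
        e <- eqs[[cand[1]]]
        cf <- sp_coeffs_in(e$num, v)
        sol <- r_div(srat(sp_neg(cf[[1]])), srat(cf[[2]]))
        sols[[v]] <- sol
        eqs <- eqs[-cand[1]]
        eqs <- lapply(eqs, function(q) r_subst(q, v, sol))
        unsolved <- setdiff(unsolved, v)
        progress <- TRUE
        break
      }
      cand2 <- which(is.finite(degs) & degs == 2)
      if (length(cand2) && length(unsolved) == 1) {
        e <- eqs[[cand2[1]]]
        cf <- sp_coeffs_in(e$num, v)
        # orient as a x^2 - b x + c with positive a on the positive orthant
        sols[[v]] <- quad_root(srat(cf[[3]]), srat(sp_neg(cf[[2]])), srat(cf[[1]]),
                               var = v, branch = "minus")
        unsolved <- setdiff(unsolved, v)
        progress <- TRUE
        break
      }
    }
  }
  if (length(unsolved))
    stop("cannot solve fast conditions symbolically for: ",
         paste(unsolved, collapse = ", "),
         " (degree > 2 or coupled quadratics); use the dominance method")
  # back-substitute solved values into each other
  for (pass in seq_along(sols)) {
    for (v in names(sols)) {
      if (!inherits(sols[[v]], "srat")) next
      for (w in names(sols)) {
        if (w == v || !inherits(sols[[w]], "srat")) next
        if (v %in% c(sp_vars(sols[[w]]$num), sp_vars(sols[[w]]$den)))
          sols[[w]] <- r_subst(sols[[w]], v, sols[[v]])
      }
    }
  }
  sols
}

## ---- network rewriting --------------------------------------------------

#' Rewrite a network under QSS assumptions
#'
#' Pools the reactions along the elementary modes of the fast subsystem and
#' computes each route's rate by matching the net production rate of every
#' terminal species to the unreduced model, with the QSS species eliminated
#' through their fast-condition solutions.
#'
#' @param net a \code{crn}.
#' @param fast_species character vector of QSS species.
#' @param substitutions named list species -> expression applied before
#'   solving (e.g. conservation eliminations such as E = Etot - ES).
#' @param method mode-enumeration method for [elementary_flux_modes()].
#' @return object of class \code{reduced_network}.
#' @export
reduce_qss <- function(net, fast_species, substitutions = list(), method = "auto") {
  fs <- fast_stoichiometry(net, "qss", fast_species)
  field <- crn_rhs(net)
  routes <- qss_routes(fs, method = method)
  if (length(routes) == 0) stop("fast subsystem has no elementary mode")
  sols <- solve_fast_conditions(field, fs, substitutions = substitutions)
  if (any(!vapply(sols, inherits, TRUE, "srat")))
    stop("QSS rewriting needs rational fast solutions (no quadratic branches)")
  terminals <- sort(unique(unlist(lapply(routes, `[[`, "terminals"))))
  # required net rates of the terminal species
  rho <- list()
  for (tsp in terminals) {
    e <- srat(rhs_spoly(field, tsp))
    for (nm in names(substitutions)) e <- r_subst(e, nm, as_srat(substitutions[[nm]]))
    for (nm in names(sols)) e <- r_subst(e, nm, sols[[nm]])
    rho[[tsp]] <- e
  }
  N <- do.call(rbind, lapply(terminals, function(tsp)
    vapply(routes, function(r) r$net_stoich[[tsp]], 0)))
  rownames(N) <- terminals
  sol <- .solve_rate_matching(N, rho)
  rates <- sol$rates
  reactions <- lapply(seq_along(routes), function(j) {
    r <- routes[[j]]
    list(id = paste0("route", j), stoich = r$net_stoich[r$terminals],
         gamma = r$gamma, rate = rates[[j]],
         intermediates = r$intermediates)
  })
  slow <- setdiff(net$species$id, c(fast_species, names(substitutions)))
  structure(list(mode = "qss", slow = slow, reactions = reactions,
                 routes = routes, solutions = sols, fs = fs,
                 substitutions = substitutions, net = net,
                 flags = sol$flags), class = "reduced_network")
}

# exact solve of N x = rho with integer N and srat right-hand sides
.solve_rate_matching <- function(N, rho) {
  nr <- nrow(N); nc <- ncol(N)
  rows <- lapply(seq_len(nr), function(i) list(coef = N[i, ], rhs = rho[[i]]))
  rates <- vector("list", nc)
  solved <- rep(FALSE, nc)
  flags <- character(0)
  for (col in seq_len(nc)) {
    piv <- which(vapply(rows, function(r) r$coef[col] != 0, TRUE) &
                 vapply(rows, function(r) all(r$coef[seq_len(col - 1)] == 0), TRUE))
    if (length(piv) == 0) next
    p <- rows[[piv[1]]]
    for (i in seq_along(rows)) {
      if (i == piv[1] || rows[[i]]$coef[col] == 0) next
      f <- rows[[i]]$coef[col] / p$coef[col]
      rows[[i]]$coef <- rows[[i]]$coef - f * p$coef
      rows[[i]]$rhs <- r_sub(rows[[i]]$rhs, r_mul(p$rhs, f))
    }
  }
  # after elimination each row with a single nonzero coef determines a rate
  for (r in rows) {
    nz <- which(r$coef != 0)
    if (length(nz) == 1 && !solved[nz]) {
      rates[[nz]] <- r_mul(r$rhs, 1 / r$coef[nz])
      solved[nz] <- TRUE
    } else if (length(nz) == 0) {
      if (!sp_equal(r$rhs$num, sp_const(0)))
        stop("rate-matching system is inconsistent: residual ", format(r$rhs))
    }
  }
  if (!all(solved)) {
    flags <- c(flags, "underdetermined: unmatched routes set to zero rate")
    for (j in which(!solved)) rates[[j]] <- srat(sp_const(0))
  }
  list(rates = rates, flags = flags)
}

#' Rewrite a network under QE assumptions
#'
#' Pools species over the conservation laws of the fast reversible
#' subsystem, solves the equilibrium conditions for the designated species,
#' and writes the slow dynamics on the surviving pools.
#'
#' @param net a \code{crn}.
#' @param fast_reactions character vector of QE reaction ids.
#' @param solve_for species determined by the equilibrium conditions.
#' @param substitutions named list species -> expression applied before
#'   solving (pool totals and full-network conservation laws).
#' @return object of class \code{reduced_network}; pool rates carry symbolic
#'   \code{quad_root} solutions where the equilibrium is quadratic.
#' @export
reduce_qe <- function(net, fast_reactions, solve_for, substitutions = list()) {
  fs <- fast_stoichiometry(net, "qe", fast_reactions)
  field <- crn_rhs(net)
  pl <- species_pools(fs)
  sols <- solve_fast_conditions(field, fs, substitutions = substitutions,
                                solve_for = solve_for)
  S <- stoichiometric_matrix(net)
  slow_rx <- setdiff(colnames(S), fast_reactions)
  reactions <- list()
  for (rid in slow_rx) {
    rx <- Filter(function(r) r$id == rid, net$reactions)[[1]]
    pool_stoich <- stats::setNames(as.numeric(t(pl$pools) %*% S[, rid]), pl$labels)
    # symbolic mass-action rate of the slow reaction, fast species replaced
    kf <- if (!is.null(rx$kf_par)) rx$kf_par else stats::setNames(numeric(0), character(0))
    rate_f <- sp_mono(if (length(kf)) 1 else rx$kf, c(kf, rx$reactants))
    rate <- srat(rate_f)
    if (rx$reversible) {
      kr <- if (!is.null(rx$kr_par)) rx$kr_par else stats::setNames(numeric(0), character(0))
      rate <- r_sub(rate, srat(sp_mono(if (length(kr)) 1 else rx$kr, c(kr, rx$products))))
    }
    rate_expr <- rate
    for (nm in names(substitutions)) rate_expr <- r_subst(rate_expr, nm, as_srat(substitutions[[nm]]))
    for (nm in names(sols)) {
      if (inherits(sols[[nm]], "srat")) {
        rate_expr <- r_subst(rate_expr, nm, sols[[nm]])
      } else {
        # rate is linear in the quadratic-root species: represent as coef * root
        cf <- sp_coeffs_in(rate_expr$num, nm)
        if (length(cf) == 2 && sp_is_zero(cf[[1]])) {
          rate_expr <- structure(list(coef = r_div(srat(cf[[2]]), srat(rate_expr$den)),
                                      expr = sols[[nm]]), class = "scaled_expr")
        } else if (length(cf) > 1) {
          stop("slow rate is not linear in the quadratic fast species ", nm)
        }
      }
    }
    reactions[[length(reactions) + 1L]] <- list(id = rid, stoich = pool_stoich,
                                                rate = rate_expr)
  }
  structure(list(mode = "qe", slow = pl$labels, pools = pl$pools,
                 reactions = reactions, solutions = sols, fs = fs,
                 substitutions = substitutions, net = net, flags = character(0)),
            class = "reduced_network")
}

#' @export
print.reduced_network <- function(x, ...) {
  cat("Reduced network (", toupper(x$mode), "): ", length(x$reactions),
      " reactions over {", paste(x$slow, collapse = ", "), "}\n", sep = "")
  for (rx in x$reactions) {
    st <- rx$stoich[rx$stoich != 0]
    from <- names(st)[st < 0]; to <- names(st)[st > 0]
    rate_s <- if (inherits(rx$rate, "scaled_expr"))
      paste0("(", format(rx$rate$coef), ") * ", format(rx$rate$expr))
    else format(rx$rate)
    cat(sprintf("  %s: %s --> %s\n      rate = %s\n", rx$id,
                if (length(from)) paste(from, collapse = " + ") else "0",
                if (length(to)) paste(to, collapse = " + ") else "0", rate_s))
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Integrate the slow dynamics of a reduced network
#'
#' Builds the ODE system of the reduced model (QSS: slow species driven by
#' the route rates; QE: pool variables driven by the slow reactions) and
#' integrates it with a stiff solver. Symbolic rates are evaluated at the
#' original parameter values.
#'
#' @param red a \code{reduced_network}.
#' @param c0 named initial values of the slow variables (QE pools use their
#'   pooled initial concentrations by default).
#' @param horizon final time.
#' @param n_points,log_grid,t_min,rtol,atol as in [integrate_full()].
#' @return a \code{crn_trajectory} over the slow variables.
#' @export
integrate_reduced <- function(red, c0 = NULL, horizon, n_points = 300,
                              log_grid = TRUE, t_min = NULL,
                              rtol = 1e-8, atol = 1e-12) {
  pars <- red$net$parameters
  vars <- red$slow
  if (is.null(c0)) {
    init <- stats::setNames(red$net$species$initial, red$net$species$id)
    c0 <- if (red$mode == "qe")
      stats::setNames(as.numeric(t(red$pools) %*% init), colnames(red$pools))
    else init[vars]
  }
  c0 <- c0[vars]
  if (is.null(t_min)) t_min <- horizon * 1e-6
  times <- if (log_grid) c(0, exp(seq(log(t_min), log(horizon), length.out = n_points - 1)))
           else seq(0, horizon, length.out = n_points)
  f <- function(t, y, p) {
    names(y) <- vars
    vals <- c(pmax(y, 0), pars)
    dy <- stats::setNames(numeric(length(vars)), vars)
    for (rx in red$reactions) {
      rate <- eval_sym(rx$rate, vals)
      st <- rx$stoich[names(rx$stoich) %in% vars]
      dy[names(st)] <- dy[names(st)] + st * rate
    }
    list(as.numeric(dy))
  }
  sol <- deSolve::lsoda(y = as.numeric(c0), times = times, func = f, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  conc <- sol[, -1, drop = FALSE]
  colnames(conc) <- vars
  structure(list(times = sol[, 1], conc = conc, method = "lsoda-reduced"),
            class = "crn_trajectory")
}

#' Generic dimension of a constraint manifold
#'
#' Dimension of the solution set of polynomial constraints g_k(c) = 0 at a
#' generic point, computed as n minus the Jacobian rank (evaluated
#' numerically at one or more random positive points).
#'
#' @param constraints list of \code{spoly} (in species and parameters).
#' @param vars variable names defining the ambient space.
#' @param pars named parameter values for the remaining symbols.
#' @param n_points random evaluation points (the maximal rank is used).
#' @param seed seed for the sampling.
#' @return integer dimension.
#' @export
constraint_dimension <- function(constraints, vars, pars = numeric(0),
                                 n_points = 5, seed = 1) {
  pts <- .with_seed(seed, matrix(stats::runif(n_points * length(vars), 0.5, 2),
                                 n_points, length(vars)))
  h <- 1e-6
  maxrank <- 0
  for (pi in seq_len(n_points)) {
    x <- stats::setNames(pts[pi, ], vars)
    J <- matrix(0, length(constraints), length(vars))
    for (k in seq_along(constraints)) for (j in seq_along(vars)) {
      xp <- x; xp[j] <- xp[j] + h
      xm <- x; xm[j] <- xm[j] - h
      J[k, j] <- (sp_eval(constraints[[k]], c(xp, pars)) -
                  sp_eval(constraints[[k]], c(xm, pars))) / (2 * h)
    }
    maxrank <- max(maxrank, qr(J, tol = 1e-7)$rank)
  }
  length(vars) - maxrank
}

## ---- effective parameters ----------------------------------------------

#' Effective parameters of a reduced model
#'
#' Expresses every coefficient of the reduced rates as an integer-exponent
#' monomial of the original parameters where possible; coefficients that are
#' sums of parameter monomials (like the Michaelis constant) are reported as
#' named rational composites, optionally simplified by dominance at the
#' given parameter values.
#'
#' @param red a \code{reduced_network} or \code{reduced_linear}.
#' @param dominance_margin if not NULL, drop composite terms more than this
#'   factor below the dominant one (evaluated at the network's parameter
#'   values), turning weakly separated composites into monomials.
#' @param ... unused.
#' @return data.frame: name, kind ("monomial"/"composite"), expression,
#'   value (numeric at the network parameters).
#' @export
effective_parameters <- function(red, ...) UseMethod("effective_parameters")

#' @rdname effective_parameters
#' @export
effective_parameters.reduced_linear <- function(red, ...) {
  out <- NULL
  for (e in red$edges) {
    mono <- e$mono[e$mono != 0]
    out <- rbind(out, data.frame(
      name = paste0("k_", e$from, "_", e$to), kind = "monomial",
      expression = .mono_str(mono), value = exp(e$logk),
      stringsAsFactors = FALSE))
  }
  out
}

#' @rdname effective_parameters
#' @export
effective_parameters.reduced_network <- function(red, dominance_margin = NULL, ...) {
  pars <- red$net$parameters
  out <- NULL
  emit <- function(name, groups) {
    # groups: list of (named param-exponent vector, numeric coef) terms
    if (length(groups) == 1 && abs(groups[[1]]$coef - 1) < 1e-12) {
      out <<- rbind(out, data.frame(name = name, kind = "monomial",
                                    expression = .mono_str(groups[[1]]$par),
                                    value = .mono_eval(groups[[1]], pars),
                                    stringsAsFactors = FALSE))
      return()
    }
    vals <- vapply(groups, .mono_eval, 0, pars = pars)
    if (!is.null(dominance_margin)) {
      keep <- abs(vals) >= max(abs(vals)) / dominance_margin
      groups <- groups[keep]; vals <- vals[keep]
    }
    if (length(groups) == 1 && abs(groups[[1]]$coef - 1) < 1e-12) {
      out <<- rbind(out, data.frame(name = name, kind = "monomial",
                                    expression = .mono_str(groups[[1]]$par),
                                    value = vals[1], stringsAsFactors = FALSE))
    } else {
      expr <- paste(vapply(groups, function(g) {
        s <- .mono_str(g$par)
        if (abs(g$coef - 1) < 1e-12) s else paste0(g$coef, "*", s)
      }, ""), collapse = " + ")
      out <<- rbind(out, data.frame(name = name, kind = "composite",
                                    expression = expr, value = sum(vals),
                                    stringsAsFactors = FALSE))
    }
  }
  for (rx in red$reactions) {
    rate <- rx$rate
    if (inherits(rate, "scaled_expr")) rate <- rate$coef
    if (!inherits(rate, "srat")) next
    ng <- .group_by_species(rate$num, names(pars))
    dg <- .group_by_species(rate$den, names(pars))
    if (length(ng) == 0) next
    # normalize by the parameter content of the highest species-degree
    # denominator group (monomial groups only)
    pivot <- NULL
    if (length(dg)) {
      degs <- vapply(dg, function(g) sum(abs(g$spe)), 0)
      for (j in order(degs, decreasing = TRUE)) {
        if (length(dg[[j]]$terms) == 1) { pivot <- dg[[j]]$terms[[1]]; break }
      }
    }
    norm_par <- if (is.null(pivot)) stats::setNames(numeric(0), character(0)) else pivot$par
    norm_coef <- if (is.null(pivot)) 1 else pivot$coef
    k <- 0
    for (g in ng) {
      k <- k + 1
      terms <- lapply(g$terms, function(tm)
        list(par = .mono_sub(tm$par, norm_par), coef = tm$coef / norm_coef))
      emit(paste0(rx$id, "_a", k), terms)
    }
    k <- 0
    for (g in dg) {
      terms <- lapply(g$terms, function(tm)
        list(par = .mono_sub(tm$par, norm_par), coef = tm$coef / norm_coef))
      if (length(terms) == 1 && length(terms[[1]]$par) == 0 &&
          abs(terms[[1]]$coef - 1) < 1e-12) next  # the pivot itself
      k <- k + 1
      emit(paste0(rx$id, "_K", k), terms)
    }
  }
  out
}

.mono_eval <- function(g, pars) {
  g$coef * (if (length(g$par)) prod(pars[names(g$par)]^g$par) else 1)
}

# split an spoly into groups sharing the same species exponents; each group
# holds its parameter-monomial terms
.group_by_species <- function(p, param_names) {
  groups <- list()
  for (t in unclass(p)) {
    sp <- t$p[setdiff(names(t$p), param_names)]
    pp <- t$p[intersect(names(t$p), param_names)]
    key <- .term_key(sp)
    if (is.null(groups[[key]]))
      groups[[key]] <- list(spe = sp, terms = list())
    groups[[key]]$terms[[length(groups[[key]]$terms) + 1L]] <-
      list(par = pp, coef = t$c)
  }
  unname(groups)
}
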