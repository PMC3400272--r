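# Data model and I/O for deterministic mass-action reaction networks.
#
# A network (class "crn") holds an ordered species table, an ordered reaction
# list, and a parameter map. Species declaration order fixes all vector and
# matrix indexing. Rate constants may be tied to parameter symbols (as integer
# exponent vectors, so that k1*Etot is representable); this is what lets the
# reduction stages report effective parameters as monomials of the original
# constants.

#' Create a species table
#'
#' @param id character vector of unique species identifiers.
#' @param name display names (defaults to id).
#' @param initial non-negative initial concentrations.
#' @param compartment optional compartment identifiers.
#' @return data.frame with one row per species.
#' @export
species_table <- function(id, name = id, initial = 0, compartment = NA_character_) {
  stopifnot(!anyDuplicated(id))
  if (length(id) == 0)
    return(data.frame(id = character(0), name = character(0),
                      initial = numeric(0), compartment = character(0),
                      stringsAsFactors = FALSE))
  df <- data.frame(id = as.character(id), name = as.character(name),
                   initial = as.numeric(initial),
                   compartment = as.character(compartment),
                   stringsAsFactors = FALSE)
  if (any(df$initial < 0)) stop("initial concentrations must be non-negative")
  df
}

#' Create a reaction
#'
#' @param id reaction identifier.
#' @param reactants named integer vector of reactant stoichiometries.
#' @param products named integer vector of product stoichiometries.
#' @param kf forward rate constant: a positive number, a parameter symbol, or a
#'   named exponent vector over parameter symbols (e.g. \code{c(k1=1, Etot=1)}).
#' @param kr backward constant in the same forms; 0 (default) means irreversible.
#' @return an object of class \code{crn_reaction}.
#' @export
reaction <- function(id, reactants, products, kf, kr = 0) {
  pr <- .parse_k(kf); pb <- .parse_k(kr)
  if (length(reactants) + length(products) == 0 ||
      (sum(abs(reactants)) + sum(abs(products))) == 0)
    stop("reaction ", id, " has no nonzero stoichiometric entry")
  structure(list(id = as.character(id),
                 reactants = .clean_stoich(reactants),
                 products = .clean_stoich(products),
                 kf = pr$value, kf_par = pr$par,
                 kr = pb$value, kr_par = pb$par,
                 reversible = !identical(pb$value, 0) || !is.null(pb$par)),
            class = "crn_reaction")
}

.clean_stoich <- function(s) {
  if (length(s) == 0) return(stats::setNames(integer(0), character(0)))
  stopifnot(!is.null(names(s)), all(s == round(s)), all(s >= 0))
  s <- s[s != 0]
  stats::setNames(as.integer(s), names(s))
}

# A rate constant spec: numeric literal, parameter symbol, or exponent vector.
.parse_k <- function(k) {
  if (is.numeric(k) && is.null(names(k)) && length(k) == 1)
    return(list(value = as.numeric(k), par = NULL))
  if (is.character(k) && length(k) == 1)
    return(list(value = NA_real_, par = stats::setNames(1, k)))
  if (is.numeric(k) && !is.null(names(k)))
    return(list(value = NA_real_, par = k))
  stop("invalid rate constant specification")
}

#' Assemble a reaction network
#'
#' @param species species table from [species_table()].
#' @param reactions list of [reaction()] objects.
#' @param parameters named numeric vector of positive parameter values.
#' @return validated object of class \code{crn}.
#' @export
crn <- function(species, reactions = list(), parameters = numeric(0)) {
  net <- structure(list(species = species, reactions = reactions,
                        parameters = parameters), class = "crn")
  validate_crn(net)
}

#' @export
validate_crn <- function(net) {
  ids <- net$species$id
  for (rx in net$reactions) {
    refs <- c(names(rx$reactants), names(rx$products))
    bad <- setdiff(refs, ids)
    if (length(bad)) stop("reaction ", rx$id, " references unknown species: ",
                          paste(bad, collapse = ", "))
    for (side in c("kf", "kr")) {
      par <- rx[[paste0(side, "_par")]]
      if (!is.null(par)) {
        miss <- setdiff(names(par), names(net$parameters))
        if (length(miss)) stop("reaction ", rx$id, " uses undeclared parameters: ",
                               paste(miss, collapse = ", "))
      }
    }
  }
  if (any(net$parameters <= 0)) stop("parameters must be positive")
  # resolve numeric values of symbolic constants
  net$reactions <- lapply(net$reactions, function(rx) {
    if (!is.null(rx$kf_par)) rx$kf <- prod(net$parameters[names(rx$kf_par)]^rx$kf_par)
    if (!is.null(rx$kr_par)) rx$kr <- prod(net$parameters[names(rx$kr_par)]^rx$kr_par)
    if (is.na(rx$kf) || rx$kf <= 0) stop("reaction ", rx$id, " needs a positive forward constant")
    if (is.na(rx$kr) || rx$kr < 0) stop("reaction ", rx$id, " has an invalid backward constant")
    rx$reversible <- rx$kr > 0
    rx
  })
  net
}

#' @export
print.crn <- function(x, ...) {
  cat("Mass-action reaction network:", nrow(x$species), "species,",
      length(x$reactions), "reactions,", length(x$parameters), "parameters\n")
  for (rx in x$reactions) {
    arrow <- if (rx$reversible) "<=>" else "-->"
    cat(sprintf("  %s: %s %s %s   (kf=%g%s)\n", rx$id,
                .format_side(rx$reactants), arrow, .format_side(rx$products),
                rx$kf, if (rx$reversible) sprintf(", kr=%g", rx$kr) else ""))
  }
  invisible(x)
}

.format_side <- function(s) {
  if (length(s) == 0) return("0")
  paste(ifelse(s == 1, names(s), paste(s, names(s))), collapse = " + ")
}

#' Number of species / reactions
#' @export
n_species <- function(net) nrow(net$species)
#' @rdname n_species
#' @export
n_reactions <- function(net) length(net$reactions)

## ---- stoichiometry and rates -------------------------------------------

#' Reactant and product stoichiometric matrices
#'
#' @param net a \code{crn}.
#' @return list with integer matrices \code{alpha} (reactants) and \code{beta}
#'   (products), species x reactions.
#' @export
stoich_matrices <- function(net) {
  n <- n_species(net); r <- n_reactions(net)
  a <- matrix(0L, n, r, dimnames = list(net$species$id,
                                        vapply(net$reactions, `[[`, "", "id")))
  b <- a
  for (j in seq_len(r)) {
    rx <- net$reactions[[j]]
    a[names(rx$reactants), j] <- rx$reactants
    b[names(rx$products), j] <- rx$products
  }
  list(alpha = a, beta = b)
}

#' Stoichiometric matrix (products minus reactants)
#'
#' Entry (i, j) is the net production of species i by reaction j.
#'
#' @param net a \code{crn}.
#' @return integer matrix, species x reactions.
#' @export
stoichiometric_matrix <- function(net) {
  m <- stoich_matrices(net)
  m$beta - m$alpha
}

#' Mass-action reaction rates at a concentration vector
#'
#' @param net a \code{crn}.
#' @param conc named (or ordered) non-negative concentration vector.
#' @param net_rates if TRUE (default) return forward minus backward rates;
#'   otherwise a list with both.
#' @return numeric vector of per-reaction rates (or list(forward, backward)).
#' @export
reaction_rates <- function(net, conc, net_rates = TRUE) {
  conc <- .conc_vec(net, conc)
  if (any(conc < 0)) stop("negative concentration: mass-action rates need conc >= 0")
  m <- stoich_matrices(net)
  fwd <- vapply(seq_len(n_reactions(net)), function(j) {
    net$reactions[[j]]$kf * prod(conc^m$alpha[, j])
  }, 0)
  bwd <- vapply(seq_len(n_reactions(net)), function(j) {
    kr <- net$reactions[[j]]$kr
    if (kr == 0) 0 else kr * prod(conc^m$beta[, j])
  }, 0)
  if (net_rates) fwd - bwd else list(forward = fwd, backward = bwd)
}

.conc_vec <- function(net, conc) {
  ids <- net$species$id
  if (!is.null(names(conc))) {
    miss <- setdiff(ids, names(conc))
    if (length(miss)) stop("missing concentrations for: ", paste(miss, collapse = ", "))
    conc <- conc[ids]
  } else stopifnot(length(conc) == length(ids))
  stats::setNames(as.numeric(conc), ids)
}

## ---- polynomial right-hand side ----------------------------------------

#' Polynomial vector field of a mass-action network
#'
#' Builds, for every species, the signed monomial list of its balance
#' polynomial P_i(c), with each monomial carrying its numeric coefficient, its
#' symbolic parameter content (integer exponents over parameter symbols), its
#' species exponent vector, and the reaction/direction it came from.
#'
#' @param net a \code{crn}.
#' @return object of class \code{crn_rhs}: list with \code{species} (ids) and
#'   \code{monomials} (per-species list of monomial records).
#' @export
crn_rhs <- function(net) {
  ids <- net$species$id
  m <- stoich_matrices(net)
  nu <- m$beta - m$alpha
  mon <- stats::setNames(replicate(length(ids), list(), simplify = FALSE), ids)
  for (j in seq_len(n_reactions(net))) {
    rx <- net$reactions[[j]]
    for (i in which(nu[, j] != 0)) {
      # forward term: nu_ij * kf * c^alpha_j
      co <- nu[i, j] * rx$kf
      mon[[i]][[length(mon[[i]]) + 1L]] <- list(
        sign = sign(co), coef = abs(co),
        par = if (is.null(rx$kf_par)) stats::setNames(numeric(0), character(0)) else rx$kf_par,
        num = abs(nu[i, j]),
        spe = m$alpha[, j], reaction = rx$id, dir = 1L)
      if (rx$kr > 0) {
        co <- -nu[i, j] * rx$kr
        mon[[i]][[length(mon[[i]]) + 1L]] <- list(
          sign = sign(co), coef = abs(co),
          par = if (is.null(rx$kr_par)) stats::setNames(numeric(0), character(0)) else rx$kr_par,
          num = abs(nu[i, j]),
          spe = m$beta[, j], reaction = rx$id, dir = -1L)
      }
    }
  }
  structure(list(species = ids, monomials = mon,
                 parameters = net$parameters), class = "crn_rhs")
}

#' Evaluate a polynomial vector field
#'
#' @param field a \code{crn_rhs}.
#' @param conc concentration vector.
#' @return named numeric vector dc/dt.
#' @export
eval_rhs <- function(field, conc) {
  ids <- field$species
  if (!is.null(names(conc))) conc <- conc[ids]
  stats::setNames(vapply(ids, function(i) {
    s <- 0
    for (t in field$monomials[[i]]) s <- s + t$sign * t$coef * prod(conc^t$spe)
    s
  }, 0), ids)
}

#' One species' balance polynomial as a symbolic polynomial
#'
#' Symbols are species ids and parameter symbols; the numeric part of each
#' coefficient not accounted for by parameter symbols is kept as the term
#' coefficient (it is the stoichiometric multiplicity for fully symbolic
#' networks).
#'
#' @param field a \code{crn_rhs}.
#' @param species species id.
#' @return an \code{spoly}.
#' @export
rhs_spoly <- function(field, species) {
  terms <- lapply(field$monomials[[species]], function(t) {
    pv <- if (length(t$par)) prod(field$parameters[names(t$par)]^t$par) else 1
    resid <- t$sign * t$coef / pv
    list(c = resid, p = c(t$par, t$spe[t$spe != 0]))
  })
  sp_poly(terms)
}

#' Substitute a conserved total for one species in a vector field
#'
#' Replaces species \code{eliminate} using the conservation law
#' \code{sum(law * c) = total} (the law must have coefficient 1 on the
#' eliminated species), and removes its equation. Expanded monomials inherit
#' the reaction provenance of the monomial they came from.
#'
#' @param field a \code{crn_rhs}.
#' @param eliminate species id to eliminate.
#' @param law named integer vector (a conservation law).
#' @param total parameter symbol naming the conserved total.
#' @return a \code{crn_rhs} over the remaining species.
#' @export
rhs_eliminate <- function(field, eliminate, law, total) {
  stopifnot(law[[eliminate]] == 1)
  others <- setdiff(names(law)[law != 0], eliminate)
  keep <- setdiff(field$species, eliminate)
  out <- stats::setNames(replicate(length(keep), list(), simplify = FALSE), keep)
  for (i in keep) {
    for (t in field$monomials[[i]]) {
      e <- t$spe[[eliminate]]
      if (is.null(e) || e == 0) {
        t$spe <- t$spe[keep]
        out[[i]][[length(out[[i]]) + 1L]] <- t
        next
      }
      # expand (total - sum_j law_j c_j)^e
      base <- list(list(par = stats::setNames(1, total), spe = stats::setNames(rep(0, length(keep)), keep), c = 1))
      repl <- base
      for (o in others) {
        # term -law_o * c_o
        base <- c(base, list(list(par = stats::setNames(numeric(0), character(0)),
                                  spe = stats::setNames(as.numeric(keep == o), keep), c = -law[[o]])))
      }
      repl <- base
      acc <- list(list(par = stats::setNames(numeric(0), character(0)),
                       spe = stats::setNames(rep(0, length(keep)), keep), c = 1))
      for (k in seq_len(e)) {
        nxt <- list()
        for (a in acc) for (b in repl) {
          pp <- a$par
          for (nm in names(b$par)) pp[nm] <- (if (nm %in% names(pp)) pp[nm] else 0) + b$par[nm]
          nxt[[length(nxt) + 1L]] <- list(par = pp, spe = a$spe + b$spe, c = a$c * b$c)
        }
        acc <- nxt
      }
      for (a in acc) {
        pval <- if (length(a$par)) prod(field$parameters[names(a$par)]^a$par) else 1
        coef <- t$coef * abs(a$c) * pval
        if (coef == 0) next
        sgn <- t$sign * sign(a$c)
        pv <- c(t$par, a$par)
        pv <- tapply(unlist(pv), names(unlist(pv)), sum)
        pv <- stats::setNames(as.numeric(pv), names(pv))
        pv <- pv[pv != 0]
        out[[i]][[length(out[[i]]) + 1L]] <- list(
          sign = sgn, coef = coef, par = pv, num = t$num,
          spe = t$spe[keep] + a$spe, reaction = t$reaction, dir = t$dir)
      }
    }
  }
  pars <- field$parameters
  structure(list(species = keep, monomials = out, parameters = pars),
            class = "crn_rhs")
}

#' Conservation laws of a reaction network
#'
#' Exact integer basis of the left kernel of the stoichiometric matrix,
#' normalized to primitive vectors with non-negative entries preferred.
#'
#' @param net a \code{crn}.
#' @return integer matrix (species x number of laws); each column b satisfies
#'   \code{t(b) \%*\% stoichiometric_matrix(net) == 0} exactly.
#' @export
conservation_laws <- function(net) {
  S <- stoichiometric_matrix(net)
  B <- left_nullspace_int(S)
  B <- .prefer_nonneg(B)
  rownames(B) <- net$species$id
  B
}
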