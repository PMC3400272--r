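# Detection of slaved species by imposed trajectories, and their
# classification into quasi-equilibrium (QE) and quasi-steady-state (QSS)
# species by monomial pruning.
#
# Given simulated trajectories c(t), the imposed trajectory of species i is
# a positive root c*_i(t) of its own balance polynomial with every other
# coordinate frozen at c(t). A species whose trajectory stays within a small
# log-distance delta of an imposed trajectory is slaved (fast, driven by the
# slow species); the remaining species are slow, and their number lower-
# bounds the dimension of any reduced model. Among slaved species, pruning
# the dominated monomials of the balance decides the sub-type: if the
# retained monomials pair into forward/backward rates of reversible
# reactions set to zero the species is at quasi-equilibrium, otherwise it is
# a quasi-steady-state species.

#' Integrate a reaction network (stiff-capable)
#'
#' @param net a \code{crn} (or a \code{crn_rhs} via \code{field}).
#' @param c0 named initial concentrations (defaults to the species table).
#' @param horizon final time.
#' @param n_points number of saved time points.
#' @param log_grid logarithmically spaced time grid (default) or linear.
#' @param t_min first positive time of the log grid.
#' @param rtol,atol solver tolerances (lsoda).
#' @return a \code{crn_trajectory}; conservation-law drift beyond 1e-6
#'   relative triggers a warning naming the law.
#' @export
integrate_full <- function(net, c0 = NULL, horizon, n_points = 300,
                           log_grid = TRUE, t_min = NULL,
                           rtol = 1e-8, atol = 1e-12) {
  field <- crn_rhs(net)
  if (is.null(c0)) c0 <- stats::setNames(net$species$initial, net$species$id)
  c0 <- c0[field$species]
  if (any(c0 < 0)) stop("negative initial concentration")
  if (is.null(t_min)) t_min <- horizon * 1e-6
  times <- if (log_grid) c(0, exp(seq(log(t_min), log(horizon), length.out = n_points - 1)))
           else seq(0, horizon, length.out = n_points)
  f <- function(t, y, p) list(eval_rhs(field, pmax(y, 0)))
  sol <- deSolve::lsoda(y = as.numeric(c0), times = times, func = f, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (nrow(sol) < length(times))
    stop("integration failed near t = ", format(sol[nrow(sol), 1]),
         " (stiff interval); tighten tolerances or shorten the horizon")
  conc <- sol[, -1, drop = FALSE]
  colnames(conc) <- field$species
  laws <- conservation_laws(net)
  if (ncol(laws)) {
    for (k in seq_len(ncol(laws))) {
      v <- conc %*% laws[, k]
      scale <- max(abs(v[1]), 1e-300)
      if (max(abs(v - v[1])) > 1e-6 * scale)
        warning("conservation law ", paste(net$species$id[laws[, k] != 0], collapse = "+"),
                " drifts by ", format(max(abs(v - v[1])) / scale), " relative")
    }
  }
  structure(list(times = times, conc = conc, method = "lsoda",
                 field = field), class = "crn_trajectory")
}

#' Imposed trajectory of one species
#'
#' At every saved time, solves P_i(c_1(t), ..., c*_i, ..., c_n(t)) = 0 for
#' the positive roots c*_i, the other coordinates frozen at the simulated
#' trajectory, and selects the root closest to c_i(t) in log distance (all
#' positive roots are retained in the result).
#'
#' @param field a \code{crn_rhs}.
#' @param traj a \code{crn_trajectory} over the same species.
#' @param species the species id.
#' @return object of class \code{imposed_trajectory}: \code{times},
#'   \code{values} (selected root, NA when no positive root exists),
#'   \code{n_roots}, \code{all_roots} (list).
#' @export
imposed_trajectory <- function(field, traj, species) {
  mons <- field$monomials[[species]]
  degs <- vapply(mons, function(t) t$spe[[species]], 0)
  if (all(degs == 0) || length(mons) == 0)
    stop("balance polynomial of ", species, " does not depend on ", species,
         ": species cannot be slaved")
  dmax <- max(degs)
  nt <- length(traj$times)
  vals <- rep(NA_real_, nt)
  nroots <- integer(nt)
  allroots <- vector("list", nt)
  other <- setdiff(field$species, species)
  for (ti in seq_len(nt)) {
    cc <- traj$conc[ti, ]
    coefs <- numeric(dmax + 1)
    for (m in mons) {
      rest <- prod(pmax(cc[other], 0)^m$spe[other])
      coefs[m$spe[[species]] + 1] <- coefs[m$spe[[species]] + 1] + m$sign * m$coef * rest
    }
    roots <- .positive_roots(coefs)
    allroots[[ti]] <- roots
    nroots[ti] <- length(roots)
    if (length(roots)) {
      ci <- max(cc[species], 1e-300)
      vals[ti] <- roots[which.min(abs(log(roots) - log(ci)))]
    }
  }
  structure(list(species = species, times = traj$times, values = vals,
                 n_roots = nroots, all_roots = allroots),
            class = "imposed_trajectory")
}

.positive_roots <- function(coefs) {
  while (length(coefs) > 1 && coefs[length(coefs)] == 0)
    coefs <- coefs[-length(coefs)]
  d <- length(coefs) - 1
  if (d <= 0) return(numeric(0))
  if (d == 1) {
    r <- -coefs[1] / coefs[2]
    return(if (is.finite(r) && r > 0) r else numeric(0))
  }
  z <- polyroot(coefs)
  re <- Re(z)[abs(Im(z)) < 1e-8 * pmax(abs(Re(z)), 1)]
  sort(re[re > 0])
}

#' Classify one species as slaved or slow
#'
#' @param traj a \code{crn_trajectory}.
#' @param imposed an \code{imposed_trajectory} for the species.
#' @param delta slaving threshold in log units (default log 2: within
#'   two-fold of the imposed value).
#' @param interval numeric length-2 time window; defaults to the whole
#'   trajectory after the initial layer (see [slaved_report()]).
#' @return list: \code{status} ("slaved"/"slow"), \code{sup_logdist},
#'   \code{interval}, \code{logdist} (per saved time, NA outside).
#' @export
classify_species <- function(traj, imposed, delta = log(2), interval = NULL) {
  if (is.null(interval)) interval <- range(traj$times)
  sel <- traj$times >= interval[1] & traj$times <= interval[2]
  ci <- pmax(traj$conc[, imposed$species], 1e-300)
  dl <- abs(log(ci) - log(imposed$values))
  dsel <- dl[sel]
  if (all(is.na(dsel))) return(list(status = "slow", sup_logdist = Inf,
                                    interval = interval, logdist = dl))
  sup <- max(dsel, na.rm = TRUE)
  if (any(is.na(dsel))) sup <- Inf  # missing imposed value counts against slaving
  list(status = if (sup < delta) "slaved" else "slow",
       sup_logdist = sup, interval = interval, logdist = dl)
}

#' Slaved / slow classification of every species, with QE/QSS sub-typing
#'
#' Runs [imposed_trajectory()] and [classify_species()] for each species and
#' [classify_qe_vs_qss()] for the slaved ones. The comparison interval
#' excludes an initial layer of \code{layer_factor} times the fastest
#' timescale (estimated from the Jacobian diagonal at the initial state).
#'
#' @param net a \code{crn}.
#' @param traj a \code{crn_trajectory} from [integrate_full()] (or compatible).
#' @param delta slaving threshold in log units.
#' @param layer_factor multiple of the fastest timescale excluded at the start.
#' @param margin dominance margin for monomial pruning (log units).
#' @param field optional \code{crn_rhs} overriding \code{crn_rhs(net)} (e.g.
#'   a reduced-variable field).
#' @return object of class \code{slaved_report}: data.frame with one row per
#'   species (status, sub-status, sup log-distance, interval) plus per-species
#'   details in \code{attr(, "details")}.
#' @export
slaved_report <- function(net, traj, delta = log(2), layer_factor = 3,
                          margin = log(10), field = NULL) {
  if (is.null(field)) field <- if (inherits(net, "crn_rhs")) net else crn_rhs(net)
  c0 <- traj$conc[1, ]
  # fastest timescale from the Jacobian diagonal at the initial state
  jdiag <- vapply(field$species, function(i) {
    s <- 0
    for (m in field$monomials[[i]]) {
      e <- m$spe[[i]]
      if (e > 0) {
        cc <- c0; cc[i] <- max(cc[i], 1e-300)
        s <- s + m$sign * m$coef * e * prod(cc^m$spe) / cc[i]
      }
    }
    abs(s)
  }, 0)
  tfast <- 1 / max(jdiag, 1e-300)
  interval <- c(min(max(traj$times) / 10, layer_factor * tfast), max(traj$times))
  rows <- NULL
  details <- list()
  for (sp in field$species) {
    imp <- tryCatch(imposed_trajectory(field, traj, sp), error = function(e) e)
    if (inherits(imp, "error")) {
      rows <- rbind(rows, data.frame(species = sp, status = "slow",
                                     substatus = "n/a", sup_logdist = NA_real_,
                                     t_from = interval[1], t_to = interval[2],
                                     stringsAsFactors = FALSE))
      details[[sp]] <- list(error = conditionMessage(imp))
      next
    }
    cl <- classify_species(traj, imp, delta = delta, interval = interval)
    sub <- "n/a"
    qq <- NULL
    if (cl$status == "slaved") {
      qq <- classify_qe_vs_qss(field, traj, sp, margin = margin, interval = interval)
      sub <- qq$status
    }
    rows <- rbind(rows, data.frame(species = sp, status = cl$status,
                                   substatus = sub, sup_logdist = cl$sup_logdist,
                                   t_from = interval[1], t_to = interval[2],
                                   stringsAsFactors = FALSE))
    details[[sp]] <- list(imposed = imp, classification = cl, qeqss = qq)
  }
  structure(rows, details = details, delta = delta, class = c("slaved_report", "data.frame"))
}

#' @export
print.slaved_report <- function(x, ...) {
  cat("Slaved-species report (delta =", format(attr(x, "delta"), digits = 3), "log units)\n")
  df <- as.data.frame(x)
  df$sup_logdist <- signif(df$sup_logdist, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Classify a slaved species as QE or QSS by monomial pruning
#'
#' Monomials of the species' balance polynomial whose time-median log
#' magnitude lies more than \code{margin} below the largest are pruned. If
#' the retained monomials pair into the forward and backward rates of
#' reversible reactions (a combination of reversible rates set to zero) the
#' species satisfies quasi-equilibrium conditions; if an irreversible
#' contribution is retained it is a quasi-steady-state species. A species
#' touched only by irreversible reactions is QSS outright.
#'
#' @param field a \code{crn_rhs}.
#' @param traj a \code{crn_trajectory}.
#' @param species species id.
#' @param margin dominance margin in log units (default one decade).
#' @param interval time window for the medians (default: whole trajectory).
#' @return list: \code{status} ("QE", "QSS" or "unresolved"),
#'   \code{retained} (data.frame of kept monomials: reaction, direction,
#'   median log10 magnitude), \code{pruned}, \code{magnitudes}.
#' @export
classify_qe_vs_qss <- function(field, traj, species, margin = log(10),
                               interval = NULL) {
  mons <- field$monomials[[species]]
  if (is.null(interval)) interval <- range(traj$times)
  sel <- which(traj$times >= interval[1] & traj$times <= interval[2])
  med <- vapply(mons, function(m) {
    v <- vapply(sel, function(ti) {
      cc <- pmax(traj$conc[ti, ], 1e-300)
      m$coef * prod(cc^m$spe)
    }, 0)
    stats::median(log(v))
  }, 0)
  tab <- data.frame(
    reaction = vapply(mons, `[[`, "", "reaction"),
    dir = vapply(mons, `[[`, 0L, "dir"),
    sign = vapply(mons, `[[`, 0, "sign"),
    median_log10 = med / log(10), stringsAsFactors = FALSE)
  # a species produced/consumed only by irreversible reactions is QSS outright
  rev_reactions <- unique(tab$reaction[tab$dir == -1L])
  if (length(rev_reactions) == 0) {
    return(list(status = "QSS", retained = tab, pruned = tab[0, ],
                magnitudes = tab))
  }
  keep <- med >= max(med) - margin
  kept <- tab[keep, , drop = FALSE]
  qe <- TRUE
  for (r in unique(kept$reaction)) {
    if (!(r %in% rev_reactions)) { qe <- FALSE; break }
    dirs <- kept$dir[kept$reaction == r]
    if (!(1L %in% dirs && -1L %in% dirs)) { qe <- FALSE; break }
  }
  # with no dominated monomial a QSS call would rest on incomparable
  # magnitudes; a clean reversible pairing still identifies QE outright
  if (all(keep) && length(mons) > 1 && !qe) {
    return(list(status = "unresolved", retained = tab, pruned = tab[0, ],
                magnitudes = tab))
  }
  list(status = if (qe) "QE" else "QSS", retained = kept,
       pruned = tab[!keep, , drop = FALSE], magnitudes = tab)
}

#' Log-distance diagnostics between actual and imposed trajectories
#'
#' @param report a \code{slaved_report}.
#' @return data.frame in long format: time, species, log-distance (the
#'   diagnostic plotted to identify slaved species).
#' @export
slaving_distances <- function(report) {
  details <- attr(report, "details")
  out <- NULL
  for (sp in names(details)) {
    d <- details[[sp]]
    if (is.null(d$classification)) next
    out <- rbind(out, data.frame(time = d$imposed$times, species = sp,
                                 logdist = d$classification$logdist,
                                 stringsAsFactors = FALSE))
  }
  out
}
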