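# Hybrid simulation of tropicalized dynamics.
#
# Inside a dominance cell the tropicalized system is a monomial (S-system)
# ODE, integrated here in logarithmic coordinates by adaptive RK4. When a
# trajectory reaches a tie surface the crossing time is located by bisection
# on the tie function; the Filippov test then decides between crossing and
# sliding. One-sided fields are always evaluated geometrically (at points
# displaced off the surface along its normal) so that several species whose
# polynomials share one tie hyperplane switch together. Sliding follows the
# Filippov combination lambda*f+ + (1-lambda)*f- with lambda solving the
# invariance condition; for several simultaneous surfaces the multilinear
# corner combination is solved by Gauss-Seidel sweeps. lambda leaving [0,1]
# exits the slide; ties of three or more monomials are flagged degenerate.

#' Simulate the tropicalized (piecewise-smooth) dynamics
#'
#' @param sys a \code{trop_system}.
#' @param c0 positive named initial concentrations.
#' @param horizon final time.
#' @param dt_factor step-size control: log-space step = dt_factor / max |du/dt|.
#' @param floor positivity floor on concentrations (log-evaluation guard).
#' @param tol log-tolerance for tie detection.
#' @param max_steps integration step budget.
#' @param sliding_drift \code{"residual"} (default): on a sliding surface the
#'   drift of every species discontinuous there is computed from its dominated
#'   residual monomials with the tied (mutually cancelling) group replaced by
#'   the value the quasi-steady balance of the sliding species implies; this
#'   reproduces the QSS/QE-reduced dynamics that the sliding mode represents.
#'   \code{"filippov"}: plain convex combination lambda f+ + (1-lambda) f-
#'   with lambda from the invariance condition (loses the slow drift when two
#'   species share one cancellation plane).
#' @return object of class \code{hybrid_trajectory}: \code{times},
#'   \code{conc}, \code{state} (per-time active cell / sliding label), and
#'   \code{events} (data.frame of crossings, sliding entries/exits,
#'   degenerate contacts, floor hits).
#' @export
simulate_hybrid <- function(sys, c0, horizon, dt_factor = 0.05, floor = 1e-30,
                            tol = 1e-9, max_steps = 100000L,
                            sliding_drift = c("residual", "filippov")) {
  sliding_drift <- match.arg(sliding_drift)
  sps <- sys$species
  stopifnot(all(c0[sps] > 0))
  u <- log(c0[sps])
  t <- 0
  sliding <- list()   # active constraints: list(normal, offset, label)
  cap <- 4096L
  times <- numeric(cap); U <- matrix(0, cap, length(sps)); states <- character(cap)
  nrec <- 0L
  ev_time <- numeric(0); ev_type <- character(0); ev_sp <- character(0); ev_det <- character(0)
  log_event <- function(tt, type, species, detail = "") {
    ev_time[length(ev_time) + 1L] <<- tt
    ev_type[length(ev_type) + 1L] <<- type
    ev_sp[length(ev_sp) + 1L] <<- species
    ev_det[length(ev_det) + 1L] <<- detail
  }
  argmax_all <- function(u) {
    vapply(sps, function(sp) {
      tp <- sys$polys[[sp]]
      if (length(tp$logc) == 0) return(NA_integer_)
      dominant_monomial(tp, exp(u))$index
    }, 0L)
  }
  state_label <- function(act) {
    sl <- vapply(sliding, function(s) s$label, "")
    paste0(paste(act, collapse = ","),
           if (length(sl)) paste0(";slide=", paste(sl, collapse = "+")) else "")
  }
  field <- function(u) .sliding_field(sys, u, sliding, floor, sliding_drift)
  on_active_plane <- function(n, off) {
    for (s in sliding) {
      # same hyperplane up to scaling?
      cr <- n %*% s$normal / sqrt(sum(n^2) * sum(s$normal^2))
      if (abs(abs(cr) - 1) < 1e-9) {
        sc <- sqrt(sum(n^2) / sum(s$normal^2)) * sign(cr)
        if (abs(off - sc * s$offset) < 1e-7 * max(1, abs(off))) return(TRUE)
      }
    }
    FALSE
  }
  act <- argmax_all(u)
  steps <- 0L
  record <- function() {
    if (nrec == cap) {
      cap <<- cap * 2L
      times <<- c(times, numeric(cap / 2L))
      U <<- rbind(U, matrix(0, cap / 2L, length(sps)))
      states <<- c(states, character(cap / 2L))
    }
    nrec <<- nrec + 1L
    times[nrec] <<- t; U[nrec, ] <<- u; states[nrec] <<- state_label(act)
  }
  record()
  while (t < horizon && steps < max_steps) {
    steps <- steps + 1L
    f <- field(u)
    fmax <- max(abs(f), 1e-12)
    h <- min(dt_factor / fmax, (horizon - t), horizon * 0.01)
    # step-size rejection: across a regime boundary the field can grow
    # violently; halve the step until the end-point field is commensurate
    for (try_i in 1:30) {
      unew <- .rk4(function(x) field(x), u, h)
      if (all(is.finite(unew)) && max(unew) < 690) {
        fn <- field(unew)
        if (max(abs(fn)) <= 50 * (fmax + 1e-12)) break
      }
      h <- h / 2
    }
    if (any(unew < log(floor))) {
      hit <- sps[unew < log(floor)]
      unew <- pmax(unew, log(floor))
      log_event(t + h, "floor", paste(hit, collapse = ","), "")
    }
    # sliding exit checks
    if (length(sliding)) {
      bad <- integer(0)
      if (sliding_drift == "filippov" || length(sliding) > 1) {
        lam <- attr(field(unew), "lambda")
        if (!any(is.na(lam))) bad <- which(lam < -1e-6 | lam > 1 + 1e-6)
      }
      if (sliding_drift == "residual" && length(sliding) == 1) {
        # the tied group must remain jointly dominant and attracting
        s <- sliding[[1]]
        tp <- sys$polys[[s$species]]
        vals <- tp$logc + as.numeric(tp$E %*% unew)
        tiev <- max(vals[s$pair])
        rest <- vals[-s$pair]
        if (length(rest) && max(rest) > tiev + 1e-9) bad <- 1L
        else {
          ss <- sliding_surface(sys, s$species, s$pair)
          upr <- unew - (sum(ss$normal * unew) - ss$offset) * ss$normal / sum(ss$normal^2)
          if (!sliding_test(ss, stats::setNames(exp(upr), sps))) bad <- 1L
        }
      }
      if (length(bad)) {
        for (di in rev(bad)) {
          log_event(t + h, "exit_sliding", sliding[[di]]$label, "")
          sliding[[di]] <- NULL
        }
        t <- t + h; u <- unew; act <- argmax_all(u); record(); next
      }
      for (s in sliding) {  # kill drift off the active surfaces
        g <- sum(s$normal * unew) - s$offset
        unew <- unew - g * s$normal / sum(s$normal^2)
      }
    }
    # tie crossing detection per species (skip planes already active)
    best <- NULL
    for (sp in sps) {
      tp <- sys$polys[[sp]]
      if (length(tp$logc) < 2) next
      i <- act[[sp]]
      vals_new <- tp$logc + as.numeric(tp$E %*% unew)
      jbest <- which.max(vals_new)
      if (jbest != i && vals_new[jbest] > vals_new[i] + tol) {
        n <- tp$E[i, ] - tp$E[jbest, ]
        off <- tp$logc[jbest] - tp$logc[i]
        if (on_active_plane(n, off)) next
        # fraction of the step at which the tie occurs (linear estimate)
        g0 <- (tp$logc[i] + sum(tp$E[i, ] * u)) - (tp$logc[jbest] + sum(tp$E[jbest, ] * u))
        g1 <- vals_new[i] - vals_new[jbest]
        frac <- if (g0 > 0 && g1 < 0) g0 / (g0 - g1) else 1
        if (is.null(best) || frac < best$frac)
          best <- list(sp = sp, i = i, j = jbest, frac = frac)
      }
    }
    if (is.null(best)) {
      t <- t + h; u <- unew; record(); next
    }
    # bisect to the tie surface
    gfun <- function(x) {
      tp <- sys$polys[[best$sp]]
      (tp$logc[best$i] + sum(tp$E[best$i, ] * x)) -
        (tp$logc[best$j] + sum(tp$E[best$j, ] * x))
    }
    a <- 0; b <- h; ulo <- u
    for (bs in 1:60) {
      mid <- (a + b) / 2
      um <- .rk4(function(x) field(x), u, mid)
      if (gfun(um) > 0) { a <- mid; ulo <- um } else b <- mid
      if (b - a < 1e-10 * max(horizon, 1)) break
    }
    t <- t + a
    u <- ulo
    s <- sliding_surface(sys, best$sp, c(best$i, best$j))
    u <- u - .surface_g(s, u) * s$normal / sum(s$normal^2)
    tp <- sys$polys[[best$sp]]
    ties <- dominant_monomial(tp, exp(u), tol = 1e-7)$ties
    if (length(ties) > 2) log_event(t, "degenerate", best$sp,
                                    paste0("ties: ", paste(ties, collapse = ",")))
    lab <- paste0(best$sp, ":", best$i, "|", best$j)
    if (sliding_test(s, stats::setNames(exp(u), sps))) {
      sliding[[length(sliding) + 1L]] <- list(normal = s$normal, offset = s$offset,
                                              species = best$sp,
                                              pair = c(best$i, best$j), label = lab)
      log_event(t, "enter_sliding", best$sp, lab)
    } else {
      log_event(t, "cross", best$sp, paste0(best$i, " -> ", best$j))
      nhat <- s$normal / sqrt(sum(s$normal^2))
      u <- u - 10 * max(tol, 1e-8) * nhat   # nudge into the new cell
    }
    act <- argmax_all(u)
    record()
  }
  if (steps >= max_steps)
    warning("hybrid simulation stopped at the step budget before the horizon")
  times <- times[seq_len(nrec)]
  U <- U[seq_len(nrec), , drop = FALSE]
  states <- states[seq_len(nrec)]
  events <- data.frame(time = ev_time, type = ev_type, species = ev_sp,
                       detail = ev_det, stringsAsFactors = FALSE)
  colnames(U) <- sps
  structure(list(times = times, conc = exp(U), logconc = U, state = states,
                 events = events, horizon = horizon), class = "hybrid_trajectory")
}

#' @export
print.hybrid_trajectory <- function(x, ...) {
  cat("Hybrid trajectory:", length(x$times), "points to t =",
      format(max(x$times)), "\n")
  if (nrow(x$events)) {
    cat("events:\n")
    tab <- table(x$events$type)
    for (nm in names(tab)) cat(" ", nm, ":", tab[[nm]], "\n")
  }
  invisible(x)
}

.rk4 <- function(f, u, h) {
  k1 <- f(u)
  k2 <- f(u + h / 2 * k1)
  k3 <- f(u + h / 2 * k2)
  k4 <- f(u + h * k3)
  u + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

.sliding_field <- function(sys, u, sliding, floor, mode) {
  if (length(sliding) == 0) return(.trop_field_log(sys, u, floor_log = log(floor)))
  if (mode == "residual" && length(sliding) == 1)
    return(.residual_field(sys, u, sliding[[1]], floor))
  .filippov_field(sys, u, sliding, floor)
}

# QSS/QE-consistent sliding drift on a single surface. The tied monomial
# group cancels at leading order, so its exact value T is unresolved by the
# max-plus field. In mass-action networks every species discontinuous on the
# plane carries a proportional copy of the tied group (the same reactions
# with opposite stoichiometry), so a single unknown T parametrizes all their
# drifts: f_r = (residual_r + kappa_r * T) / c_r. Invariance of the surface,
# <d, f> = 0, is linear in T and closes the system; the result reproduces
# the reduced (QSS/QE) dynamics that the sliding mode represents. The plain
# Filippov combination loses this drift whenever two species share one
# cancellation plane.
.residual_field <- function(sys, u, s, floor) {
  sps <- sys$species
  u <- pmax(u, log(floor))
  tp_s <- sys$polys[[s$species]]
  G <- s$pair
  d <- s$normal
  f0 <- stats::setNames(numeric(length(sps)), sps)   # T-independent part
  fT <- stats::setNames(numeric(length(sps)), sps)   # coefficient of T
  for (si in seq_along(sps)) {
    r <- sps[si]
    tp <- sys$polys[[r]]
    if (length(tp$logc) == 0) next
    match_idx <- vapply(G, function(g) {
      hits <- which(apply(tp$E, 1, function(e) all(e == tp_s$E[g, ])))
      if (length(hits) == 1) hits else NA_integer_
    }, 0L)
    dm <- dominant_monomial(tp, exp(u), tol = 1e-7)
    tied_here <- !any(is.na(match_idx)) &&
      all(match_idx %in% dm$ties) && length(dm$ties) >= 2
    if (tied_here) {
      kap <- (tp$sign[match_idx] * exp(tp$logc[match_idx])) /
             (tp_s$sign[G] * exp(tp_s$logc[G]))
      if (max(abs(kap - kap[1])) <= 1e-9 * max(abs(kap))) {
        vals_r <- tp$sign * exp(tp$logc + as.numeric(tp$E %*% u))
        f0[si] <- sum(vals_r[-match_idx]) * exp(-u[si])
        fT[si] <- kap[1] * exp(-u[si])
        next
      }
    }
    f0[si] <- dm$sign * exp(dm$log_value - u[si])
  }
  coefT <- sum(d * fT)
  if (abs(coefT) < 1e-300) {
    f <- f0
  } else {
    T <- -sum(d * f0) / coefT
    f <- f0 + fT * T
  }
  attr(f, "lambda") <- NA_real_
  f
}

# Filippov field honoring active sliding constraints. One-sided (corner)
# fields are evaluated at geometric offsets off the active planes; the
# multilinear combination's lambdas solve the invariance conditions
# <n_k, f> = 0, by direct solve for one plane and Gauss-Seidel sweeps for
# several. The lambda vector is attached as an attribute.
.filippov_field <- function(sys, u, sliding, floor) {
  m <- length(sliding)
  delta <- 1e-6
  nh <- lapply(sliding, function(s) s$normal / sqrt(sum(s$normal^2)))
  # project u onto all active planes first
  for (s in sliding) {
    g <- sum(s$normal * u) - s$offset
    u <- u - g * s$normal / sum(s$normal^2)
  }
  corners <- expand.grid(rep(list(c(1, -1)), m))
  fcorner <- lapply(seq_len(nrow(corners)), function(ci) {
    off <- Reduce(`+`, lapply(seq_len(m), function(k) corners[ci, k] * delta * nh[[k]]))
    .trop_field_log(sys, u + off, floor_log = log(floor))
  })
  weight <- function(lam, ci) {
    prod(vapply(seq_len(m), function(k)
      if (corners[ci, k] == 1) lam[k] else 1 - lam[k], 0))
  }
  fmix <- function(lam) {
    Reduce(`+`, lapply(seq_len(nrow(corners)), function(ci)
      weight(lam, ci) * fcorner[[ci]]))
  }
  lam <- rep(0.5, m)
  for (sweep in seq_len(if (m == 1) 1 else 25)) {
    for (k in seq_len(m)) {
      l1 <- lam; l1[k] <- 1
      l0 <- lam; l0[k] <- 0
      g1 <- sum(sliding[[k]]$normal * fmix(l1))
      g0 <- sum(sliding[[k]]$normal * fmix(l0))
      lam[k] <- if (abs(g1 - g0) < 1e-300) 0.5 else g0 / (g0 - g1)
    }
  }
  f <- fmix(pmin(pmax(lam, 0), 1))
  attr(f, "lambda") <- lam
  f
}

#' Write a trajectory to CSV
#'
#' @param traj a \code{crn_trajectory} or \code{hybrid_trajectory}.
#' @param path output file; hybrid trajectories gain a \code{state} column
#'   with the active cell / sliding label.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$conc, check.names = FALSE)
  if (!is.null(traj$state)) df$state <- traj$state
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
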