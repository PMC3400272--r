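# Synthetic-network generators, in-text model builders, and separation
# diagnostics.
#
# The generators define the study conditions used throughout the test suite:
# random simple digraphs with rate constants eps^rank (totally separated by
# construction), the irreversible Michaelis-Menten mechanism and its
# two-variable eliminated form, and a five-variable cell-cycle oscillator.

#' Random monomolecular network with totally separated constants
#'
#' Draws a random simple digraph on \code{n} nodes with \code{m} edges and
#' assigns constants \code{eps^rank(e)} for a seeded random permutation of
#' 1..m, so the constants are totally separated by a factor 1/eps.
#'
#' @param n number of species (nodes).
#' @param m number of reactions (directed edges), at most n(n-1).
#' @param eps separation parameter in (0, 1); adjacent constants differ by 1/eps.
#' @param seed integer seed; same seed gives an identical network.
#' @return a \code{crn} whose reactions are all monomolecular.
#' @export
generate_separated_monomolecular <- function(n, m, eps = 0.1, seed = 1) {
  stopifnot(n >= 2, m >= 1, m <= n * (n - 1), eps > 0, eps < 1)
  rs <- .with_seed(seed, {
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, ]
    idx <- sample(nrow(pairs), m)
    perm <- sample(m)
    list(pairs = pairs[idx, ], perm = perm)
  })
  ids <- paste0("A", seq_len(n))
  sp <- species_table(ids, initial = rep(1 / n, n))
  pars <- stats::setNames(eps^rs$perm, paste0("k", seq_len(m)))
  rxns <- lapply(seq_len(m), function(e) {
    reaction(paste0("r", e),
             reactants = stats::setNames(1L, ids[rs$pairs$from[e]]),
             products = stats::setNames(1L, ids[rs$pairs$to[e]]),
             kf = paste0("k", e))
  })
  crn(sp, rxns, pars)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' The irreversible Michaelis-Menten mechanism
#'
#' Builds the two-reaction enzymatic mechanism S + E <=> ES -> P + E with
#' symbolic constants k1, km1 (the dissociation constant of the complex) and
#' k2, plus the two-variable form in (S, ES) obtained by eliminating E and P
#' through the conservation laws E + ES = Etot and S + ES + P = Stot.
#'
#' @param k1,km1,k2 positive rate constants (binding, unbinding, catalysis).
#' @param Etot total enzyme; \code{Stot} total substrate (initial S).
#' @return list with elements \code{mechanism} (4-species \code{crn}),
#'   \code{reduced_field} (2-variable \code{crn_rhs} over S, ES with Etot as a
#'   parameter) and \code{parameters}.
#' @export
build_michaelis_menten <- function(k1 = 1, km1 = 1, k2 = 1, Etot = 1, Stot = 10) {
  stopifnot(k1 > 0, km1 >= 0, k2 >= 0, Etot > 0, Stot > 0)
  sp <- species_table(c("S", "E", "ES", "P"),
                      initial = c(Stot, Etot, 0, 0))
  pars <- c(k1 = k1, km1 = km1, k2 = k2, Etot = Etot, Stot = Stot)
  pars <- pars[pars > 0]
  rxns <- list(
    reaction("r1", c(S = 1L, E = 1L), c(ES = 1L), kf = "k1",
             kr = if (km1 > 0) "km1" else 0))
  if (k2 > 0)
    rxns[[2]] <- reaction("r2", c(ES = 1L), c(P = 1L, E = 1L), kf = "k2")
  mech <- crn(sp, rxns, pars)
  field <- crn_rhs(mech)
  f2 <- rhs_eliminate(field, "E", c(E = 1, ES = 1), "Etot")
  f2 <- f2[c("species", "monomials", "parameters")]
  class(f2) <- "crn_rhs"
  f2$species <- setdiff(f2$species, "P")
  f2$monomials <- f2$monomials[f2$species]
  f2$monomials <- lapply(f2$monomials, function(l) lapply(l, function(t) {
    t$spe <- t$spe[f2$species]; t
  }))
  list(mechanism = mech, reduced_field = f2, parameters = pars)
}

#' Five-variable cell-cycle oscillator
#'
#' Builds the mass-action network whose balance equations are
#' y1' = k9 y2 - k8 y1 + k6 y3, y2' = k8 y1 - k9 y2 - k3 y2 y5,
#' y3' = k4p y4 + k4 y4 y3^2 / C^2 - k6 y3,
#' y4' = -k4p y4 - k4 y4 y3^2 / C^2 + k3 y2 y5, y5' = k1 - k3 y2 y5,
#' with the conservation law y1 + y2 + y3 + y4 = C.
#'
#' @param k1,k3,k4,k4p,k6,k8,k9 positive rate constants.
#' @param C conserved total of y1..y4 (also scales the autocatalytic term).
#' @param y0 optional named initial state (defaults put the conserved mass in y4).
#' @return a \code{crn} over species y1..y5.
#' @export
build_cell_cycle <- function(k1, k3, k4, k4p, k6, k8, k9, C = 1, y0 = NULL) {
  pars <- c(k1 = k1, k3 = k3, k4 = k4, k4p = k4p, k6 = k6, k8 = k8, k9 = k9, C = C)
  stopifnot(all(pars > 0))
  init <- c(y1 = 0, y2 = 0, y3 = 0, y4 = C, y5 = 0)
  if (!is.null(y0)) init[names(y0)] <- y0
  sp <- species_table(paste0("y", 1:5), initial = init[paste0("y", 1:5)])
  rxns <- list(
    reaction("ry9", c(y2 = 1L), c(y1 = 1L), kf = "k9"),
    reaction("ry8", c(y1 = 1L), c(y2 = 1L), kf = "k8"),
    reaction("ry6", c(y3 = 1L), c(y1 = 1L), kf = "k6"),
    reaction("ry3", c(y2 = 1L, y5 = 1L), c(y4 = 1L), kf = "k3"),
    reaction("ry4p", c(y4 = 1L), c(y3 = 1L), kf = "k4p"),
    reaction("ry4", c(y4 = 1L, y3 = 2L), c(y3 = 3L), kf = c(k4 = 1, C = -2)),
    reaction("ry1", stats::setNames(integer(0), character(0)), c(y5 = 1L), kf = "k1"))
  crn(sp, rxns, pars)
}

#' Check total separation of a constant set
#'
#' Constants are totally separated at a given factor when every ratio of
#' adjacent sorted constants is at least that factor. Also reports the Zipf
#' power-law diagnostic when there are enough values.
#'
#' @param constants positive numeric vector.
#' @param factor required minimal adjacent ratio (default 10, one decade).
#' @return object of class \code{separation_report}: sorted constants, minimal
#'   adjacent log10-ratio, \code{totally_separated} flag, and (for >= 10
#'   values) the Zipf slope estimate with its standard error.
#' @export
check_total_separation <- function(constants, factor = 10) {
  stopifnot(all(constants > 0), factor > 1)
  s <- sort(constants, decreasing = TRUE)
  ratios <- if (length(s) > 1) s[-length(s)] / s[-1] else numeric(0)
  zipf <- if (length(constants) >= 10) tryCatch(zipf_diagnostic(constants),
                                                error = function(e) NULL) else NULL
  structure(list(sorted = s,
                 min_log10_ratio = if (length(ratios)) log10(min(ratios)) else Inf,
                 factor = factor,
                 totally_separated = all(ratios >= factor * (1 - 1e-12)),
                 zipf = zipf),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf("%d constants spanning %.2f decades; min adjacent ratio 10^%.3f\n",
              length(x$sorted), log10(x$sorted[1] / x$sorted[length(x$sorted)]),
              x$min_log10_ratio))
  cat(sprintf("totally separated at factor %g: %s\n", x$factor, x$totally_separated))
  if (!is.null(x$zipf))
    cat(sprintf("Zipf density exponent: %.3f (se %.3f)\n", x$zipf$slope, x$zipf$se))
  invisible(x)
}

#' Zipf power-law diagnostic for rate constants or timescales
#'
#' Estimates the exponent of a power-law density p(v) ~ v^gamma from a sample
#' of positive values. A log-uniform sample (density ~ 1/v) has exponent -1;
#' finding this over a wide range indicates total separation is plausible. The
#' estimate regresses log bin counts against log bin midpoints over
#' logarithmically spaced bins; since counts per log-bin scale as v * p(v),
#' the exponent is the regression slope minus one.
#'
#' @param values positive numeric vector, length >= 10.
#' @param bins number of logarithmic bins (default: ~ sqrt(n)/2, clamped to
#'   \code{[8, 40]}).
#' @return list: \code{slope} (density exponent estimate), \code{se} (its
#'   standard error), \code{rank_plot} (data.frame of log10 value vs log10
#'   rank for plotting).
#' @export
zipf_diagnostic <- function(values, bins = NULL) {
  stopifnot(all(values > 0))
  if (length(values) < 10) stop("need at least 10 values")
  if (max(values) / min(values) < 1 + 1e-12) stop("degenerate input: all values equal")
  if (is.null(bins)) bins <- max(8, min(40, round(sqrt(length(values)) / 2)))
  br <- exp(seq(log(min(values)) - 1e-9, log(max(values)) + 1e-9, length.out = bins + 1))
  cnt <- graphics::hist(values, breaks = br, plot = FALSE)$counts
  mid <- sqrt(br[-1] * br[-length(br)])
  keep <- cnt > 0
  if (sum(keep) < 3) stop("degenerate input: too few occupied bins")
  fit <- stats::lm(log(cnt[keep]) ~ log(mid[keep]))
  sl <- summary(fit)$coefficients
  srt <- sort(values, decreasing = TRUE)
  list(slope = unname(sl[2, 1]) - 1, se = unname(sl[2, 2]),
       rank_plot = data.frame(log10_rank = log10(seq_along(srt)),
                              log10_value = log10(srt)))
}
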