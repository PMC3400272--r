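# Shared fixtures, built in code.

# monomolecular network exercising rule c: cycle A2 -> A3 -> A4 -> A2 with a
# slow exit A3 -> A5 and return A5 -> A2; the cycle must be glued, its exit
# constant renormalized to the monomial k5*k4/k3, and the outer cycle cut by
# comparing k5*k4/k3 with k6
glued_cycle_network <- function(k6 = 1e-2) {
  sp <- species_table(paste0("A", 2:5), initial = c(1, 0, 0, 0))
  pars <- c(k2 = 1, k3 = 1e-1, k4 = 1e-4, k5 = 1e-6, k6 = k6)
  rx <- list(
    reaction("e2", c(A2 = 1L), c(A3 = 1L), kf = "k2"),
    reaction("e3", c(A3 = 1L), c(A4 = 1L), kf = "k3"),
    reaction("e4", c(A4 = 1L), c(A2 = 1L), kf = "k4"),
    reaction("e5", c(A3 = 1L), c(A5 = 1L), kf = "k5"),
    reaction("e6", c(A5 = 1L), c(A2 = 1L), kf = "k6"))
  crn(sp, rx, pars)
}

# substitution list eliminating the free enzyme through E + ES = Etot
mm_enzyme_elimination <- function() {
  list(E = sp_sub(sp_var("Etot"), sp_var("ES")))
}

# random mass-action network with small stoichiometries, for rhs oracles
random_crn <- function(n = 4, r = 5, seed = 1) {
  set.seed(seed)
  ids <- paste0("X", seq_len(n))
  sp <- species_table(ids, initial = runif(n, 0.5, 2))
  pars <- stats::setNames(10^runif(r, -2, 1), paste0("k", seq_len(r)))
  rxns <- lapply(seq_len(r), function(j) {
    repeat {
      re <- stats::setNames(sample(0:2, n, replace = TRUE, prob = c(.6, .3, .1)), ids)
      pr <- stats::setNames(sample(0:2, n, replace = TRUE, prob = c(.6, .3, .1)), ids)
      if (sum(re) + sum(pr) > 0 && !identical(re, pr)) break
    }
    reaction(paste0("r", j), re[re > 0], pr[pr > 0], kf = paste0("k", j))
  })
  crn(sp, rxns, pars)
}

# sup-norm distance between two trajectories on a common grid
traj_sup_error <- function(t1, t2, species = colnames(t1$conc)) {
  max(abs(t1$conc[, species, drop = FALSE] - t2$conc[, species, drop = FALSE]))
}
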