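# Imposed trajectories, slaved/slow classification, QE vs QSS sub-typing.

test_that("linear relaxation matches its closed form and the integrator is stiff-safe", {
  sp <- species_table(c("A", "B"), initial = c(1, 0))
  net <- crn(sp, list(reaction("r", c(A = 1L), c(B = 1L), kf = 0.3)))
  tr <- integrate_full(net, horizon = 20, log_grid = FALSE)
  expect_lt(max(abs(tr$conc[, "A"] - exp(-0.3 * tr$times))), 1e-6)
  expect_lt(max(abs(rowSums(tr$conc) - 1)), 1e-8)
})

test_that("the complex shows a fast initial layer followed by slow decay", {
  mm <- build_michaelis_menten(k1 = 1, km1 = 1e-3, k2 = 1, Etot = 0.01, Stot = 1)
  tr <- integrate_full(mm$mechanism, horizon = 200)
  es <- tr$conc[, "ES"]
  peak <- which.max(es)
  expect_lt(tr$times[peak], 20)             # fast rise
  expect_lt(es[length(es)], es[peak] / 2)   # slow decay afterwards
  # halved tolerances do not change the trajectory materially
  tr2 <- integrate_full(mm$mechanism, horizon = 200, rtol = 5e-9, atol = 5e-13)
  expect_lt(max(abs(tr$conc - tr2$conc)), 1e-5)
})

test_that("a linear balance gives the monic-root imposed trajectory", {
  # P_B = k A - g B  =>  B* = (k/g) A
  sp <- species_table(c("A", "B"), initial = c(1, 0))
  net <- crn(sp, list(reaction("r1", c(A = 1L), c(A = 1L, B = 1L), kf = 2),
                      reaction("r2", c(B = 1L), stats::setNames(integer(0), character(0)), kf = 4)))
  field <- crn_rhs(net)
  traj <- structure(list(times = c(1, 2), conc = rbind(c(A = 1, B = 9), c(A = 2, B = 9))),
                    class = "crn_trajectory")
  imp <- imposed_trajectory(field, traj, "B")
  expect_equal(imp$values, c(0.5, 1))   # (k/g) A = A/2
  expect_equal(imp$n_roots, c(1L, 1L))
  # a species its polynomial does not depend on cannot be slaved
  expect_error(imposed_trajectory(field, traj, "A"), "cannot be slaved")
})

test_that("positive polynomial roots agree with a dense sign-scan oracle", {
  set.seed(17)
  for (rep in 1:20) {
    coefs <- runif(4, -2, 2)
    roots <- crnreduce:::.positive_roots(coefs)
    # oracle: sign changes of the cubic on a dense positive grid
    xs <- exp(seq(log(1e-4), log(1e4), length.out = 40000))
    f <- function(x) coefs[1] + coefs[2] * x + coefs[3] * x^2 + coefs[4] * x^3
    v <- f(xs)
    brackets <- which(v[-1] * v[-length(v)] < 0)
    oracle <- vapply(brackets, function(i)
      uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root, 0)
    expect_equal(length(roots), length(oracle))
    if (length(roots)) expect_equal(roots, sort(oracle), tolerance = 1e-5)
  }
})

test_that("a species identically on its imposed trajectory has distance zero", {
  sp <- species_table(c("A", "B"), initial = c(1, 0))
  net <- crn(sp, list(reaction("r1", c(A = 1L), c(A = 1L, B = 1L), kf = 2),
                      reaction("r2", c(B = 1L), stats::setNames(integer(0), character(0)), kf = 4)))
  field <- crn_rhs(net)
  times <- 1:5
  conc <- cbind(A = rep(2, 5), B = rep(1, 5))  # B = (k/g) A exactly
  traj <- structure(list(times = times, conc = conc), class = "crn_trajectory")
  imp <- imposed_trajectory(field, traj, "B")
  cl <- classify_species(traj, imp)
  expect_equal(cl$status, "slaved")
  expect_equal(cl$sup_logdist, 0)
})

test_that("a deliberately slow species in a two-timescale chain is not slaved", {
  # A -> B -> C with B fast would be slaved; make B slow instead (kb << ka)
  sp <- species_table(c("A", "B", "C"), initial = c(1, 0, 0))
  net <- crn(sp, list(reaction("r1", c(A = 1L), c(B = 1L), kf = "ka"),
                      reaction("r2", c(B = 1L), c(C = 1L), kf = "kb")),
             c(ka = 1, kb = 1e-3))
  tr <- integrate_full(net, horizon = 50)
  rep_ <- slaved_report(net, tr)
  expect_equal(rep_$status[rep_$species == "B"], "slow")
  d <- attr(rep_, "details")$B$classification$sup_logdist
  expect_gt(d, log(10))  # imposed value (ka/kb) A is far above the actual B
})

test_that("the complex is slaved with the correct sub-type in both regimes", {
  # catalysis-dominated: QSS; unbinding-dominated: QE (Etot/Stot = 1e-2)
  qss <- build_michaelis_menten(k1 = 1, km1 = 1e-3, k2 = 1, Etot = 0.1, Stot = 10)
  tr <- integrate_full(qss$mechanism, horizon = 50)
  rep1 <- slaved_report(qss$mechanism, tr)
  expect_equal(rep1$status[rep1$species == "ES"], "slaved")
  expect_equal(rep1$substatus[rep1$species == "ES"], "QSS")
  qe <- build_michaelis_menten(k1 = 1, km1 = 1, k2 = 1e-3, Etot = 0.1, Stot = 10)
  tr2 <- integrate_full(qe$mechanism, horizon = 2e4)
  rep2 <- slaved_report(qe$mechanism, tr2)
  expect_equal(rep2$status[rep2$species == "ES"], "slaved")
  expect_equal(rep2$substatus[rep2$species == "ES"], "QE")
  # the QE pruning retains exactly the binding forward/backward pair
  ret <- attr(rep2, "details")$ES$qeqss$retained
  expect_setequal(paste(ret$reaction, ret$dir), c("r1 1", "r1 -1"))
})

test_that("a species touched only by irreversible reactions is QSS outright", {
  sp <- species_table(c("A", "B", "C"), initial = c(1, 0, 0))
  net <- crn(sp, list(reaction("r1", c(A = 1L), c(B = 1L), kf = 1),
                      reaction("r2", c(B = 1L), c(C = 1L), kf = 100)),
             numeric(0))
  tr <- integrate_full(net, horizon = 10)
  q <- classify_qe_vs_qss(crn_rhs(net), tr, "B")
  expect_equal(q$status, "QSS")
})

test_that("refining the time grid does not inflate the slaving distance", {
  mm <- build_michaelis_menten(k1 = 1, km1 = 1e-3, k2 = 1, Etot = 0.1, Stot = 10)
  field <- crn_rhs(mm$mechanism)
  tr1 <- integrate_full(mm$mechanism, horizon = 50, n_points = 150)
  tr2 <- integrate_full(mm$mechanism, horizon = 50, n_points = 600)
  layer <- c(1, 50)
  d1 <- classify_species(tr1, imposed_trajectory(field, tr1, "ES"), interval = layer)
  d2 <- classify_species(tr2, imposed_trajectory(field, tr2, "ES"), interval = layer)
  expect_lt(d2$sup_logdist, d1$sup_logdist * 1.1 + 1e-12)
})

test_that("classification is invariant under joint rescaling of constants and time", {
  base <- build_michaelis_menten(k1 = 1, km1 = 1e-3, k2 = 1, Etot = 0.1, Stot = 10)
  fast <- build_michaelis_menten(k1 = 100, km1 = 0.1, k2 = 100, Etot = 0.1, Stot = 10)
  tr1 <- integrate_full(base$mechanism, horizon = 50)
  tr2 <- integrate_full(fast$mechanism, horizon = 0.5)
  r1 <- slaved_report(base$mechanism, tr1)
  r2 <- slaved_report(fast$mechanism, tr2)
  expect_equal(r1$status, r2$status)
  expect_equal(r1$substatus, r2$substatus)
})

test_that("the number of slow species lower-bounds the reduced dimension", {
  mm <- build_michaelis_menten(k1 = 1, km1 = 1e-3, k2 = 1, Etot = 0.1, Stot = 10)
  tr <- integrate_full(mm$mechanism, horizon = 50)
  rep_ <- slaved_report(mm$mechanism, tr)
  n_slow <- sum(rep_$status == "slow")
  red <- reduce_qss(mm$mechanism, "ES", substitutions = mm_enzyme_elimination())
  # reduced model: S and P (plus the conserved total as a parameter)
  expect_gte(length(red$slow), n_slow)
})
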