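# QSS/QE rewriting: fast stoichiometry, pools, elementary modes, symbolic
# rates and effective parameters.

test_that("fast stoichiometric matrices follow the mode conventions", {
  mm <- build_michaelis_menten()
  # QSS on the complex: one row, columns binding and catalysis
  fs <- fast_stoichiometry(mm$mechanism, "qss", "ES")
  expect_equal(dim(fs$Sf), c(1L, 2L))
  expect_equal(unname(fs$Sf[1, ]), c(1, -1))
  expect_equal(length(fs$excluded), 0)
  # QE on the binding reaction: one column, the product's zero row excluded
  fs2 <- fast_stoichiometry(mm$mechanism, "qe", "r1")
  expect_equal(dim(fs2$Sf), c(3L, 1L))
  expect_equal(fs2$excluded, "P")
  expect_equal(unname(fs2$Sf[, 1]), c(-1, -1, 1))
  expect_error(fast_stoichiometry(mm$mechanism, "qss", character(0)), "empty")
})

test_that("QE species pools are fast conservation laws minus the global ones", {
  mm <- build_michaelis_menten()
  fs <- fast_stoichiometry(mm$mechanism, "qe", "r1")
  pl <- species_pools(fs)
  # candidates span substrate-total, enzyme-total and the untouched product
  expect_equal(ncol(pl$all_candidates), 3)
  expect_true(all(t(pl$all_candidates[rownames(fs$Sf), 1:2]) %*% fs$Sf == 0))
  # after removing the full-network laws only the substrate total survives
  expect_equal(ncol(pl$pools), 1)
  expect_equal(unname(pl$pools[, 1]), c(1, 0, 1, 0))  # S + ES
  expect_equal(pl$labels, "S+ES")
})

test_that("random fast subsystems give exact kernels of the right dimension", {
  set.seed(23)
  for (rep in 1:20) {
    m <- sample(2:4, 1); n <- sample(2:5, 1)
    Sf <- matrix(sample(-2:2, m * n, replace = TRUE), m, n)
    B <- left_nullspace_int(Sf)
    expect_equal(ncol(B), m - qr(t(Sf))$rank)
    if (ncol(B)) expect_true(all(t(B) %*% Sf == 0))
  }
})

test_that("elementary modes match the exhaustive oracle and respect signs", {
  # chain intermediate: single route pooling the two reactions
  Sf <- matrix(c(1, -1), 1)
  m <- elementary_flux_modes(Sf, c(FALSE, FALSE))
  expect_equal(unname(m[, 1]), c(1, 1))
  # sign-infeasible support: A produced by both reactions, no mode
  Sf2 <- matrix(c(1, 1), 1)
  expect_equal(ncol(elementary_flux_modes(Sf2, c(FALSE, FALSE))), 0)
  # with reversibility the balancing mode exists
  expect_equal(ncol(elementary_flux_modes(Sf2, c(TRUE, FALSE))), 1)
  # tableau equals exhaustive on random instances up to 4x6
  set.seed(31)
  for (rep in 1:40) {
    nr <- sample(2:4, 1); nc <- sample(3:6, 1)
    S <- matrix(sample(-2:2, nr * nc, replace = TRUE), nr, nc)
    rev <- sample(c(TRUE, FALSE), nc, replace = TRUE)
    e1 <- elementary_flux_modes(S, rev, method = "exhaustive")
    e2 <- elementary_flux_modes(S, rev, method = "tableau")
    expect_setequal(apply(e1, 2, paste, collapse = ","),
                    apply(e2, 2, paste, collapse = ","))
    # every mode is an exact kernel vector with minimal support
    if (ncol(e1)) expect_true(all(S %*% e1 == 0))
  }
})

test_that("route intermediates are conserved and terminals are not", {
  mm <- build_michaelis_menten()
  fs <- fast_stoichiometry(mm$mechanism, "qss", "ES")
  routes <- qss_routes(fs)
  expect_equal(length(routes), 1)
  r <- routes[[1]]
  expect_equal(unname(r$gamma[c("r1", "r2")]), c(1, 1))
  expect_setequal(r$terminals, c("S", "P"))
  expect_setequal(r$intermediates, c("E", "ES"))  # enzyme cycles through the route
  expect_equal(unname(r$net_stoich[c("S", "P")]), c(-1, 1))
})

test_that("the catalytic QSS reduction recovers the hyperbolic rate law exactly", {
  mm <- build_michaelis_menten(k1 = 2, km1 = 3, k2 = 5, Etot = 0.1, Stot = 10)
  red <- reduce_qss(mm$mechanism, "ES", substitutions = mm_enzyme_elimination())
  # [ES] = Etot S / (km + S), km = (km1 + k2)/k1
  km <- r_div(srat(sp_add(sp_var("km1"), sp_var("k2"))), srat(sp_var("k1")))
  target_es <- r_div(srat(sp_mul(sp_var("Etot"), sp_var("S"))),
                     r_add(km, srat(sp_var("S"))))
  expect_true(r_equal(red$solutions$ES, target_es))
  # route rate k2 Etot S / (km + S)
  expect_true(r_equal(red$reactions[[1]]$rate, r_mul(srat(sp_var("k2")), target_es)))
  # effective parameters: the monomial k2*Etot and the composite km
  ep <- effective_parameters(red)
  expect_true(any(ep$kind == "monomial" & ep$value == 0.5))   # k2 * Etot
  expect_true(any(ep$kind == "composite" & abs(ep$value - 4) < 1e-12))  # (3+5)/2
  # under catalysis >> unbinding the composite collapses to a monomial
  mm2 <- build_michaelis_menten(k1 = 2, km1 = 1e-4, k2 = 5, Etot = 0.1, Stot = 10)
  red2 <- reduce_qss(mm2$mechanism, "ES", substitutions = mm_enzyme_elimination())
  ep2 <- effective_parameters(red2, dominance_margin = 10)
  expect_true(all(ep2$kind == "monomial"))
})

test_that("the linear fast condition solves as a ratio of constants", {
  sp <- species_table(c("A", "X"), initial = c(1, 0))
  net <- crn(sp, list(reaction("r1", c(A = 1L), c(A = 1L, X = 1L), kf = "k"),
                      reaction("r2", c(X = 1L), stats::setNames(integer(0), character(0)), kf = "g")),
             c(k = 2, g = 4))
  fs <- fast_stoichiometry(net, "qss", "X")
  sol <- solve_fast_conditions(crn_rhs(net), fs)
  expect_true(r_equal(sol$X, r_div(srat(sp_mul(sp_var("k"), sp_var("A"))), srat(sp_var("g")))))
})

test_that("the equilibrium-binding reduction returns the admissible quadratic root", {
  mm <- build_michaelis_menten(k1 = 2, km1 = 3, k2 = 0.01, Etot = 0.1, Stot = 10)
  red <- reduce_qe(mm$mechanism, "r1", solve_for = "ES",
                   substitutions = list(S = sp_sub(sp_var("Stot"), sp_var("ES")),
                                        E = sp_sub(sp_var("Etot"), sp_var("ES"))))
  expect_equal(red$slow, "S+ES")
  root <- red$solutions$ES
  expect_s3_class(root, "quad_root")
  vals <- c(k1 = 2, km1 = 3, k2 = 0.01, Etot = 0.1, Stot = 10)
  x <- eval_sym(root, vals)
  expect_lt(abs(2 * (10 - x) * (0.1 - x) - 3 * x), 1e-12)
  expect_true(x > 0 && x < 0.1)
  # the low-enzyme limit is the classical hyperbolic rate
  lim <- r_mul(srat(sp_var("k2")), limit_small_parameter(root, "Etot"))
  target <- r_div(srat(sp_mono(1, c(k2 = 1, Etot = 1, Stot = 1))),
                  r_add(r_div(srat(sp_var("km1")), srat(sp_var("k1"))), srat(sp_var("Stot"))))
  expect_true(r_equal(lim, target))
})

test_that("reduced and full dynamics of a separated chain agree within 5 percent", {
  sp <- species_table(c("A1", "A2", "A3"), initial = c(1, 0, 0))
  net <- crn(sp, list(reaction("r1", c(A1 = 1L), c(A2 = 1L), kf = "ka"),
                      reaction("r2", c(A2 = 1L), c(A3 = 1L), kf = "kb")),
             c(ka = 0.01, kb = 10))   # separation 1e3
  red <- reduce_qss(net, "A2")
  t_full <- integrate_full(net, horizon = 600)
  t_red <- integrate_reduced(red, horizon = 600)
  err <- max(abs(t_full$conc[, c("A1", "A3")] - t_red$conc[, c("A1", "A3")]))
  expect_lt(err, 0.05)
})

test_that("identity reduction yields no effective parameters", {
  sp <- species_table(c("A", "B"), initial = c(1, 0))
  net <- crn(sp, list(reaction("r", c(A = 1L), c(B = 1L), kf = "k")), c(k = 1))
  red <- structure(list(mode = "qss", slow = c("A", "B"), reactions = list(),
                        net = net, flags = character(0)), class = "reduced_network")
  expect_null(effective_parameters(red))
})

test_that("the glued-cycle reduction reports its renormalized monomial", {
  net <- glued_cycle_network(k6 = 1e-12)
  r <- reduce_monomolecular(rank_label(net))
  ep <- effective_parameters(r)
  row <- ep[ep$name == "k_A4_A5", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$value, 1e-9, tolerance = 1e-9)
  expect_true(grepl("k5", row$expression) && grepl("k4", row$expression) &&
              grepl("k3\\^-1", row$expression))
})

test_that("the slow-manifold dimension drops by one per independent constraint", {
  g1 <- sp_sub(sp_mono(1, c(k8 = 1, y1 = 1)), sp_mono(1, c(k9 = 1, y2 = 1)))
  g2 <- sp_sub(sp_var("k1"), sp_mono(1, c(k3 = 1, y2 = 1, y5 = 1)))
  g3 <- sp_sub(sp_add(sp_add(sp_var("y1"), sp_var("y2")),
                      sp_add(sp_var("y3"), sp_var("y4"))), sp_var("C"))
  pars <- c(k1 = 0.015, k3 = 200, k8 = 1e3, k9 = 1e3, C = 1)
  vars <- paste0("y", 1:5)
  expect_equal(constraint_dimension(list(g1), vars, pars), 4)
  expect_equal(constraint_dimension(list(g1, g2), vars, pars), 3)
  expect_equal(constraint_dimension(list(g1, g2, g3), vars, pars), 2)
  # a redundant constraint (twice the conservation law) does not reduce further
  g3b <- sp_scale(g3, 2)
  expect_equal(constraint_dimension(list(g1, g2, g3, g3b), vars, pars), 2)
})
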