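# Network data model, stoichiometry, rates, conservation laws and I/O.

test_that("the enzymatic mechanism is encoded with the expected structure", {
  mm <- build_michaelis_menten(k1 = 1, km1 = 1, k2 = 2, Etot = 1, Stot = 10)
  net <- mm$mechanism
  expect_equal(n_species(net), 4)
  expect_equal(n_reactions(net), 2)
  expect_true(net$reactions[[1]]$reversible)
  expect_false(net$reactions[[2]]$reversible)
  S <- stoichiometric_matrix(net)
  expect_equal(unname(S[, 1]), c(-1, -1, 1, 0))   # S, E, ES, P
  expect_equal(unname(S[, 2]), c(0, 1, -1, 1))
})

test_that("mass-action rates match hand evaluation", {
  mm <- build_michaelis_menten(k1 = 1, km1 = 1, k2 = 2, Etot = 3, Stot = 10)
  cc <- c(S = 2, E = 3, ES = 1, P = 0)
  rates <- reaction_rates(mm$mechanism, cc)
  expect_equal(rates[[1]], 2 * 3 - 1)      # k1*S*E - km1*ES = 5
  expect_equal(rates[[2]], 2 * 1)          # irreversible: forward only
  expect_equal(unname(reaction_rates(mm$mechanism, c(S = 1, E = 1, ES = 1, P = 1))),
               c(1 - 1, 2))                # unit concentrations: kf - kr
  expect_error(reaction_rates(mm$mechanism, c(S = -1, E = 1, ES = 1, P = 1)),
               "negative")
})

test_that("rhs equals stoichiometric matrix times net rates on random networks", {
  for (seed in 1:5) {
    net <- random_crn(n = 4, r = 5, seed = seed)
    S <- stoichiometric_matrix(net)
    field <- crn_rhs(net)
    for (rep in 1:5) {
      cc <- stats::setNames(runif(4, 0.1, 3), net$species$id)
      v1 <- eval_rhs(field, cc)
      v2 <- as.numeric(S %*% reaction_rates(net, cc))
      expect_lt(max(abs(v1 - v2)), 1e-12 * max(1, max(abs(v2))))
    }
  }
})

test_that("degenerate and empty networks are handled", {
  # self-loop reaction has a zero stoichiometric column
  sp <- species_table("A", initial = 1)
  net <- crn(sp, list(reaction("r", c(A = 1L), c(A = 1L), kf = 1)))
  expect_equal(unname(stoichiometric_matrix(net)[, 1]), 0L)
  # empty network loads without error
  tf <- tempfile(fileext = ".tsv")
  empty <- crn(species_table(character(0)), list(), numeric(0))
  write_crn_native(empty, tf)
  net2 <- read_crn_native(tf)
  expect_equal(n_species(net2), 0)
  expect_equal(n_reactions(net2), 0)
})

test_that("conservation laws span the left kernel and prefer non-negative form", {
  mm <- build_michaelis_menten()
  laws <- conservation_laws(mm$mechanism)
  expect_equal(ncol(laws), 2)
  expect_true(all(t(laws) %*% stoichiometric_matrix(mm$mechanism) == 0))
  keys <- apply(laws != 0, 2, function(z) paste(rownames(laws)[z], collapse = "+"))
  expect_setequal(keys, c("E+ES", "S+ES+P"))
  # single reaction A -> B conserves A + B
  net <- crn(species_table(c("A", "B"), initial = c(1, 0)),
             list(reaction("r", c(A = 1L), c(B = 1L), kf = 1)))
  expect_equal(unname(conservation_laws(net)[, 1]), c(1, 1))
  # random networks: dimension equals n - rank(S)
  for (seed in 1:5) {
    net <- random_crn(4, 5, seed)
    S <- stoichiometric_matrix(net)
    laws <- conservation_laws(net)
    expect_equal(ncol(laws), nrow(S) - qr(S)$rank)
    if (ncol(laws)) expect_true(all(t(laws) %*% S == 0))
  }
})

test_that("conserved totals stay constant along trajectories", {
  net <- generate_separated_monomolecular(5, 7, eps = 0.2, seed = 3)
  traj <- integrate_full(net, horizon = 100)
  expect_lt(max(abs(rowSums(traj$conc) - 1)), 1e-6)
})

test_that("eliminating E and P reproduces the two-variable balance equations", {
  mm <- build_michaelis_menten(k1 = 2, km1 = 3, k2 = 5, Etot = 0.5, Stot = 4)
  f2 <- mm$reduced_field
  expect_setequal(f2$species, c("S", "ES"))
  # term-by-term: dS/dt = -k1 Etot S + k1 S ES + km1 ES
  pS <- rhs_spoly(f2, "S")
  target_S <- sp_add(sp_add(sp_mono(-1, c(k1 = 1, Etot = 1, S = 1)),
                            sp_mono(1, c(k1 = 1, S = 1, ES = 1))),
                     sp_mono(1, c(km1 = 1, ES = 1)))
  expect_true(sp_equal(pS, target_S))
  pES <- rhs_spoly(f2, "ES")
  target_ES <- sp_add(sp_add(sp_mono(1, c(k1 = 1, Etot = 1, S = 1)),
                             sp_mono(-1, c(k1 = 1, S = 1, ES = 1))),
                      sp_add(sp_mono(-1, c(km1 = 1, ES = 1)),
                             sp_mono(-1, c(k2 = 1, ES = 1))))
  expect_true(sp_equal(pES, target_ES))
  # numeric consistency with the full mechanism on the conservation slice
  cc4 <- c(S = 2, E = 0.5 - 0.2, ES = 0.2, P = 1)
  v4 <- eval_rhs(crn_rhs(mm$mechanism), cc4)
  v2 <- eval_rhs(f2, c(S = 2, ES = 0.2))
  expect_equal(v4[["S"]], v2[["S"]], tolerance = 1e-12)
  expect_equal(v4[["ES"]], v2[["ES"]], tolerance = 1e-12)
})

test_that("native format round-trips field by field", {
  net <- build_michaelis_menten(k1 = 2, km1 = 3, k2 = 5, Etot = 0.5, Stot = 4)$mechanism
  tf <- tempfile(fileext = ".tsv")
  write_crn_native(net, tf)
  net2 <- read_crn_native(tf)
  expect_equal(net2$species, net$species)
  expect_equal(net2$parameters, net$parameters)
  for (j in seq_along(net$reactions)) {
    expect_equal(net2$reactions[[j]]$reactants, net$reactions[[j]]$reactants)
    expect_equal(net2$reactions[[j]]$products, net$reactions[[j]]$products)
    expect_equal(net2$reactions[[j]]$kf, net$reactions[[j]]$kf)
    expect_equal(net2$reactions[[j]]$kr, net$reactions[[j]]$kr)
    expect_equal(net2$reactions[[j]]$reversible, net$reactions[[j]]$reversible)
  }
})

test_that("reaction side parsing handles multiplicities", {
  s <- parse_side("2 A + B")
  expect_equal(s, c(A = 2L, B = 1L))
  expect_equal(length(parse_side("0")), 0)
})

test_that("the SBML reader handles the mass-action subset and rejects the rest", {
  path <- system.file("extdata", "michaelis_menten_synthetic.xml", package = "crnreduce")
  net <- load_network(path)
  expect_equal(n_species(net), 4)
  expect_equal(n_reactions(net), 2)
  expect_true(net$reactions[[1]]$reversible)
  expect_equal(net$parameters[["k1"]], 2)
  expect_equal(net$reactions[[1]]$kf, 2)
  expect_equal(net$reactions[[1]]$kr, 3)
  S <- stoichiometric_matrix(net)
  expect_equal(unname(S[c("S", "E", "ES", "P"), "binding"]), c(-1, -1, 1, 0))
  # round-trip through the SBML writer
  tf <- tempfile(fileext = ".xml")
  write_crn_sbml(net, tf)
  net2 <- read_crn_sbml(tf)
  expect_equal(stoichiometric_matrix(net2), S)
  expect_equal(net2$reactions[[1]]$kf, net$reactions[[1]]$kf)
  # a Hill-type kinetic law must fail loudly, naming the reaction
  bad <- readLines(path)
  bad <- sub("<ci>k2</ci>", "<apply><divide/><ci>k2</ci><ci>ES</ci></apply>", bad)
  tf2 <- tempfile(fileext = ".xml")
  writeLines(bad, tf2)
  expect_error(read_crn_sbml(tf2), "catalysis")
})
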