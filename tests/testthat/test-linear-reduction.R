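# Graph-rewriting reduction of monomolecular networks and its spectral
# approximation.

test_that("rank labels order constants with rank 1 on the quickest reaction", {
  sp <- species_table(paste0("A", 1:3), initial = c(1, 0, 0))
  net <- crn(sp, list(reaction("r1", c(A1 = 1L), c(A2 = 1L), kf = 10),
                      reaction("r2", c(A1 = 1L), c(A3 = 1L), kf = 1)))
  g <- rank_label(net)
  ranks <- stats::setNames(vapply(g$edges, `[[`, 0L, "rank"),
                           vapply(g$edges, `[[`, "", "to"))
  expect_equal(ranks[["A2"]], 1L)
  expect_equal(ranks[["A3"]], 2L)
})

test_that("random constants eps^perm are ranked by the inverse permutation", {
  for (seed in 1:5) {
    net <- generate_separated_monomolecular(6, 9, eps = 0.1, seed = seed)
    g <- rank_label(net)
    ks <- vapply(g$edges, function(e) exp(e$logk), 0)
    ranks <- vapply(g$edges, `[[`, 0L, "rank")
    expect_equal(ranks, rank(-ks))  # sort oracle
  }
})

test_that("exactly equal constants raise a tie error", {
  sp <- species_table(paste0("A", 1:3), initial = c(1, 0, 0))
  net <- crn(sp, list(reaction("r1", c(A1 = 1L), c(A2 = 1L), kf = 2),
                      reaction("r2", c(A1 = 1L), c(A3 = 1L), kf = 2)))
  expect_error(rank_label(net), "tie")
  expect_error(reaction(1, c(A1 = 0L), c(A1 = 0L), kf = 1), "stoichiometric")
})

# draw a separated random network whose reduction needs no tie-breaking:
# rank constants eps^pi(e) are totally separated, but derived cycle monomials
# can still collide (equal rank sums), which is outside the theory's
# total-separation premise and raises a tie error by design
tie_free_network <- function(seed, eps, n_range = 4:8) {
  repeat {
    set.seed(seed)
    n <- sample(n_range, 1); m <- sample(n:min(2 * n, n * (n - 1)), 1)
    net <- generate_separated_monomolecular(n, m, eps = eps, seed = seed)
    r <- tryCatch(reduce_monomolecular(rank_label(net)), error = function(e) NULL)
    if (!is.null(r)) return(list(net = net, reduced = r))
    seed <- seed + 1000
  }
}

test_that("rule a prunes all but the fastest outgoing edge", {
  sp <- species_table(paste0("A", 1:3), initial = c(1, 0, 0))
  net <- crn(sp, list(reaction("r1", c(A1 = 1L), c(A2 = 1L), kf = 10),
                      reaction("r2", c(A1 = 1L), c(A3 = 1L), kf = 1)))
  r <- reduce_monomolecular(rank_label(net))
  expect_equal(length(r$edges), 1)
  expect_equal(r$edges[[1]]$to, "A2")
})

test_that("an isolated cycle is cut at its slowest step", {
  sp <- species_table(paste0("A", 1:3), initial = c(1, 0, 0))
  net <- crn(sp, list(reaction("r1", c(A1 = 1L), c(A2 = 1L), kf = 1),
                      reaction("r2", c(A2 = 1L), c(A3 = 1L), kf = 0.1),
                      reaction("r3", c(A3 = 1L), c(A1 = 1L), kf = 1e-3)))
  r <- reduce_monomolecular(rank_label(net))
  pairs <- vapply(r$edges, function(e) paste(e$from, e$to), "")
  expect_setequal(pairs, c("A1 A2", "A2 A3"))  # slowest step A3 -> A1 removed
})

test_that("a cycle with a slow exit is glued and renormalized to k5*k4/k3", {
  net <- glued_cycle_network(k6 = 1e-2)
  r <- reduce_monomolecular(rank_label(net))
  rec <- r$glue_records[[1]]
  expect_setequal(rec$cycle, c("A2", "A3", "A4"))
  expect_equal(rec$limit_node, "A4")
  # quasi-stationary weight of the exit node A3 is the monomial k4/k3
  expect_equal(rec$weights$A3, c(k4 = 1, k3 = -1))
  # final digraph: chain A5 -> A2 -> A3 -> A4 (the k5 k4 / k3 edge lost the
  # outer-cycle comparison against k6)
  pairs <- vapply(r$edges, function(e) paste(e$from, e$to), "")
  expect_setequal(pairs, c("A5 A2", "A2 A3", "A3 A4"))
})

test_that("the glued exit edge survives and re-attaches from the limiting node", {
  net <- glued_cycle_network(k6 = 1e-12)  # now k6 loses against k5*k4/k3
  r <- reduce_monomolecular(rank_label(net))
  pairs <- vapply(r$edges, function(e) paste(e$from, e$to), "")
  expect_setequal(pairs, c("A2 A3", "A3 A4", "A4 A5"))
  e45 <- Filter(function(e) e$from == "A4", r$edges)[[1]]
  expect_equal(e45$mono[order(names(e45$mono))],
               c(k3 = -1, k4 = 1, k5 = 1)[order(names(c(k3 = -1, k4 = 1, k5 = 1)))])
  expect_equal(exp(e45$logk), 1e-6 * 1e-4 / 1e-1, tolerance = 1e-12)
  ep <- effective_parameters(r)
  expect_true("k5*k4*k3^-1" %in% ep$expression || "k4*k5*k3^-1" %in% ep$expression ||
              any(grepl("k3\\^-1", ep$expression)))
})

test_that("reduction output is acyclic and deterministic on random networks", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:8, 1); m <- sample(n:min(2 * n, n * (n - 1)), 1)
    net <- generate_separated_monomolecular(n, m, eps = 0.05, seed = seed)
    r <- tryCatch(reduce_monomolecular(rank_label(net)),
                  error = function(e) reduce_monomolecular(rank_label(net), "perturb"))
    from <- vapply(r$edges, `[[`, "", "from")
    expect_false(anyDuplicated(from) > 0)
    expect_equal(length(crnreduce:::.cycles_det(r$nodes, r$edges)), 0)
    expect_setequal(r$nodes, net$species$id)
  }
})

test_that("a single reaction relaxes as one exponential", {
  sp <- species_table(c("A1", "A2"), initial = c(1, 0))
  net <- crn(sp, list(reaction("r", c(A1 = 1L), c(A2 = 1L), kf = 0.7)))
  g <- rank_label(net)
  times <- seq(0, 10, length.out = 50)
  tr <- exact_solution(g, times = times)
  expect_equal(tr$conc[, "A1"], exp(-0.7 * times), tolerance = 1e-10)
  expect_equal(tr$conc[, "A2"], 1 - exp(-0.7 * times), tolerance = 1e-10)
})

test_that("a separated 3-chain has eigenvalues near 0, -k1, -k2", {
  sp <- species_table(paste0("A", 1:3), initial = c(1, 0, 0))
  net <- crn(sp, list(reaction("r1", c(A1 = 1L), c(A2 = 1L), kf = 1),
                      reaction("r2", c(A2 = 1L), c(A3 = 1L), kf = 1e-3)))
  ev <- sort(eigen(kinetic_matrix(rank_label(net)))$values)
  expect_equal(ev[1], -1, tolerance = 2e-3)
  expect_equal(ev[2], -1e-3, tolerance = 2e-3)
  expect_equal(ev[3], 0, tolerance = 1e-12)
})

test_that("eigen solution matches the matrix-exponential oracle", {
  net <- generate_separated_monomolecular(5, 7, eps = 0.2, seed = 9)
  g <- rank_label(net)
  times <- exp(seq(log(0.01), log(1e5), length.out = 60))
  tr <- exact_solution(g, times = times)
  K <- kinetic_matrix(g)
  oracle <- t(vapply(times, function(t)
    as.numeric(crnreduce:::.expm_mat(K, t) %*% g$initial[g$nodes]),
    numeric(5)))
  expect_lt(max(abs(tr$conc - oracle)), 1e-8)
})

test_that("the log-space eigen oracle matches dense eigen where both work", {
  net <- generate_separated_monomolecular(6, 8, eps = 0.05, seed = 4)
  g <- rank_label(net)
  ev1 <- sort(Re(eigen(kinetic_matrix(g))$values))
  ev2 <- sort(eigenvalues_separated(g))
  expect_equal(ev1, ev2, tolerance = 1e-6)
})

test_that("spectral approximation of a 2-chain is exact", {
  sp <- species_table(c("A1", "A2"), initial = c(1, 0))
  net <- crn(sp, list(reaction("r", c(A1 = 1L), c(A2 = 1L), kf = 0.5)))
  r <- reduce_monomolecular(rank_label(net))
  ap <- spectral_approximation(r)
  expect_equal(ap$eigenvalues, -0.5)
  expect_equal(unname(ap$left[1, ]), c(1, 0))
  expect_equal(unname(ap$right[1, ]), c(-1, 1))  # donor A1, receiver A2
  ss <- single_step_approximations(r)
  expect_equal(ss$donor, "A1")
  expect_equal(ss$receiver, "A2")
  expect_equal(ss$timescale, 2)
})

test_that("each approximate eigenvalue is close to an exact one at strong separation", {
  for (seed in c(2, 5, 8)) {
    tf <- tie_free_network(seed, eps = 1e-3, n_range = 4:7)
    ev <- eigenvalues_separated(rank_label(tf$net))
    for (e in tf$reduced$edges) {
      k <- exp(e$logk)
      expect_lt(min(abs(ev + k) / k), 0.05)
    }
  }
})

test_that("exact eigenvectors approach the 0-1 form at strong separation", {
  tf <- tie_free_network(12, eps = 1e-3, n_range = 5:6)
  r <- tf$reduced
  ap <- spectral_approximation(r)
  eg <- eigen(kinetic_matrix(rank_label(tf$net)))
  checked <- 0
  for (i in seq_along(ap$eigenvalues)) {
    lam <- ap$eigenvalues[i]
    if (abs(lam) < 1e-12) next  # below dense-eigen resolution
    j <- which.min(abs(Re(eg$values) - lam))
    v <- Re(eg$vectors[, j])[match(colnames(ap$right), rownames(eg$vectors))]
    if (is.null(rownames(eg$vectors))) v <- Re(eg$vectors[, j])
    donor <- match(ap$edges$donor[i], colnames(ap$right))
    v <- -v / v[donor]   # canonical form: -1 at the donor coordinate
    expect_lt(max(abs(v - ap$right[i, ])), 0.1)
    checked <- checked + 1
  }
  expect_gt(checked, 0)
})

test_that("single-step approximations are ordered quick to slow and consistent", {
  net <- glued_cycle_network()
  r <- reduce_monomolecular(rank_label(net))
  ss <- single_step_approximations(r)
  expect_false(is.unsorted(ss$timescale))
  # every donor pool contains its donor, and receivers are reachable sinks
  for (i in seq_len(nrow(ss))) {
    pool <- strsplit(ss$pool[i], ",")[[1]]
    expect_true(ss$donor[i] %in% pool)
  }
})

test_that("trajectory error of the reduced digraph shrinks with separation", {
  errs <- vapply(c(1e-1, 1e-2), function(eps) {
    net <- generate_separated_monomolecular(6, 8, eps = eps, seed = 21)
    g <- rank_label(net)
    r <- tryCatch(reduce_monomolecular(g),
                  error = function(e) reduce_monomolecular(g, "perturb"))
    kmax <- max(vapply(g$edges, function(e) exp(e$logk), 0))
    kmin <- min(vapply(r$edges, function(e) exp(e$logk), 1))
    times <- exp(seq(log(0.01 / kmax), log(10 / kmin), length.out = 60))
    traj_sup_error(linear_solution_multiscale(g, times = times),
                   linear_solution_multiscale(r, times = times))
  }, 0)
  expect_lt(errs[2], errs[1])
})

test_that("DOT export writes one labeled edge per reaction", {
  net <- glued_cycle_network()
  tf <- tempfile(fileext = ".dot")
  export_dot(rank_label(net), tf)
  txt <- readLines(tf)
  expect_equal(sum(grepl("->", txt)), 5)
  expect_true(any(grepl("k5", txt)))
})
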