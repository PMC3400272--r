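# Multiscale reduction of monomolecular reaction networks.
#
# A monomolecular network is a digraph with one rate constant per edge. With
# totally separated constants it reduces to an acyclic deterministic digraph
# (every out-degree <= 1) by three rewriting rules:
#   rule a - at every node keep only the fastest outgoing edge;
#   rule b - cut a cycle by removing its slowest (limiting) step;
#   rule c - when a cycle has slow outgoing reactions, glue it into a single
#     node; outgoing constants are renormalized by the cycle's normalized
#     quasi-stationary distribution, which in the totally separated limit is
#     the monomial k_lim / k_i at node i (k_lim = slowest intra-cycle exit).
# Gluing iterates with pruning until the pruned system is acyclic; glued
# cycles are then restored in reverse order and cut. On restoration the
# surviving outgoing edge of a glued node is re-attached from the cycle's
# limiting node (the node carrying the quasi-stationary mass), which keeps
# the digraph deterministic and the relaxation timescales correct.
#
# All renormalized constants are carried as exact integer-exponent monomials
# over the original constants; dominance comparisons happen on log-values.

#' Rank-label a monomolecular network
#'
#' Builds the labeled digraph of a monomolecular network: every edge carries
#' its constant and an integer rank, rank 1 for the largest constant (the
#' quickest reaction).
#'
#' @param net a \code{crn} whose reactions all have one reactant and one
#'   product with unit stoichiometry (reversible reactions give two edges).
#' @param drop_self_loops drop reactions A -> A (they have no dynamical
#'   effect); otherwise they are an error.
#' @return object of class \code{labeled_digraph}.
#' @export
rank_label <- function(net, drop_self_loops = TRUE) {
  edges <- list()
  for (rx in net$reactions) {
    if (length(rx$reactants) != 1 || length(rx$products) != 1 ||
        rx$reactants[[1]] != 1 || rx$products[[1]] != 1)
      stop("reaction ", rx$id, " is not monomolecular")
    from <- names(rx$reactants); to <- names(rx$products)
    if (from == to) {
      if (drop_self_loops) next
      stop("reaction ", rx$id, " is a self-loop")
    }
    mono <- if (!is.null(rx$kf_par)) rx$kf_par else stats::setNames(1, paste0(".k_", rx$id))
    edges[[length(edges) + 1L]] <- list(from = from, to = to, mono = mono, id = rx$id)
    if (rx$reversible) {
      monob <- if (!is.null(rx$kr_par)) rx$kr_par else stats::setNames(1, paste0(".kr_", rx$id))
      edges[[length(edges) + 1L]] <- list(from = to, to = from, mono = monob,
                                          id = paste0(rx$id, "_rev"))
    }
  }
  logp <- log(net$parameters)
  # anonymous numeric constants get synthetic symbols
  for (e in edges) for (nm in names(e$mono)) {
    if (!nm %in% names(logp)) {
      rid <- sub("^\\.kr?_", "", nm)
      rx <- Filter(function(r) r$id == rid, net$reactions)[[1]]
      logp[nm] <- log(if (startsWith(nm, ".kr_")) rx$kr else rx$kf)
    }
  }
  pair <- vapply(edges, function(e) paste(e$from, e$to, sep = "->"), "")
  if (anyDuplicated(pair)) stop("parallel edges: ", pair[duplicated(pair)][1])
  lk <- vapply(edges, function(e) sum(e$mono * logp[names(e$mono)]), 0)
  o <- order(lk, decreasing = TRUE)
  if (any(diff(lk[o]) == 0)) {
    i <- which(diff(lk[o]) == 0)[1]
    stop("tie between constants of edges ", pair[o[i]], " and ", pair[o[i + 1]])
  }
  rank <- integer(length(edges)); rank[o] <- seq_along(edges)
  for (i in seq_along(edges)) { edges[[i]]$logk <- lk[i]; edges[[i]]$rank <- rank[i] }
  structure(list(nodes = net$species$id, edges = edges, logp = logp,
                 initial = stats::setNames(net$species$initial, net$species$id)),
            class = "labeled_digraph")
}

#' @export
print.labeled_digraph <- function(x, ...) {
  cat("Labeled monomolecular digraph:", length(x$nodes), "nodes,",
      length(x$edges), "edges\n")
  for (e in x$edges[order(vapply(x$edges, `[[`, 0L, "rank"))])
    cat(sprintf("  [%d] %s -> %s  k = %s = %.3g\n", e$rank, e$from, e$to,
                .mono_str(e$mono), exp(e$logk)))
  invisible(x)
}

.nth_primes <- function(n) {
  out <- integer(0); x <- 1L
  while (length(out) < n) {
    x <- x + 1L
    if (all(x %% out[out <= sqrt(x)] != 0)) out <- c(out, x)
  }
  out
}

.mono_str <- function(mono) {
  mono <- mono[mono != 0]
  if (length(mono) == 0) return("1")
  paste(ifelse(mono == 1, names(mono), paste0(names(mono), "^", mono)), collapse = "*")
}

.mono_add <- function(a, b) {
  out <- a
  for (nm in names(b)) out[nm] <- (if (nm %in% names(out)) out[[nm]] else 0) + b[[nm]]
  out[out != 0]
}

.mono_sub <- function(a, b) .mono_add(a, -b)

.edge_logk <- function(mono, logp) sum(mono * logp[names(mono)])

# functional-digraph pruning: keep the fastest outgoing edge per node
.prune <- function(edges) {
  if (length(edges) == 0) return(edges)
  from <- vapply(edges, `[[`, "", "from")
  keep <- logical(length(edges))
  for (f in unique(from)) {
    idx <- which(from == f)
    lk <- vapply(edges[idx], `[[`, 0, "logk")
    if (length(idx) > 1 && sum(lk == max(lk)) > 1)
      stop("tie between constants of outgoing edges of ", f)
    keep[idx[which.max(lk)]] <- TRUE
  }
  edges[keep]
}

# cycles of a deterministic (out-degree <= 1) digraph; returns list of node
# vectors in cycle order
.cycles_det <- function(nodes, edges) {
  nxt <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  for (e in edges) nxt[e$from] <- e$to
  color <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 active, 2 done
  cycles <- list()
  for (s in nodes) {
    if (color[s] != 0L) next
    path <- character(0); u <- s
    while (!is.na(u) && color[u] == 0L) {
      color[u] <- 1L; path <- c(path, u); u <- nxt[u]
    }
    if (!is.na(u) && color[u] == 1L) {
      i <- match(u, path)
      cycles[[length(cycles) + 1L]] <- path[i:length(path)]
    }
    color[path] <- 2L
  }
  cycles
}

.is_acyclic <- function(nodes, edges) length(.cycles_det(nodes, edges)) == 0

#' Reduce a monomolecular labeled digraph to an acyclic deterministic digraph
#'
#' Applies pruning (rule a), hierarchical cycle gluing with quasi-stationary
#' renormalization (rule c) and cycle cutting at the limiting step (rule b)
#' until the network is an acyclic deterministic digraph. Edge constants of
#' the result are exact monomials over the original constants.
#'
#' @param g a \code{labeled_digraph} from [rank_label()].
#' @param tie_break \code{"error"} (default; the theory assumes total
#'   separation) or \code{"perturb"}: multiply the original constants by
#'   distinct factors close to 1 to break accidental ties between derived
#'   monomials, with a warning.
#' @return object of class \code{reduced_linear}: acyclic deterministic
#'   digraph with monomial edge constants and a provenance record of every
#'   rewriting step.
#' @export
reduce_monomolecular <- function(g, tie_break = c("error", "perturb")) {
  tie_break <- match.arg(tie_break)
  logp <- g$logp
  if (tie_break == "perturb") {
    # multiply constant i by exp(eta * log(prime_i)): log-primes are linearly
    # independent over the rationals, so two distinct integer-exponent
    # monomials can never stay tied after perturbation
    logp <- logp + 1e-9 * log(.nth_primes(length(logp)))
  }
  W <- lapply(g$edges, function(e) { e$logk <- .edge_logk(e$mono, logp); e })
  nodes <- g$nodes
  glue_stack <- list()
  prov <- list()
  gi <- 0L
  repeat {
    P <- .prune(W)
    cyc <- .cycles_det(nodes, P)
    if (length(cyc) == 0) break
    # membership map for this round's cycles
    memb <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
    for (ci in seq_along(cyc)) memb[cyc[[ci]]] <- ci
    gids <- character(length(cyc))
    records <- vector("list", length(cyc))
    for (ci in seq_along(cyc)) {
      gi <- gi + 1L
      gids[ci] <- paste0(".glue", gi)
      C <- cyc[[ci]]
      # intra-cycle exit edges (from the pruned system)
      intra <- Filter(function(e) e$from %in% C, P)
      names(intra) <- vapply(intra, `[[`, "", "from")
      lk <- vapply(intra, `[[`, 0, "logk")
      if (sum(lk == min(lk)) > 1)
        stop("tie between constants of the limiting step candidates in cycle ",
             paste(C, collapse = "->"), " (",
             paste(names(lk)[lk == min(lk)], collapse = ", "), ")")
      lim <- names(intra)[which.min(lk)]
      wts <- lapply(C, function(u) .mono_sub(intra[[lim]]$mono, intra[[u]]$mono))
      names(wts) <- C
      records[[ci]] <- list(id = gids[ci], cycle = C, intra = intra,
                            limit_node = lim, weights = wts)
      prov[[length(prov) + 1L]] <- list(op = "glue", node = gids[ci], cycle = C,
                                        limit_node = lim)
    }
    # transform the full current network
    newW <- list()
    addW <- function(e) newW[[length(newW) + 1L]] <<- e
    for (e in W) {
      ci_f <- memb[[e$from]]; ci_t <- memb[[e$to]]
      if (!is.na(ci_f) && !is.na(ci_t) && ci_f == ci_t) {
        next  # reaction inside a glued cycle vanishes
      }
      e2 <- e
      if (!is.na(ci_f)) {
        # outgoing reaction: renormalize by the quasi-stationary weight
        rec <- records[[ci_f]]
        e2$mono <- .mono_add(e$mono, rec$weights[[e$from]])
        e2$logk <- .edge_logk(e2$mono, logp)
        e2$orig_from <- e$from
        e2$from <- rec$id
      }
      if (!is.na(ci_t)) {
        e2$orig_to <- if (is.null(e2$orig_to)) e$to else e2$orig_to
        e2$to <- gids[ci_t]
      }
      addW(e2)
    }
    # collapse parallel edges (keep the dominant one)
    if (length(newW)) {
      pr <- vapply(newW, function(e) paste(e$from, e$to, sep = "->"), "")
      keep <- logical(length(newW))
      for (p in unique(pr)) {
        idx <- which(pr == p)
        lk <- vapply(newW[idx], `[[`, 0, "logk")
        if (length(idx) > 1 && sum(lk == max(lk)) > 1)
          stop("tie between parallel edge constants into ", p)
        keep[idx[which.max(lk)]] <- TRUE
      }
      newW <- newW[keep]
    }
    nodes <- c(setdiff(nodes, unlist(cyc)), gids)
    glue_stack <- c(glue_stack, records)
    W <- newW
  }
  R <- .prune(W)
  pruned_ids <- vapply(R, function(e) paste(e$from, e$to, sep = "->"), "")
  prov[[length(prov) + 1L]] <- list(op = "prune", kept = pruned_ids)
  # restore glued cycles in reverse order, cutting each at the limiting step
  for (rec in rev(glue_stack)) {
    out_idx <- which(vapply(R, function(e) identical(e$from, rec$id), TRUE))
    in_idx <- which(vapply(R, function(e) identical(e$to, rec$id), TRUE))
    if (length(out_idx) > 1) stop("internal: glued node with out-degree > 1")
    for (i in in_idx) {
      R[[i]]$to <- R[[i]]$orig_to
      R[[i]]$orig_to <- NULL
    }
    # cycle chain: all intra-cycle exit edges except the limiting step
    for (u in rec$cycle) {
      if (u == rec$limit_node) next
      R[[length(R) + 1L]] <- rec$intra[[u]]
    }
    if (length(out_idx) == 1) {
      # re-attach the surviving outgoing edge from the limiting node
      R[[out_idx]]$from <- rec$limit_node
      prov[[length(prov) + 1L]] <- list(op = "restore_cut", node = rec$id,
                                        cut = rec$limit_node,
                                        attach = .mono_str(R[[out_idx]]$mono))
    } else {
      prov[[length(prov) + 1L]] <- list(op = "restore_cut", node = rec$id,
                                        cut = rec$limit_node, attach = NA_character_)
    }
    nodes <- c(setdiff(nodes, rec$id), rec$cycle)
  }
  nodes <- g$nodes[g$nodes %in% nodes]  # original declaration order
  stopifnot(.is_acyclic(nodes, R))
  from <- vapply(R, `[[`, "", "from")
  stopifnot(!anyDuplicated(from))
  structure(list(nodes = nodes, edges = R, logp = logp,
                 glue_records = glue_stack, provenance = prov,
                 initial = g$initial, perturbed = tie_break == "perturb"),
            class = "reduced_linear")
}

#' @export
print.reduced_linear <- function(x, ...) {
  cat("Reduced acyclic deterministic digraph:", length(x$nodes), "nodes,",
      length(x$edges), "edges\n")
  for (e in x$edges[order(vapply(x$edges, `[[`, 0, "logk"), decreasing = TRUE)])
    cat(sprintf("  %s -> %s  k = %s = %.3g\n", e$from, e$to,
                .mono_str(e$mono), exp(e$logk)))
  cat(length(x$glue_records), "cycle gluings;", length(x$provenance),
      "rewriting steps recorded\n")
  invisible(x)
}

#' Kinetic matrix of a monomolecular digraph
#'
#' K[j, i] = k(i -> j) off-diagonal; K[i, i] = minus the total outgoing
#' constant, so dc/dt = K c.
#'
#' @param g a \code{labeled_digraph} or \code{reduced_linear}.
#' @return numeric matrix with species dimnames.
#' @export
kinetic_matrix <- function(g) {
  n <- length(g$nodes)
  K <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  for (e in g$edges) {
    k <- exp(e$logk)
    K[e$to, e$from] <- K[e$to, e$from] + k
    K[e$from, e$from] <- K[e$from, e$from] - k
  }
  K
}

#' Exact solution of a monomolecular network
#'
#' Solves dc/dt = K c by eigendecomposition; if the kinetic matrix is close
#' to defective, falls back to a matrix-exponential computed by scaling and
#' squaring, flagged in the result.
#'
#' @param g a \code{labeled_digraph} or \code{reduced_linear}.
#' @param c0 initial concentrations (named or in node order; defaults to the
#'   network's initial concentrations).
#' @param times numeric time grid.
#' @return object of class \code{crn_trajectory}: \code{times}, \code{conc}
#'   (time x species matrix), \code{method}.
#' @export
exact_solution <- function(g, c0 = NULL, times) {
  K <- kinetic_matrix(g)
  n <- nrow(K)
  if (is.null(c0)) c0 <- g$initial[g$nodes]
  if (!is.null(names(c0))) c0 <- c0[g$nodes]
  c0 <- as.numeric(c0)
  eig <- eigen(K)
  method <- "eigen"
  rc <- tryCatch(rcond(eig$vectors), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-10) {
    method <- "expm"
    conc <- t(vapply(times, function(t) as.numeric(.expm_mat(K * t) %*% c0),
                     numeric(n)))
  } else {
    a <- solve(eig$vectors, c0)
    conc <- t(vapply(times, function(t) {
      Re(eig$vectors %*% (a * exp(eig$values * t)))
    }, numeric(n)))
  }
  colnames(conc) <- rownames(K)
  structure(list(times = times, conc = conc, method = method,
                 eigenvalues = if (method == "eigen") Re(eig$values) else NULL),
            class = "crn_trajectory")
}

# matrix exponential by scaling and squaring with a Taylor core; adequate for
# the small kinetic matrices handled here
.expm_mat <- function(A, t = 1) {
  # exp(A * t) with the scaling factor computed in logs, so arbitrarily large
  # t never overflows; squaring a compartmental propagator multiplies
  # non-negative matrices, which is cancellation-free and entrywise stable
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  lg <- log2(max(nrm, 1e-300)) + log2(max(t, 1e-300))
  s <- max(0L, ceiling(lg) + 2L)
  h <- exp(log(t) - s * log(2))
  As <- A * h
  X <- diag(n); term <- diag(n)
  for (k in 1:25) {
    term <- term %*% As / k
    X <- X + term
    if (max(abs(term)) < 1e-17) break
  }
  # mass-conserving kinetics: keep the unit eigenvalue exact, otherwise the
  # truncation error (1 - eps)^(2^s) annihilates the propagator at huge t
  conserving <- all(abs(colSums(A)) < 1e-9 * max(abs(A)))
  if (conserving) X <- sweep(X, 2, colSums(X), "/")
  for (i in seq_len(s)) {
    X <- X %*% X
    if (conserving) X <- sweep(X, 2, colSums(X), "/")
  }
  X
}

#' @export
print.crn_trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$times), "time points,", ncol(x$conc),
      "species (", x$method, ")\n")
  invisible(x)
}

#' 0-1 spectral approximation of a reduced acyclic deterministic digraph
#'
#' For totally separated constants, each remaining edge i -> j with constant
#' k carries one relaxation mode: eigenvalue -k, left eigenvector with
#' coordinates in \{0, 1\} marking the pool of species that drain through the
#' edge on faster timescales, and right eigenvector with a single -1 (the
#' donor i) and +1 (the receiver: the first species downstream of j that
#' relaxes more slowly, or the terminal sink).
#'
#' @param r a \code{reduced_linear}.
#' @return object of class \code{spectral_solution}: \code{eigenvalues}
#'   (non-positive, one per edge), matrices \code{left} and \code{right}
#'   (modes in rows), and \code{edges} (donor, receiver, timescale).
#' @export
spectral_approximation <- function(r) {
  nodes <- r$nodes
  nxt <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  kout <- stats::setNames(rep(-Inf, length(nodes)), nodes)
  for (e in r$edges) { nxt[e$from] <- e$to; kout[e$from] <- e$logk }
  m <- length(r$edges)
  ord <- order(vapply(r$edges, `[[`, 0, "logk"), decreasing = TRUE)
  edges <- r$edges[ord]
  L <- matrix(0, m, length(nodes), dimnames = list(NULL, nodes))
  R <- matrix(0, m, length(nodes), dimnames = list(NULL, nodes))
  info <- data.frame(donor = character(m), receiver = character(m),
                     timescale = numeric(m), constant = numeric(m),
                     stringsAsFactors = FALSE)
  for (idx in seq_len(m)) {
    e <- edges[[idx]]
    # left: nodes whose whole path to the donor is faster than this edge
    for (u in nodes) {
      v <- u; ok <- FALSE
      while (TRUE) {
        if (v == e$from) { ok <- TRUE; break }
        if (is.na(nxt[v]) || kout[v] <= e$logk) break
        v <- nxt[v]
      }
      if (ok) L[idx, u] <- 1
    }
    # right: -1 at the donor, +1 at the first slower (or terminal) node downstream
    v <- e$to
    while (!is.na(nxt[v]) && kout[v] > e$logk) v <- nxt[v]
    R[idx, e$from] <- -1
    R[idx, v] <- 1
    info$donor[idx] <- e$from
    info$receiver[idx] <- v
    info$constant[idx] <- exp(e$logk)
    info$timescale[idx] <- exp(-e$logk)
  }
  structure(list(eigenvalues = -info$constant, left = L, right = R,
                 edges = info, nodes = nodes), class = "spectral_solution")
}

#' @export
print.spectral_solution <- function(x, ...) {
  cat("0-1 spectral approximation:", length(x$eigenvalues), "relaxation modes\n")
  for (i in seq_along(x$eigenvalues)) {
    pool <- colnames(x$left)[x$left[i, ] == 1]
    cat(sprintf("  t=%.3g: pool {%s} -> %s\n", x$edges$timescale[i],
                paste(pool, collapse = ","), x$edges$receiver[i]))
  }
  invisible(x)
}

#' Successive single-step approximations of a reduced digraph
#'
#' On each of its timescales a monomolecular network with total separation
#' behaves as one effective reaction: the mode's donor pool empties into the
#' receiver. Entries are ordered from the quickest to the slowest timescale.
#'
#' @param r a \code{reduced_linear}.
#' @return data.frame with columns timescale, constant, donor, receiver,
#'   pool (comma-separated donor pool).
#' @export
single_step_approximations <- function(r) {
  sp <- spectral_approximation(r)
  pool <- vapply(seq_along(sp$eigenvalues), function(i)
    paste(colnames(sp$left)[sp$left[i, ] == 1], collapse = ","), "")
  data.frame(timescale = sp$edges$timescale, constant = sp$edges$constant,
             donor = sp$edges$donor, receiver = sp$edges$receiver,
             pool = pool, stringsAsFactors = FALSE)
}

#' Export a digraph in DOT format
#'
#' @param g a \code{labeled_digraph} or \code{reduced_linear}.
#' @param path output file.
#' @export
export_dot <- function(g, path) {
  lines <- c("digraph crn {")
  for (e in g$edges) {
    lab <- if (!is.null(e$rank)) sprintf("%s (#%d)", .mono_str(e$mono), e$rank)
           else .mono_str(e$mono)
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];', e$from, e$to, lab))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
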