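# Stochastic-thermodynamic layer: path products, cycle condition, detailed
# balance, equilibrium steady states, per-edge entropy change, and ligand
# conservation.

# forward/backward label ratio of one reversible edge pair, numeric
label_ratio <- function(g, from, to, x = NULL) {
  ef <- edge_id(g, from, to)
  eb <- edge_id(g, to, from)
  if (is.na(ef) || is.na(eb)) {
    lf_stop("IrreversibleStep",
            paste0("edge pair ", from, " <-> ", to, " is not reversible"),
            pair = c(from, to))
  }
  vals <- edge_values(g, x = x)
  vals[ef] / vals[eb]
}

#' Path product along a reversible path
#'
#' The product of forward/backward label ratios along a path of reversible
#' edges. It is multiplicative under concatenation and equals the
#' exponential of the total entropy change (in units of kB) along the path;
#' around a cycle it equals 1 exactly when no entropy is produced.
#'
#' @param g an `lf_graph` whose labels evaluate numerically.
#' @param path vertex sequence `i1, ..., ik`; consecutive pairs must be
#'   connected by edges in both directions.
#' @param x optional numeric input-symbol value.
#' @return numeric path product.
#' @export
path_product <- function(g, path, x = NULL) {
  path <- as.character(path)
  if (length(path) < 2) return(1)
  mu <- 1
  for (i in seq_len(length(path) - 1)) {
    mu <- mu * label_ratio(g, path[i], path[i + 1], x = x)
  }
  mu
}

# Fundamental cycle basis from a spanning tree of the undirected support:
# each non-tree undirected edge {a, b} closes the tree path b ~> a.
fundamental_cycles <- function(g) {
  und <- unique(t(apply(g$edges[, c("from", "to")], 1, sort)))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = und[, 1], to = und[, 2]), directed = FALSE,
    vertices = data.frame(name = g$vertices))
  tree <- igraph::mst(ig)
  tree_ends <- igraph::as_edgelist(tree)
  tree_key <- paste(pmin(tree_ends[, 1], tree_ends[, 2]),
                    pmax(tree_ends[, 1], tree_ends[, 2]), sep = "\r")
  all_key <- paste(pmin(und[, 1], und[, 2]), pmax(und[, 1], und[, 2]),
                   sep = "\r")
  chords <- und[!(all_key %in% tree_key), , drop = FALSE]
  lapply(seq_len(nrow(chords)), function(i) {
    a <- chords[i, 1]; b <- chords[i, 2]
    p <- igraph::shortest_paths(tree, from = b, to = a)$vpath[[1]]
    c(a, names(p))  # cycle a -> b ~tree~> a as vertex sequence
  })
}

#' Check the cycle condition (Wegscheider condition)
#'
#' A reversible graph can reach thermodynamic equilibrium exactly when the
#' product of edge labels clockwise equals the product counterclockwise
#' around every cycle of reversible edges. It suffices to check a
#' fundamental cycle basis built from one spanning tree of the undirected
#' support; the test is `|log mu(C)| < tol` for each basis cycle `C`, which
#' is symmetric in the direction of traversal.
#'
#' @param g a reversible, strongly connected `lf_graph`.
#' @param tol tolerance on `|log mu|` (default 1e-9).
#' @param x optional numeric input-symbol value (default 1 when the graph
#'   has an input symbol).
#' @return list with elements `ok` (logical) and `violating_cycle` (vertex
#'   sequence of the first failing basis cycle, or NULL).
#' @export
satisfies_cycle_condition <- function(g, tol = 1e-9, x = NULL) {
  if (!is_reversible(g)) {
    lf_stop("NotReversible", "graph is not reversible")
  }
  if (is.null(x) && !is.null(g$input_symbol)) x <- 1
  vals <- edge_values(g, x = x)
  if (max(vals) / min(vals) > 1e12) {
    lf_warn("IllConditionedLabels",
            "label ratios span more than 1e12; cycle check may be inaccurate")
  }
  for (cyc in fundamental_cycles(g)) {
    mu <- path_product(g, cyc, x = x)
    if (abs(log(mu)) >= tol) {
      return(list(ok = FALSE, violating_cycle = cyc))
    }
  }
  list(ok = TRUE, violating_cycle = NULL)
}

# Equilibrium basis mu_i relative to the reference vertex (the first
# declared vertex): path products along one spanning-tree path each. Well
# defined only under the cycle condition.
equilibrium_mu <- function(g, x = NULL) {
  ig <- as_igraph(g)
  ref <- g$vertices[1]
  paths <- igraph::shortest_paths(igraph::as_undirected(ig), from = ref)$vpath
  mu <- stats::setNames(numeric(n_vertices(g)), g$vertices)
  for (i in seq_along(paths)) {
    p <- names(paths[[i]])
    mu[i] <- path_product(g, p, x = x)
  }
  mu
}

#' Equilibrium steady state from label ratios
#'
#' At thermodynamic equilibrium the steady state depends only on the label
#' ratios: `u_i* = mu_i / (mu_1 + ... + mu_N) * u_tot`, where `mu_i` is the
#' path product from the reference vertex (the first declared vertex,
#' `mu_1 = 1`) to vertex `i` along any reversible path. The `mu_i` play the
#' role of Boltzmann factors and the denominator is the partition function.
#' Requires the cycle condition, which makes `mu_i` path independent.
#'
#' @param g a reversible, strongly connected `lf_graph` satisfying the
#'   cycle condition.
#' @param u_tot total mass (default 1).
#' @param tol tolerance forwarded to the cycle-condition check.
#' @param x optional numeric input-symbol value (default 1 if present).
#' @return named numeric steady state summing to `u_tot`.
#' @export
equilibrium_steady_state <- function(g, u_tot = 1, tol = 1e-9, x = NULL) {
  if (is.null(x) && !is.null(g$input_symbol)) x <- 1
  chk <- satisfies_cycle_condition(g, tol = tol, x = x)
  if (!chk$ok) {
    lf_stop("NotAtEquilibrium",
            paste0("cycle condition violated on cycle ",
                   paste(chk$violating_cycle, collapse = " -> ")),
            cycle = chk$violating_cycle)
  }
  mu <- equilibrium_mu(g, x = x)
  mu / sum(mu) * u_tot
}

#' Detailed-balance residuals
#'
#' For each unordered reversible pair `{i, j}` the flux imbalance
#' `r_ij = u_i l(i -> j) - u_j l(j -> i)` at the supplied state. All
#' residuals vanish exactly when the state is a thermodynamic-equilibrium
#' steady state.
#'
#' @param g a reversible `lf_graph`.
#' @param u named numeric state vector over the vertices.
#' @param x optional numeric input-symbol value.
#' @return data frame with columns `i`, `j`, `residual`.
#' @export
detailed_balance_residuals <- function(g, u, x = NULL) {
  if (!is_reversible(g)) {
    lf_stop("NotReversible", "graph is not reversible")
  }
  vals <- edge_values(g, x = x)
  pairs <- unique(t(apply(g$edges[, c("from", "to")], 1, sort)))
  u <- u[g$vertices]
  res <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    u[[i]] * vals[edge_id(g, i, j)] - u[[j]] * vals[edge_id(g, j, i)]
  }, numeric(1))
  data.frame(i = pairs[, 1], j = pairs[, 2], residual = res)
}

#' Entropy change across a reversible edge pair
#'
#' Local detailed balance identifies the log label ratio of a reversible
#' edge pair with the total entropy change (environment plus internal, in
#' units of kB) for the transition `i -> j`. The value is antisymmetric
#' under swapping `i` and `j`.
#'
#' @param g an `lf_graph`.
#' @param i,j vertices joined by edges in both directions.
#' @param x optional numeric input-symbol value.
#' @return total entropy change in units of kB (dimensionless).
#' @export
edge_entropy <- function(g, i, j, x = NULL) {
  log(label_ratio(g, as.character(i), as.character(j), x = x))
}

#' Solve the ligand conservation law
#'
#' When the input symbol is the free concentration of a ligand `L` that
#' binds to some vertices of the graph, total ligand is conserved:
#' `L_tot = [L] + sum over bound vertices of u_i*([L])`. The bound mass is
#' increasing and the free term is linear, so the closure has a unique root
#' which is found by monotone 1-D root finding.
#'
#' @param g a strongly connected `lf_graph` with an input symbol.
#' @param ligand_vertices vertices with ligand bound (each bound vertex
#'   counts one ligand; pass a vertex several times for multiple bound
#'   copies).
#' @param L_tot total ligand.
#' @param u_tot total graph mass.
#' @return list with `L_free` (the consistent free concentration) and
#'   `state` (the steady state at that concentration).
#' @export
solve_ligand_conservation <- function(g, ligand_vertices, L_tot, u_tot = 1) {
  if (is.null(g$input_symbol)) {
    lf_stop("NoInputSymbol", "graph has no input symbol")
  }
  ligand_vertices <- as.character(ligand_vertices)
  vertex_index(g, unique(ligand_vertices))
  if (u_tot == 0 || length(ligand_vertices) == 0) {
    return(list(L_free = L_tot,
                state = stats::setNames(rep(0, n_vertices(g)), g$vertices)))
  }
  bound_mass <- function(xx) {
    u <- steady_state(g, u_tot = u_tot, x = xx)
    sum(u[ligand_vertices])
  }
  h <- function(xx) xx + bound_mass(xx) - L_tot
  lo <- L_tot * 1e-12
  while (h(lo) > 0 && lo > L_tot * 1e-300) lo <- lo / 1e3
  if (h(lo) > 0 || h(L_tot) < 0) {
    lf_stop("NoRoot", "could not bracket the ligand conservation root",
            bracket = c(lo, L_tot), h = c(h(lo), h(L_tot)))
  }
  root <- stats::uniroot(h, c(lo, L_tot), tol = 1e-12 * max(1, L_tot))$root
  list(L_free = root, state = steady_state(g, u_tot = u_tot, x = root))
}
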