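# Spanning forests, rooted tree counts and the Matrix-Tree prescription for
# steady states.

#' Enumerate spanning forests rooted at a vertex set
#'
#' A spanning forest is a subgraph that spans all vertices, is acyclic when
#' edge directions are ignored, and gives each vertex at most one outgoing
#' edge; the vertices without an outgoing edge are exactly the roots. The
#' enumeration assigns each non-root vertex one of its outgoing edges in
#' turn, pruning any assignment whose pointer chain closes a cycle, so each
#' forest is generated exactly once.
#'
#' @param g an `lf_graph`.
#' @param roots nonempty vector of root vertices.
#' @return a list of forests (class `forest_set`); each forest is a data
#'   frame of directed edges with columns `from`, `to`.
#' @examples
#' g <- lf_graph(1:3, data.frame(from = c(1, 2, 3, 2, 3, 1),
#'                               to   = c(2, 3, 1, 1, 2, 3),
#'                               label = paste0("k", 1:6)))
#' length(enumerate_spanning_forests(g, roots = "1"))
#' @export
enumerate_spanning_forests <- function(g, roots) {
  roots <- as.character(roots)
  if (length(roots) == 0) {
    lf_stop("EmptyRootSet", "root set must be nonempty")
  }
  ri <- vertex_index(g, roots)
  n <- n_vertices(g)
  non_roots <- setdiff(seq_len(n), ri)
  fi <- match(g$edges$from, g$vertices)
  ti <- match(g$edges$to, g$vertices)
  out_edges <- lapply(seq_len(n), function(v) which(fi == v))

  forests <- list()
  choice <- integer(n)  # edge id chosen for each vertex, 0 = none
  target <- integer(n)  # target vertex of that edge, 0 = none

  recurse <- function(k) {
    if (k > length(non_roots)) {
      sel <- choice[non_roots]
      forests[[length(forests) + 1L]] <<-
        data.frame(from = g$edges$from[sel], to = g$edges$to[sel])
      return(invisible())
    }
    v <- non_roots[k]
    for (e in out_edges[[v]]) {
      # follow already-assigned pointers from the target; a return to v
      # would close a cycle
      w <- ti[e]
      ok <- TRUE
      while (w != 0L) {
        if (w == v) { ok <- FALSE; break }
        w <- target[w]
      }
      if (!ok) next
      choice[v] <<- e
      target[v] <<- ti[e]
      recurse(k + 1L)
      choice[v] <<- 0L
      target[v] <<- 0L
    }
    invisible()
  }
  recurse(1L)
  structure(forests, class = "forest_set", roots = roots,
            vertices = g$vertices)
}

# Fraction-free (Bareiss) integer determinant; entries and all intermediate
# values are integers represented exactly in doubles (valid below 2^53).
bareiss_det <- function(A) {
  n <- nrow(A)
  if (n == 0) return(1)
  if (n == 1) return(A[1, 1])
  sign <- 1
  prev <- 1
  for (k in seq_len(n - 1)) {
    if (A[k, k] == 0) {
      p <- which(A[(k + 1):n, k] != 0)
      if (length(p) == 0) return(0)
      p <- p[1] + k
      tmp <- A[k, ]; A[k, ] <- A[p, ]; A[p, ] <- tmp
      sign <- -sign
    }
    idx <- (k + 1):n
    A[idx, idx] <- (A[idx, idx] * A[k, k] -
                      outer(A[idx, k], A[k, idx])) / prev
    prev <- A[k, k]
  }
  sign * A[n, n]
}

#' Count spanning trees rooted at a vertex
#'
#' Exact count via the Matrix-Tree theorem: the number of spanning trees
#' rooted at `root` equals `(-1)^(N-1)` times the principal minor of the
#' unit-label Laplacian obtained by deleting the root's row and column. The
#' determinant is computed by fraction-free integer elimination, so counts
#' such as the 42 467 328 spanning trees of the 4-dimensional hypercube are
#' exact.
#'
#' @param g an `lf_graph` (strong connectivity guarantees a positive count).
#' @param root a vertex.
#' @return the number of spanning trees rooted at `root`.
#' @export
count_rooted_trees <- function(g, root) {
  n <- n_vertices(g)
  r <- vertex_index(g, root)
  L <- matrix(0, n, n)
  fi <- match(g$edges$from, g$vertices)
  ti <- match(g$edges$to, g$vertices)
  for (k in seq_along(fi)) {
    L[ti[k], fi[k]] <- L[ti[k], fi[k]] + 1
    L[fi[k], fi[k]] <- L[fi[k], fi[k]] - 1
  }
  (-1)^(n - 1) * bareiss_det(L[-r, -r, drop = FALSE])
}

#' Tree polynomials (canonical Laplacian kernel basis)
#'
#' Computes the vector of tree polynomials: entry `i` is the sum, over all
#' spanning trees rooted at vertex `i`, of the product of the edge labels.
#' This positive-coefficient polynomial vector spans the Laplacian kernel of
#' a strongly connected graph, so the steady state is proportional to it.
#'
#' @param g a strongly connected `lf_graph`.
#' @return a named list of polynomials, one per vertex, in the graph's
#'   parameter/input symbols. Use [steady_state()] for numeric values.
#' @export
rho_symbolic <- function(g) {
  if (!is_strongly_connected(g)) {
    lf_stop("NotStronglyConnected", "graph is not strongly connected")
  }
  out <- vector("list", n_vertices(g))
  names(out) <- g$vertices
  for (v in g$vertices) {
    trees <- enumerate_spanning_forests(g, roots = v)
    out[[v]] <- poly_sum(lapply(trees, function(tr) {
      ids <- mapply(function(f, t) edge_id(g, f, t), tr$from, tr$to)
      poly_prod(g$label_polys[as.integer(ids)])
    }))
  }
  out
}

# Numeric tree-polynomial vector via Laplacian cofactors:
# rho_i = (-1)^(N-1) det(L[-i, -i]).
rho_numeric <- function(g, x = NULL, params = NULL) {
  L <- laplacian_matrix(g, x = x, params = params)
  n <- nrow(L)
  sgn <- (-1)^(n - 1)
  vapply(seq_len(n), function(i) {
    if (n == 1) return(1)
    sgn * det(L[-i, -i, drop = FALSE])
  }, numeric(1))
}

#' Steady state via the Matrix-Tree theorem
#'
#' For a strongly connected graph the steady state of `du/dt = L u` is the
#' normalized tree-polynomial vector: `u_i* = rho_i / (rho_1 + ... + rho_N)
#' * u_tot`. The numeric fast path solves the reduced linear system obtained
#' by fixing a reference vertex (falling back to an SVD null vector if the
#' system is ill conditioned) and never enumerates trees; the symbolic mode
#' returns the exact rational prescription.
#'
#' @param g a strongly connected `lf_graph`.
#' @param u_tot total concentration/probability mass (default 1).
#' @param mode `"numeric"` (default) or `"symbolic"`.
#' @param x optional numeric input-symbol value (numeric mode).
#' @return numeric mode: named numeric vector summing to `u_tot`. Symbolic
#'   mode: list with elements `rho` (list of polynomials) and `u_tot`.
#' @examples
#' g <- lf_graph(c("1", "2"), data.frame(from = c("1", "2"), to = c("2", "1"),
#'                                       label = c("a", "b")),
#'               parameters = c(a = 2, b = 1))
#' steady_state(g)  # (1/3, 2/3)
#' @export
steady_state <- function(g, u_tot = 1, mode = c("numeric", "symbolic"),
                         x = NULL) {
  mode <- match.arg(mode)
  if (!is_strongly_connected(g)) {
    lf_stop("NotStronglyConnected", "graph is not strongly connected")
  }
  if (mode == "symbolic") {
    return(list(rho = rho_symbolic(g), u_tot = u_tot))
  }
  L <- laplacian_matrix(g, x = x)
  n <- nrow(L)
  if (n == 1) return(stats::setNames(u_tot, g$vertices))
  A <- L[-1, -1, drop = FALSE]
  b <- -L[-1, 1]
  u <- tryCatch({
    v <- solve(A, b)
    if (rcond(A) < 1e-12 || any(v < 0)) NULL else c(1, v)
  }, error = function(e) NULL)
  if (is.null(u)) {
    sv <- svd(L)
    u <- sv$v[, n]
    if (sum(u) < 0) u <- -u
    u[u < 0] <- 0
  }
  stats::setNames(u / sum(u) * u_tot, g$vertices)
}
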