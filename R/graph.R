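# Core representation: finite, simple, directed graphs with labelled edges.

#' Build a linear framework graph
#'
#' Constructs a finite, simple, directed graph whose edges carry positive
#' label expressions (rates). Labels are arithmetic expressions over named
#' positive parameters, positive numeric literals and at most one designated
#' input symbol, restricted to sums and products so that positivity is
#' guaranteed syntactically.
#'
#' @param vertices character (or coercible) vector of distinct vertex
#'   identifiers. Vectors and matrices produced by the package use this
#'   declaration order throughout.
#' @param edges a data frame with columns `from`, `to`, `label`, or a list of
#'   3-element vectors `c(from, to, label)`.
#' @param parameters optional named numeric vector of positive parameter
#'   values used when labels are evaluated numerically.
#' @param input_symbol optional name of the scalar input symbol (for example
#'   a ligand concentration) appearing in binding-edge labels.
#' @param annotations optional 0/1 matrix with one row per vertex giving a
#'   binding pattern (used by hypercube models and coarse graining).
#' @return an object of class `lf_graph`.
#' @examples
#' g <- lf_graph(c("1", "2"), data.frame(from = c("1", "2"), to = c("2", "1"),
#'                                       label = c("a", "b")),
#'               parameters = c(a = 2, b = 1))
#' laplacian_matrix(g)
#' @export
lf_graph <- function(vertices, edges, parameters = NULL, input_symbol = NULL,
                     annotations = NULL) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) {
    lf_stop("UnknownVertex", "duplicate vertex identifiers")
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      data.frame(from = e[[1]], to = e[[2]], label = e[[3]])
    }))
  }
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      label = as.character(edges$label))
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    if (!(e$from %in% vertices) || !(e$to %in% vertices)) {
      lf_stop("UnknownVertex",
              paste0("edge ", e$from, " -> ", e$to,
                     " references an undeclared vertex"))
    }
    if (e$from == e$to) {
      lf_stop("SelfLoop", paste0("self-loop on vertex ", e$from))
    }
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    d <- edges[duplicated(key), , drop = FALSE][1, ]
    lf_stop("DuplicateEdge",
            paste0("duplicate edge ", d$from, " -> ", d$to))
  }
  label_polys <- lapply(edges$label, parse_label)
  if (!is.null(parameters)) {
    parameters <- unlist(parameters)
    if (is.null(names(parameters)) || any(names(parameters) == "")) {
      lf_stop("UnboundParameter", "parameters must be a named numeric vector")
    }
  }
  if (!is.null(annotations)) {
    annotations <- as.matrix(annotations)
    if (nrow(annotations) != length(vertices)) {
      lf_stop("MissingAnnotation",
              "annotation matrix must have one row per vertex")
    }
    rownames(annotations) <- vertices
  }
  structure(list(vertices = vertices, edges = edges,
                 label_polys = label_polys,
                 parameters = parameters,
                 input_symbol = if (is.null(input_symbol)) NULL
                                else as.character(input_symbol),
                 annotations = annotations),
            class = "lf_graph")
}

#' @export
print.lf_graph <- function(x, ...) {
  cat("linear framework graph: ", length(x$vertices), " vertices, ",
      nrow(x$edges), " edges\n", sep = "")
  if (!is.null(x$input_symbol)) {
    cat("input symbol:", x$input_symbol, "\n")
  }
  invisible(x)
}

n_vertices <- function(g) length(g$vertices)

vertex_index <- function(g, v) {
  i <- match(as.character(v), g$vertices)
  if (anyNA(i)) {
    lf_stop("UnknownVertex",
            paste0("unknown vertex: ", paste(v[is.na(i)], collapse = ", ")))
  }
  i
}

# Numeric edge label values at the given parameter binding.
edge_values <- function(g, x = NULL, params = NULL) {
  values <- g$parameters
  if (!is.null(params)) values[names(params)] <- params
  if (!is.null(x)) {
    if (is.null(g$input_symbol)) {
      lf_stop("NoInputSymbol", "graph has no input symbol")
    }
    values[g$input_symbol] <- x
  }
  vapply(g$label_polys, poly_eval, numeric(1), values = values)
}

has_edge <- function(g, from, to) {
  any(g$edges$from == from & g$edges$to == to)
}

edge_id <- function(g, from, to) {
  which(g$edges$from == from & g$edges$to == to)[1]
}

#' Laplacian matrix of a graph
#'
#' Returns the column-sum-zero Laplacian `L` with off-diagonal entry
#' `L[j, i]` equal to the label of edge `i -> j`, so that the dynamics reads
#' `du/dt = L u` and total mass is conserved. Row/column order is the vertex
#' declaration order.
#'
#' @param g an `lf_graph` with all label symbols bound (via `parameters`
#'   and, if the graph has one, `x` for the input symbol).
#' @param x optional numeric value for the input symbol.
#' @param params optional named numeric overrides for parameters.
#' @return numeric `N x N` matrix with zero column sums.
#' @export
laplacian_matrix <- function(g, x = NULL, params = NULL) {
  n <- n_vertices(g)
  L <- matrix(0, n, n, dimnames = list(g$vertices, g$vertices))
  vals <- edge_values(g, x = x, params = params)
  fi <- match(g$edges$from, g$vertices)
  ti <- match(g$edges$to, g$vertices)
  for (k in seq_along(vals)) {
    L[ti[k], fi[k]] <- L[ti[k], fi[k]] + vals[k]
    L[fi[k], fi[k]] <- L[fi[k], fi[k]] - vals[k]
  }
  L
}

# Symbolic Laplacian: N x N list-matrix of polynomials, column sums
# identically zero by construction.
laplacian_symbolic <- function(g) {
  n <- n_vertices(g)
  L <- matrix(list(poly_zero()), n, n,
              dimnames = list(g$vertices, g$vertices))
  fi <- match(g$edges$from, g$vertices)
  ti <- match(g$edges$to, g$vertices)
  for (k in seq_along(fi)) {
    L[[ti[k], fi[k]]] <- poly_add(L[[ti[k], fi[k]]], g$label_polys[[k]])
    L[[fi[k], fi[k]]] <- poly_add(L[[fi[k], fi[k]]],
                                  poly_scale(g$label_polys[[k]], -1))
  }
  L
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$edges[, c("from", "to")], directed = TRUE,
                                vertices = data.frame(name = g$vertices))
}

#' Test strong connectivity
#'
#' A graph is strongly connected when every ordered pair of vertices is
#' joined by a directed path; this guarantees a one-dimensional Laplacian
#' kernel and hence a unique normalized steady state.
#'
#' @param g an `lf_graph`.
#' @return logical.
#' @export
is_strongly_connected <- function(g) {
  if (length(g$vertices) <= 1) return(TRUE)
  if (nrow(g$edges) == 0) return(FALSE)
  igraph::is_connected(as_igraph(g), mode = "strong")
}

#' Test reversibility
#'
#' TRUE when the edge set is closed under reversal: whenever `i -> j` is an
#' edge, so is `j -> i`. Reversibility is a structural prerequisite for the
#' thermodynamic layer (path products, cycle condition, detailed balance).
#'
#' @param g an `lf_graph`.
#' @return logical.
#' @export
is_reversible <- function(g) {
  if (nrow(g$edges) == 0) return(TRUE)
  fwd <- paste(g$edges$from, g$edges$to, sep = "\r")
  rev <- paste(g$edges$to, g$edges$from, sep = "\r")
  all(rev %in% fwd)
}

#' Integrate the Laplacian dynamics
#'
#' Propagates `du/dt = L u` from an initial state with a stiff-capable
#' implicit integrator (`deSolve::lsoda`, rtol 1e-8, atol 1e-10). Total mass
#' is conserved along the trajectory.
#'
#' @param g an `lf_graph` with numerically bound labels.
#' @param u0 non-negative numeric initial state, one entry per vertex.
#' @param t_end final time.
#' @param n_steps number of output time points (default 100).
#' @param x optional numeric input-symbol value.
#' @return a matrix with columns `time` and one column per vertex.
#' @export
propagate <- function(g, u0, t_end, n_steps = 100, x = NULL) {
  L <- laplacian_matrix(g, x = x)
  u0 <- as.numeric(u0)
  if (length(u0) != n_vertices(g)) {
    lf_stop("UnknownVertex", "u0 must have one entry per vertex")
  }
  if (any(u0 < 0)) {
    lf_stop("UnboundParameter", "initial state must be non-negative")
  }
  times <- seq(0, t_end, length.out = n_steps + 1)
  sol <- deSolve::ode(y = stats::setNames(u0, g$vertices), times = times,
                      func = function(t, y, p) list(as.numeric(L %*% y)),
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  colnames(sol)[1] <- "time"
  sol
}

# Dimension of the numeric Laplacian kernel by singular-value count
# (singular values below rel_tol * max are counted as zero).
kernel_dimension <- function(g, x = NULL, rel_tol = 1e-10) {
  s <- svd(laplacian_matrix(g, x = x))$d
  sum(s < rel_tol * max(s, 1e-300))
}

# ---- file I/O --------------------------------------------------------------

#' Read / write graphs as JSON
#'
#' The JSON dialect stores `vertices`, `edges` (objects with `from`, `to`,
#' `label`), `parameters`, `input_symbol` and optional binding-pattern
#' `annotations`. `write_graph_json` followed by `read_graph_json`
#' round-trips a graph exactly.
#'
#' @param path file path.
#' @param g an `lf_graph`.
#' @return `read_graph_json` returns an `lf_graph`; `write_graph_json`
#'   returns `path` invisibly.
#' @export
read_graph_json <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  params <- if (length(spec$parameters)) unlist(spec$parameters) else NULL
  ann <- if (!is.null(spec$annotations)) as.matrix(spec$annotations) else NULL
  lf_graph(spec$vertices, as.data.frame(spec$edges), parameters = params,
           input_symbol = spec$input_symbol, annotations = ann)
}

#' @rdname read_graph_json
#' @export
write_graph_json <- function(g, path) {
  obj <- list(vertices = g$vertices, edges = g$edges,
              parameters = as.list(g$parameters),
              input_symbol = g$input_symbol)
  if (!is.null(g$annotations)) obj$annotations <- unname(g$annotations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read / write graphs as TSV
#'
#' Three-column `from` / `to` / `label` table; parameter values travel in a
#' JSON sidecar (`<path>.params.json`) when present.
#'
#' @param path TSV file path.
#' @param g an `lf_graph`.
#' @return `read_graph_tsv` returns an `lf_graph`.
#' @export
read_graph_tsv <- function(path) {
  edges <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character")
  sidecar <- paste0(path, ".params.json")
  params <- NULL
  input_symbol <- NULL
  if (file.exists(sidecar)) {
    side <- jsonlite::fromJSON(sidecar)
    if (length(side$parameters)) params <- unlist(side$parameters)
    input_symbol <- side$input_symbol
  }
  lf_graph(unique(c(edges$from, edges$to)), edges, parameters = params,
           input_symbol = input_symbol)
}

#' @rdname read_graph_tsv
#' @export
write_graph_tsv <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(g$parameters) || !is.null(g$input_symbol)) {
    jsonlite::write_json(list(parameters = as.list(g$parameters),
                              input_symbol = g$input_symbol),
                         paste0(path, ".params.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
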