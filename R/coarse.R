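# Partition-based coarse graining. The quotient graph's labels are sums of
# tree polynomials over the target block, which makes the coarse graph
# satisfy the cycle condition (even when the fine graph does not) and makes
# its steady state reproduce the block-aggregated fine steady state. The
# construction says nothing about transient dynamics.

#' Validate a vertex partition
#'
#' @param g an `lf_graph`.
#' @param blocks list of vertex vectors; blocks must be disjoint, nonempty
#'   and cover the vertex set.
#' @return the partition as a named list of character vectors.
#' @export
validate_partition <- function(g, blocks) {
  blocks <- lapply(blocks, as.character)
  if (length(blocks) == 0 || any(lengths(blocks) == 0)) {
    lf_stop("InvalidPartition", "blocks must be nonempty")
  }
  all_v <- unlist(blocks)
  if (anyDuplicated(all_v)) {
    lf_stop("InvalidPartition",
            paste0("vertex in more than one block: ",
                   all_v[duplicated(all_v)][1]))
  }
  if (!setequal(all_v, g$vertices)) {
    lf_stop("InvalidPartition", "blocks must cover the vertex set exactly")
  }
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    names(blocks) <- paste0("B", seq_along(blocks))
  }
  blocks
}

#' Coarse-grain a graph over a vertex partition
#'
#' Builds the quotient graph on the partition blocks: there is an edge
#' `w -> z` whenever some fine edge crosses from block `w` to block `z`, and
#' its label is `Q` times the sum of the fine graph's tree polynomials over
#' the target block. With this labelling the coarse graph always satisfies
#' the cycle condition and its steady state equals the block sums of the
#' fine steady state; the dimensional constant `Q` cancels from every
#' steady-state quantity.
#'
#' @param g a strongly connected, reversible `lf_graph` with numerically
#'   bound labels.
#' @param blocks a partition (list of vertex vectors).
#' @param Q positive scale constant fixing the label dimension (default 1).
#' @param x optional numeric input-symbol value at which fine labels (and
#'   hence tree polynomials) are evaluated.
#' @return an `lf_graph` on the block identifiers, with the block
#'   membership attached as attribute `"blocks"`.
#' @export
coarse_grain <- function(g, blocks, Q = 1, x = NULL) {
  if (!is_reversible(g)) {
    lf_stop("NotReversible", "coarse graining requires a reversible graph")
  }
  blocks <- validate_partition(g, blocks)
  rho <- rho_numeric(g, x = x)
  names(rho) <- g$vertices
  block_of <- stats::setNames(rep(names(blocks), lengths(blocks)),
                              unlist(blocks))
  bw <- block_of[g$edges$from]
  bz <- block_of[g$edges$to]
  cross <- unique(data.frame(from = bw, to = bz)[bw != bz, ])
  if (nrow(cross) == 0) {
    lf_stop("InvalidPartition", "partition produces no cross-block edges")
  }
  block_rho <- vapply(blocks, function(b) sum(rho[b]), numeric(1))
  labels <- vapply(cross$to, function(z) Q * block_rho[[z]], numeric(1))
  # labels are stored numerically through auto-named parameters so the
  # coarse graph is a first-class lf_graph
  pnames <- paste0("cg", seq_len(nrow(cross)))
  cg <- lf_graph(names(blocks),
                 data.frame(from = cross$from, to = cross$to, label = pnames),
                 parameters = stats::setNames(labels, pnames))
  attr(cg, "blocks") <- blocks
  cg
}

#' Partition hypercube vertices by binding pattern
#'
#' Groups the vertices of a hypercube-structured graph by the pattern of
#' site occupancy restricted to a subset of sites. Requires per-vertex 0/1
#' binding annotations (as produced by [make_hypercube()]).
#'
#' @param g an annotated `lf_graph`.
#' @param site_subset column indices (or names) of the annotation matrix to
#'   restrict to; the empty set yields one block with every vertex, the full
#'   set yields the singleton partition.
#' @return a named list of vertex vectors (one block per distinct pattern).
#' @export
binding_pattern_partition <- function(g, site_subset) {
  if (is.null(g$annotations)) {
    lf_stop("MissingAnnotation", "graph carries no binding annotations")
  }
  if (length(site_subset) == 0) {
    return(stats::setNames(list(g$vertices), "all"))
  }
  pat <- g$annotations[, site_subset, drop = FALSE]
  key <- apply(pat, 1, paste, collapse = "")
  split(g$vertices, factor(key, levels = unique(key)))
}

#' Push an output function through a coarse graining
#'
#' Given a fine output `f(x) = sum_i lambda_i u_i*(G)` on a graph at
#' thermodynamic equilibrium, computes non-negative coarse coefficients
#' `lambda_w`, independent of the input, such that the coarse output on the
#' quotient graph equals the fine output for every input value. The
#' coefficients are the equilibrium-weighted block averages
#' `lambda_w = sum_{i in G_w} lambda_i mu_i / sum_{i in G_w} mu_i`.
#'
#' @param g a strongly connected, reversible `lf_graph` satisfying the
#'   cycle condition.
#' @param output_coeffs named (or vertex-ordered) non-negative coefficients.
#' @param blocks a partition of the vertices.
#' @param x_ref input value at which the Boltzmann weights are evaluated
#'   (default 1); at equilibrium the result does not depend on this choice.
#' @return named numeric vector of coarse coefficients, one per block.
#' @export
pushforward_output <- function(g, output_coeffs, blocks, x_ref = 1) {
  blocks <- validate_partition(g, blocks)
  chk <- satisfies_cycle_condition(g, x = if (is.null(g$input_symbol)) NULL
                                          else x_ref)
  if (!chk$ok) {
    lf_stop("NotAtEquilibrium",
            "pushforward requires the fine graph at equilibrium",
            cycle = chk$violating_cycle)
  }
  lam <- as.numeric(output_coeffs)
  if (!is.null(names(output_coeffs))) {
    lam <- as.numeric(output_coeffs[g$vertices])
  }
  if (any(lam < 0)) {
    lf_stop("InvalidPartition", "output coefficients must be non-negative")
  }
  mu <- equilibrium_mu(g, x = if (is.null(g$input_symbol)) NULL else x_ref)
  vapply(blocks, function(b) {
    idx <- match(b, g$vertices)
    sum(lam[idx] * mu[idx]) / sum(mu[idx])
  }, numeric(1))
}
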