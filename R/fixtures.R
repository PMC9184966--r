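# Generators for the graph families used throughout: hypercube binding
# structures, detailed-balanced (equilibrium) parametrizations, random
# strongly connected and reversible graphs, the two-conformation
# ligand-binding square, and random enzyme mechanisms. All randomness is
# seeded explicitly; the same call with the same seed reproduces the same
# object.

fmt_num <- function(v) sprintf("%.17g", v)

#' Hypercube binding graph
#'
#' Builds the hypercube structure on `n_sites` binding sites: one vertex per
#' 0/1 occupancy pattern, with reversible edges flipping a single site.
#' Binding edges for sites listed in `input_sites` carry the input symbol
#' (the free ligand concentration). With shared per-site rates
#' (`per_edge = FALSE`, the default) the cycle condition holds
#' automatically; with `per_edge = TRUE` every directed edge gets its own
#' parameter (named `b<site>_<pattern>` / `u<site>_<pattern>`), which is
#' generically a non-equilibrium parametrization when values are random.
#'
#' @param n_sites number of binding sites (`2^n_sites` vertices).
#' @param input_sites integer indices of sites whose binding edge labels
#'   carry the input symbol.
#' @param input_symbol input symbol name (default `"x"`).
#' @param on,off per-site binding/unbinding rates (default all 1), recycled
#'   to `n_sites`; ignored when `per_edge = TRUE` and `seed` is given.
#' @param per_edge give every directed edge its own parameter.
#' @param seed optional seed for random per-edge rates, drawn log-uniformly
#'   over `[10^-r, 10^r]`.
#' @param r log10 half-range for random rates (default 1).
#' @return an `lf_graph` with a binding-pattern annotation matrix (one
#'   column per site).
#' @examples
#' g <- make_hypercube(2)           # the square C2: 4 vertices, 8 edges
#' count_rooted_trees(g, "00")      # 4 spanning trees per root
#' @export
make_hypercube <- function(n_sites, input_sites = integer(0),
                           input_symbol = "x", on = 1, off = 1,
                           per_edge = FALSE, seed = NULL, r = 1) {
  stopifnot(n_sites >= 1)
  bits <- as.matrix(expand.grid(rep(list(0:1), n_sites)))
  colnames(bits) <- paste0("site", seq_len(n_sites))
  vname <- apply(bits, 1, paste, collapse = "")
  on <- rep_len(on, n_sites)
  off <- rep_len(off, n_sites)
  if (!is.null(seed)) set.seed(seed)
  edges <- NULL
  params <- numeric(0)
  for (v in seq_len(nrow(bits))) {
    for (s in seq_len(n_sites)) {
      if (bits[v, s] == 1) next
      w <- v + 2^(s - 1)  # flip site s on
      pat <- vname[v]
      if (per_edge) {
        pb <- paste0("b", s, "_", pat)
        pu <- paste0("u", s, "_", pat)
        params[pb] <- if (is.null(seed)) on[s] else 10^stats::runif(1, -r, r)
        params[pu] <- if (is.null(seed)) off[s] else 10^stats::runif(1, -r, r)
        lb <- pb
        lu <- pu
      } else {
        lb <- fmt_num(on[s])
        lu <- fmt_num(off[s])
      }
      if (s %in% input_sites) lb <- paste0(lb, "*", input_symbol)
      edges <- rbind(edges,
                     data.frame(from = c(vname[v], vname[w]),
                                to = c(vname[w], vname[v]),
                                label = c(lb, lu)))
    }
  }
  lf_graph(vname, edges,
           parameters = if (length(params)) params else NULL,
           input_symbol = if (length(input_sites)) input_symbol else NULL,
           annotations = bits)
}

#' Regulated-recruitment gene-regulation model
#'
#' Hypercube with `m` sites bound by a transcription factor (the input) and
#' one further site bound by polymerase; the natural output is the
#' steady-state probability that the polymerase site is occupied.
#'
#' @param m number of input-binding sites.
#' @param ... forwarded to [make_hypercube()].
#' @return list with `graph` and `output` (0/1 coefficient vector marking
#'   polymerase-bound vertices).
#' @export
make_regulated_recruitment <- function(m, ...) {
  g <- make_hypercube(m + 1, input_sites = seq_len(m), ...)
  out <- as.numeric(g$annotations[, m + 1] == 1)
  list(graph = g, output = out)
}

#' Two-conformation ligand-binding square
#'
#' The 4-vertex reversible square describing a biomolecule with two
#' conformations (vertices 1, 2 unbound; 3, 4 bound) and a single
#' ligand-binding site; the ligand concentration `x` multiplies the two
#' binding labels. Edge labels: `1->2: k5`, `2->1: k1`, `1->3: k2*x`,
#' `3->1: k8`, `3->4: k3`, `4->3: k7`, `2->4: k6*x`, `4->2: k4`. The single
#' independent cycle satisfies the cycle condition exactly when
#' `k1 k2 k3 k4 = k5 k6 k7 k8`; passing `equilibrium = TRUE` overwrites
#' `k8` to enforce it.
#'
#' @param k named or positional numeric vector `k1..k8` (default all 1).
#' @param equilibrium impose the cycle condition by overwriting `k8`.
#' @param symbolic keep the rates symbolic (no numeric parameters bound).
#' @return an `lf_graph` with input symbol `x`; the bound vertices are
#'   `"3"` and `"4"`.
#' @export
make_binding_square <- function(k = rep(1, 8), equilibrium = FALSE,
                            symbolic = FALSE) {
  k <- as.numeric(k)
  stopifnot(length(k) == 8)
  names(k) <- paste0("k", 1:8)
  if (equilibrium) k["k8"] <- k["k1"] * k["k2"] * k["k3"] * k["k4"] /
      (k["k5"] * k["k6"] * k["k7"])
  edges <- data.frame(
    from  = c("1", "2", "1", "3", "3", "4", "2", "4"),
    to    = c("2", "1", "3", "1", "4", "3", "4", "2"),
    label = c("k5", "k1", "k2*x", "k8", "k3", "k7", "k6*x", "k4"))
  ann <- cbind(bound = c(0, 0, 1, 1))
  lf_graph(as.character(1:4), edges,
           parameters = if (symbolic) NULL else k,
           input_symbol = "x", annotations = ann)
}

#' Detailed-balanced parametrization of a reversible graph
#'
#' Draws an equilibrium (detailed-balanced) random labelling of a
#' reversible structure: each vertex `i` receives a potential `phi_i` (with
#' Boltzmann weights `exp(-phi_i)` spanning `[10^-r, 10^r]`) and each
#' unordered edge pair a symmetric scale `s_ij` log-uniform over
#' `[10^-r, 10^r]`; labels are `l(i -> j) = s_ij exp((phi_i - phi_j)/2)`.
#' The construction satisfies the cycle condition up to floating-point
#' rounding, and the equilibrium basis recovers the potential differences.
#'
#' @param structure either an integer (number of vertices of a random
#'   reversible structure) or a reversible `lf_graph` whose structure to
#'   reuse.
#' @param seed integer seed.
#' @param r log10 half-range (default 3).
#' @param extra_edges for random structures, number of chord pairs added to
#'   the base spanning tree (default `ceiling(n/2)`).
#' @return an `lf_graph` with numeric-literal labels and the potentials
#'   attached as attribute `"phi"`.
#' @export
make_detailed_balanced <- function(structure, seed, r = 3,
                                   extra_edges = NULL) {
  set.seed(seed)
  if (is.numeric(structure)) {
    n <- structure
    if (is.null(extra_edges)) extra_edges <- ceiling(n / 2)
    pairs <- random_reversible_structure(n, extra_edges)
    vertices <- as.character(seq_len(n))
  } else {
    g0 <- structure
    if (!is_reversible(g0)) {
      lf_stop("NotReversible", "structure must be reversible")
    }
    und <- unique(t(apply(g0$edges[, c("from", "to")], 1, sort)))
    pairs <- data.frame(a = und[, 1], b = und[, 2])
    vertices <- g0$vertices
    n <- length(vertices)
  }
  phi <- stats::setNames(stats::runif(n, -r / 2 * log(10), r / 2 * log(10)),
                         vertices)
  phi[1] <- 0
  s <- 10^stats::runif(nrow(pairs), -r, r)
  edges <- NULL
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]; b <- pairs$b[i]
    lab_f <- s[i] * exp((phi[[a]] - phi[[b]]) / 2)
    lab_b <- s[i] * exp((phi[[b]] - phi[[a]]) / 2)
    edges <- rbind(edges, data.frame(from = c(a, b), to = c(b, a),
                                     label = fmt_num(c(lab_f, lab_b))))
  }
  g <- lf_graph(vertices, edges)
  attr(g, "phi") <- phi
  g
}

# random reversible structure: a random spanning tree plus chords, as
# unordered vertex pairs
random_reversible_structure <- function(n, extra_edges) {
  vs <- as.character(seq_len(n))
  pairs <- NULL
  for (v in 2:n) {
    u <- sample(v - 1, 1)
    pairs <- rbind(pairs, data.frame(a = vs[min(u, v)], b = vs[max(u, v)]))
  }
  tries <- 0
  while (extra_edges > 0 && tries < 100 * extra_edges) {
    uv <- sort(sample(n, 2))
    key <- paste(pairs$a, pairs$b)
    cand <- paste(vs[uv[1]], vs[uv[2]])
    if (!(cand %in% key)) {
      pairs <- rbind(pairs, data.frame(a = vs[uv[1]], b = vs[uv[2]]))
      extra_edges <- extra_edges - 1
    }
    tries <- tries + 1
  }
  pairs
}

#' Random reversible graph with generic labels
#'
#' Same structures as [make_detailed_balanced()] but with all `2 E`
#' directed labels drawn independently log-uniform over `[10^-r, 10^r]`, so
#' the cycle condition fails generically.
#'
#' @param n number of vertices.
#' @param seed integer seed.
#' @param r log10 half-range (default 1).
#' @param extra_edges chord pairs beyond the spanning tree.
#' @return an `lf_graph`.
#' @export
make_random_reversible <- function(n, seed, r = 1, extra_edges = NULL) {
  set.seed(seed)
  if (is.null(extra_edges)) extra_edges <- ceiling(n / 2)
  pairs <- random_reversible_structure(n, extra_edges)
  edges <- NULL
  for (i in seq_len(nrow(pairs))) {
    lab <- 10^stats::runif(2, -r, r)
    edges <- rbind(edges,
                   data.frame(from = c(pairs$a[i], pairs$b[i]),
                              to = c(pairs$b[i], pairs$a[i]),
                              label = fmt_num(lab)))
  }
  lf_graph(as.character(seq_len(n)), edges)
}

#' Random strongly connected directed graph
#'
#' A random cyclic ordering of the vertices guarantees strong connectivity;
#' additional directed edges are added with probability `p_extra` per
#' ordered pair. Labels are numeric literals log-uniform over
#' `[10^-r, 10^r]`.
#'
#' @param n number of vertices.
#' @param seed integer seed.
#' @param p_extra probability of each extra ordered pair (default 0.3).
#' @param r log10 half-range (default 1).
#' @return an `lf_graph`.
#' @export
make_random_strong <- function(n, seed, p_extra = 0.3, r = 1) {
  set.seed(seed)
  vs <- as.character(seq_len(n))
  ord <- sample(n)
  edges <- data.frame(from = vs[ord], to = vs[c(ord[-1], ord[1])],
                      label = fmt_num(10^stats::runif(n, -r, r)))
  if (n >= 2) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (any(edges$from == vs[i] & edges$to == vs[j])) next
        if (stats::runif(1) < p_extra) {
          edges <- rbind(edges,
                         data.frame(from = vs[i], to = vs[j],
                                    label = fmt_num(10^stats::runif(1, -r, r))))
        }
      }
    }
  }
  lf_graph(vs, edges)
}

# ---- enzyme mechanism fixtures --------------------------------------------

rand_rates <- function(nms, r = 1) {
  stats::setNames(10^stats::runif(length(nms), -r, r), nms)
}

#' Random enzyme mechanisms
#'
#' Draws a mechanism from one of four families used to exercise the
#' modification-cycle machinery: `"mm_irrev"` (classical irreversible
#' Michaelis-Menten), `"mm_rev"` (fully reversible Michaelis-Menten),
#' `"bibi"` (two binding routes and two release routes with a central
#' catalytic core) and `"deadend"` (reversible Michaelis-Menten plus a
#' dead-end product complex that sequesters enzyme without catalysis).
#' Rates are log-uniform over `[10^-1, 10^1]`. The mechanism converts
#' `sub` into `prod`.
#'
#' @param family one of `"mm_irrev"`, `"mm_rev"`, `"bibi"`, `"deadend"`.
#' @param enzyme enzyme name; intermediate names are prefixed with it.
#' @param sub,prod substrate and product symbols (`"S0"`/`"S1"` order gives
#'   a forward enzyme, reversed gives the demodifying enzyme).
#' @param seed optional integer seed.
#' @return an `enzyme_mechanism`.
#' @export
make_mechanism <- function(family = c("mm_irrev", "mm_rev", "bibi",
                                      "deadend"),
                           enzyme = "E", sub = "S0", prod = "S1",
                           seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  iv <- function(i) paste0(enzyme, "Y", i)
  if (family == "mm_irrev") {
    pars <- rand_rates(paste0(enzyme, c("on", "off", "cat")))
    enzyme_mechanism(enzyme, iv(1), list(
      list(type = "binding", substrate = sub, to = iv(1),
           rate = paste0(enzyme, "on")),
      list(type = "release", from = iv(1), substrate = sub,
           rate = paste0(enzyme, "off")),
      list(type = "release", from = iv(1), substrate = prod,
           rate = paste0(enzyme, "cat"))), pars)
  } else if (family == "mm_rev") {
    pars <- rand_rates(paste0(enzyme, 1:6))
    enzyme_mechanism(enzyme, iv(1:2), list(
      list(type = "binding", substrate = sub, to = iv(1),
           rate = paste0(enzyme, 1)),
      list(type = "release", from = iv(1), substrate = sub,
           rate = paste0(enzyme, 2)),
      list(type = "conversion", from = iv(1), to = iv(2),
           rate = paste0(enzyme, 3)),
      list(type = "conversion", from = iv(2), to = iv(1),
           rate = paste0(enzyme, 4)),
      list(type = "release", from = iv(2), substrate = prod,
           rate = paste0(enzyme, 5)),
      list(type = "binding", substrate = prod, to = iv(2),
           rate = paste0(enzyme, 6))), pars)
  } else if (family == "bibi") {
    pars <- rand_rates(paste0(enzyme, 1:14))
    enzyme_mechanism(enzyme, iv(1:4), list(
      list(type = "binding", substrate = sub, to = iv(1),
           rate = paste0(enzyme, 1)),
      list(type = "release", from = iv(1), substrate = sub,
           rate = paste0(enzyme, 2)),
      list(type = "binding", substrate = sub, to = iv(2),
           rate = paste0(enzyme, 3)),
      list(type = "release", from = iv(2), substrate = sub,
           rate = paste0(enzyme, 4)),
      list(type = "conversion", from = iv(1), to = iv(3),
           rate = paste0(enzyme, 5)),
      list(type = "conversion", from = iv(3), to = iv(1),
           rate = paste0(enzyme, 6)),
      list(type = "conversion", from = iv(2), to = iv(3),
           rate = paste0(enzyme, 7)),
      list(type = "conversion", from = iv(3), to = iv(2),
           rate = paste0(enzyme, 8)),
      list(type = "conversion", from = iv(3), to = iv(4),
           rate = paste0(enzyme, 9)),
      list(type = "conversion", from = iv(4), to = iv(3),
           rate = paste0(enzyme, 10)),
      list(type = "release", from = iv(3), substrate = prod,
           rate = paste0(enzyme, 11)),
      list(type = "binding", substrate = prod, to = iv(3),
           rate = paste0(enzyme, 12)),
      list(type = "release", from = iv(4), substrate = prod,
           rate = paste0(enzyme, 13)),
      list(type = "binding", substrate = prod, to = iv(4),
           rate = paste0(enzyme, 14))), pars)
  } else {
    pars <- rand_rates(paste0(enzyme, 1:8))
    enzyme_mechanism(enzyme, iv(1:3), list(
      list(type = "binding", substrate = sub, to = iv(1),
           rate = paste0(enzyme, 1)),
      list(type = "release", from = iv(1), substrate = sub,
           rate = paste0(enzyme, 2)),
      list(type = "conversion", from = iv(1), to = iv(2),
           rate = paste0(enzyme, 3)),
      list(type = "conversion", from = iv(2), to = iv(1),
           rate = paste0(enzyme, 4)),
      list(type = "release", from = iv(2), substrate = prod,
           rate = paste0(enzyme, 5)),
      list(type = "binding", substrate = prod, to = iv(2),
           rate = paste0(enzyme, 6)),
      # dead-end complex: binds product, only releases it back
      list(type = "binding", substrate = prod, to = iv(3),
           rate = paste0(enzyme, 7)),
      list(type = "release", from = iv(3), substrate = prod,
           rate = paste0(enzyme, 8))), pars)
  }
}

#' Random modification cycle
#'
#' Couples two randomly drawn mechanisms (forward enzyme on S0 -> S1,
#' reverse enzyme on S1 -> S0) with random conservation totals: enzyme
#' totals log-uniform over `[0.5, 2]` and substrate total over `[1, 10]`.
#'
#' @param seed integer seed.
#' @param families families to draw from (see [make_mechanism()]).
#' @return a `modification_cycle`.
#' @export
make_random_cycle <- function(seed,
                              families = c("mm_irrev", "mm_rev", "bibi",
                                           "deadend")) {
  set.seed(seed)
  fam_e <- sample(families, 1)
  fam_f <- sample(families, 1)
  mE <- make_mechanism(fam_e, enzyme = "E", sub = "S0", prod = "S1")
  mF <- make_mechanism(fam_f, enzyme = "F", sub = "S1", prod = "S0")
  modification_cycle(mE, mF,
                     E_tot = exp(stats::runif(1, log(0.5), log(2))),
                     F_tot = exp(stats::runif(1, log(0.5), log(2))),
                     S_tot = exp(stats::runif(1, log(1), log(10))))
}
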