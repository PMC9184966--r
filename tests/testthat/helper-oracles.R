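# Independent brute-force oracles used to validate the fast implementations.

# Canonical string form of a forest (edge data frame) for set comparison.
forest_key <- function(f) {
  if (nrow(f) == 0) return("")
  paste(sort(paste0(f$from, ">", f$to)), collapse = ",")
}

# Brute-force spanning-forest enumeration: test every subset of the edge set
# against the definition (spanning; at most one outgoing edge per vertex;
# no cycles ignoring direction; rootless vertices exactly the root set).
# With <= 1 outgoing edge per vertex, an undirected cycle exists iff
# following the out-pointers returns to the start, so pointer chasing
# decides acyclicity.
forest_oracle <- function(g, roots) {
  roots <- as.character(roots)
  n <- length(g$vertices)
  ne <- nrow(g$edges)
  fi <- match(g$edges$from, g$vertices)
  ti <- match(g$edges$to, g$vertices)
  ri <- match(roots, g$vertices)
  keys <- character(0)
  for (mask in 0:(2^ne - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(ne) - 1)) > 0)
    out_cnt <- tabulate(fi[sel], nbins = n)
    if (any(out_cnt > 1)) next
    # roots = vertices with no outgoing edge, must equal the root set
    if (!setequal(which(out_cnt == 0), ri)) next
    ptr <- integer(n)
    ptr[fi[sel]] <- ti[sel]
    ok <- TRUE
    for (v in seq_len(n)) {
      seen <- integer(0)
      w <- v
      while (w != 0L) {
        if (w %in% seen) { ok <- FALSE; break }
        seen <- c(seen, w)
        w <- ptr[w]
      }
      if (!ok) break
    }
    if (!ok) next
    keys <- c(keys, forest_key(g$edges[sel, , drop = FALSE]))
  }
  sort(keys)
}

# Brute-force all-pairs reachability via boolean matrix closure.
strongly_connected_oracle <- function(g) {
  n <- length(g$vertices)
  if (n <= 1) return(TRUE)
  A <- diag(TRUE, n)
  for (k in seq_len(nrow(g$edges))) {
    A[match(g$edges$from[k], g$vertices),
      match(g$edges$to[k], g$vertices)] <- TRUE
  }
  for (it in seq_len(n)) A <- (A %*% A) > 0
  all(A)
}

# Nullspace direction of a numeric matrix by SVD.
nullspace_vector <- function(L) {
  v <- svd(L)$v[, ncol(L)]
  if (sum(v) < 0) v <- -v
  v
}

# symbolic monomial product helper for expected tree polynomials
mono <- function(...) poly_prod(lapply(c(...), linfra:::poly_sym))

# random positive rational response of the equilibrium-hypercube type:
# numerator/denominator with non-negative coefficients, num <= den
random_response <- function(m, seed) {
  set.seed(seed)
  bits <- as.matrix(expand.grid(rep(list(0:1), m + 1)))
  b_in <- rowSums(bits[, seq_len(m), drop = FALSE])
  outb <- bits[, m + 1] == 1
  cw <- 10^stats::runif(2^(m + 1), -3, 3)
  num <- vapply(0:m, function(d) sum(cw[b_in == d & outb]), numeric(1))
  den <- vapply(0:m, function(d) sum(cw[b_in == d]), numeric(1))
  linfra:::new_response_fn(num, den)
}
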