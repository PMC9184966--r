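# Input-output response functions and sharpness (position-steepness)
# analysis with Hill-function references.

# ---- univariate polynomial helpers (ascending coefficient order) -----------

pv_trim <- function(a, tol = 0) {
  while (length(a) > 1 && abs(a[length(a)]) <= tol) a <- a[-length(a)]
  a
}

pv_eval <- function(a, x) {
  out <- 0
  for (k in rev(seq_along(a))) out <- out * x + a[k]
  out
}

pv_deriv <- function(a) {
  if (length(a) <= 1) return(0)
  a[-1] * seq_len(length(a) - 1)
}

pv_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

pv_sub <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  a - b
}

# real non-negative roots of a coefficient vector
pv_real_nonneg_roots <- function(a, tol = 1e-8) {
  a <- pv_trim(a, tol = max(abs(a)) * 1e-14)
  if (length(a) <= 1) return(numeric(0))
  r <- polyroot(a)
  re <- Re(r)[abs(Im(r)) < tol * (1 + abs(Re(r)))]
  sort(unique(re[re >= 0]))
}

# ---- response functions ----------------------------------------------------

new_response_fn <- function(num, den, meta = list()) {
  scale <- max(abs(den))
  structure(list(num = num / scale, den = den / scale, meta = meta),
            class = "response_fn")
}

#' @export
print.response_fn <- function(x, ...) {
  fmt <- function(a) paste(signif(a, 6), "x^", seq_along(a) - 1,
                           sep = "", collapse = " + ")
  cat("rational response function\n  numerator:  ", fmt(x$num),
      "\n  denominator:", fmt(x$den), "\n")
  invisible(x)
}

#' Evaluate a response function
#' @param rf a `response_fn`.
#' @param x numeric input values.
#' @return numeric values of the bounded rational function.
#' @export
eval_response <- function(rf, x) {
  pv_eval(rf$num, x) / pv_eval(rf$den, x)
}

#' Steady-state input-output response of a graph
#'
#' Builds the response `f(x) = sum_i lambda_i u_i*(x)` of a strongly
#' connected graph whose binding edges carry the input symbol, as an exact
#' rational function of the input. The numerator is the output-weighted sum
#' of the tree polynomials and the denominator their total; both are
#' collected by powers of the input with the remaining parameters evaluated
#' numerically (`symbolic = FALSE`) or kept as polynomials
#' (`symbolic = TRUE`). Common powers of the input cancel.
#'
#' @param g a strongly connected `lf_graph` with an input symbol.
#' @param output_coeffs non-negative output coefficients, one per vertex.
#' @param symbolic if TRUE, return the coefficient polynomials of each power
#'   of the input instead of numeric coefficients.
#' @return `symbolic = FALSE`: a `response_fn` with numeric coefficient
#'   vectors `num`, `den` (ascending powers). `symbolic = TRUE`: a list with
#'   `num_coeffs` and `den_coeffs`, lists of polynomials indexed by power of
#'   the input.
#' @export
response_function <- function(g, output_coeffs, symbolic = FALSE) {
  if (is.null(g$input_symbol)) {
    lf_stop("NoInputSymbol", "graph has no input symbol")
  }
  lam <- as.numeric(output_coeffs)
  if (length(lam) != n_vertices(g) || any(lam < 0) || all(lam == 0)) {
    lf_stop("InvalidPartition",
            "output coefficients must be non-negative, not all zero, one per vertex")
  }
  rho <- rho_symbolic(g)
  if (!symbolic) {
    rho <- lapply(rho, poly_substitute, values = g$parameters)
    extra <- setdiff(unique(unlist(lapply(rho, poly_vars))), g$input_symbol)
    if (length(extra) > 0) {
      lf_stop("UnboundParameter",
              paste0("unbound parameter(s): ", paste(extra, collapse = ", ")))
    }
  }
  num_poly <- poly_sum(mapply(poly_scale, rho, lam, SIMPLIFY = FALSE))
  den_poly <- poly_sum(rho)
  xsym <- g$input_symbol
  num_c <- poly_collect(num_poly, xsym)
  den_c <- poly_collect(den_poly, xsym)
  # cancel common powers of x
  lead0 <- function(cs) {
    k <- 0L
    while (k < length(cs) - 1 && poly_is_zero(cs[[k + 1]])) k <- k + 1L
    k
  }
  drop <- min(lead0(num_c), lead0(den_c))
  if (drop > 0) {
    num_c <- num_c[-(seq_len(drop))]
    den_c <- den_c[-(seq_len(drop))]
  }
  if (symbolic) {
    return(list(num_coeffs = num_c, den_coeffs = den_c,
                input_symbol = xsym))
  }
  num <- vapply(num_c, function(p) poly_eval(p, numeric(0)), numeric(1))
  den <- vapply(den_c, function(p) poly_eval(p, numeric(0)), numeric(1))
  new_response_fn(pv_trim(num, max(abs(den)) * 1e-13),
                  pv_trim(den, max(abs(den)) * 1e-13))
}

#' Hill function as a rational response
#'
#' `H_h(x) = x^h / (1 + x^h)` for integer `h >= 1`, in the same rational
#' representation as graph-derived responses (half-max point 1).
#'
#' @param h integer Hill coefficient.
#' @return a `response_fn`.
#' @export
hill_response <- function(h) {
  stopifnot(h == round(h), h >= 1)
  num <- c(numeric(h), 1)
  den <- num
  den[1] <- 1
  new_response_fn(num, den, meta = list(hill = h))
}

# ---- sharpness -------------------------------------------------------------

response_extrema <- function(rf) {
  P <- rf$num; Q <- rf$den
  W <- pv_sub(pv_mul(pv_deriv(P), Q), pv_mul(P, pv_deriv(Q)))
  cand <- c(0, pv_real_nonneg_roots(W))
  vals <- eval_response(rf, cand)
  # x -> Inf limit: ratio of coefficients at the denominator's degree
  dq <- length(Q)
  pinf <- if (length(P) < dq) 0 else P[dq] / Q[dq]
  vals <- c(vals, pinf)
  list(M = max(vals), m = min(vals), W = W)
}

#' Half-maximal input of a response
#'
#' The smallest positive input at which the response crosses the midpoint
#' of its global range over `[0, Inf)`.
#'
#' @param rf a `response_fn`.
#' @return numeric `x0.5`.
#' @export
half_max_point <- function(rf) {
  ex <- response_extrema(rf)
  if (ex$M - ex$m <= 1e-14 * max(abs(ex$M), 1)) {
    lf_stop("ConstantFunction", "response is constant; no half-max point")
  }
  target <- (ex$M + ex$m) / 2
  roots <- pv_real_nonneg_roots(pv_sub(rf$num, rf$den * target))
  roots <- roots[roots > 0]
  if (length(roots) == 0) {
    lf_stop("ConstantFunction", "no positive half-max crossing found")
  }
  min(roots)
}

#' Position and steepness of a response
#'
#' Normalizes the input by the half-max point, `g(y) = f(y x0.5)`, and
#' reports the steepness `s = max_y |g'(y)|` and the position `p`, the `y`
#' at which the maximum is attained. Critical points are found exactly from
#' the roots of the derivative's numerator polynomial, with the endpoint
#' `y = 0` included; ties are broken towards the smallest `y`.
#'
#' @param rf a non-constant `response_fn`.
#' @return list with `p`, `s`, `x0.5`.
#' @examples
#' position_steepness(hill_response(2))  # p ~ 0.577, s ~ 0.6495
#' @export
position_steepness <- function(rf) {
  x05 <- half_max_point(rf)
  P <- rf$num; Q <- rf$den
  W <- pv_sub(pv_mul(pv_deriv(P), Q), pv_mul(P, pv_deriv(Q)))
  # d/dx of f' = W / Q^2 has numerator W' Q - 2 W Q'
  V <- pv_sub(pv_mul(pv_deriv(W), Q), 2 * pv_mul(W, pv_deriv(Q)))
  cand <- c(0, pv_real_nonneg_roots(V))
  fprime <- vapply(cand, function(xx) {
    pv_eval(W, xx) / pv_eval(Q, xx)^2
  }, numeric(1))
  gprime <- abs(fprime) * x05
  best <- which(gprime > max(gprime) - 1e-12 * max(gprime))
  i <- best[which.min(cand[best])]
  list(p = cand[i] / x05, s = gprime[i], x0.5 = x05)
}

#' Position-steepness of a Hill function (closed form)
#'
#' For `H_h(x) = x^h / (1 + x^h)` with `h > 1` the normalized derivative is
#' maximal at `y* = ((h - 1) / (h + 1))^(1/h)`, giving
#' `s = h y*^(h-1) / (1 + y*^h)^2` and `p = y*`. For `h = 1` the maximum
#' sits at the boundary: `p = 0`, `s = 1`.
#'
#' @param h Hill coefficient, `h >= 1` (not necessarily an integer).
#' @return list with `p` and `s`.
#' @export
hill_ps <- function(h) {
  stopifnot(h >= 1)
  if (h == 1) return(list(p = 0, s = 1))
  y <- ((h - 1) / (h + 1))^(1 / h)
  list(p = y, s = h * y^(h - 1) / (1 + y^h)^2)
}

#' The Hill line
#'
#' Locus of (position, steepness) points of the Hill functions as the
#' coefficient varies.
#'
#' @param h_values Hill coefficients (> 1).
#' @return data frame with columns `h`, `p`, `s`.
#' @export
hill_line <- function(h_values) {
  pts <- lapply(h_values, hill_ps)
  data.frame(h = h_values,
             p = vapply(pts, `[[`, numeric(1), "p"),
             s = vapply(pts, `[[`, numeric(1), "s"))
}

# dense-grid maximization oracle used to cross-check position_steepness:
# |g'| evaluated on a log-spaced grid of normalized inputs (plus y = 0)
ps_grid_oracle <- function(rf, n = 1e5, y_max = 1e4) {
  x05 <- half_max_point(rf)
  y <- c(0, exp(seq(log(1e-6), log(y_max), length.out = n)))
  W <- pv_sub(pv_mul(pv_deriv(rf$num), rf$den),
              pv_mul(rf$num, pv_deriv(rf$den)))
  gp <- abs(pv_eval(W, y * x05) / pv_eval(rf$den, y * x05)^2) * x05
  i <- which.max(gp)
  list(p = y[i], s = gp[i])
}

# ---- (p, s) region sampling ------------------------------------------------

#' Sample the equilibrium position-steepness region of a hypercube model
#'
#' Draws random thermodynamic-equilibrium parametrizations of the
#' regulated-recruitment hypercube model with `m` input-binding sites plus
#' one output site, computes each response's (position, steepness) point
#' and summarizes the cloud. At equilibrium a state's Boltzmann weight is
#' `c_i x^(b_i)` where `b_i` counts input-bound sites, so each draw samples
#' the weights `c_i` log-uniformly over `[10^-r, 10^r]`; the output is the
#' steady-state probability that the output site is occupied. Points with
#' position below `p_min` sit on the anomalous low-position boundary and
#' are flagged, not discarded.
#'
#' @param m number of input-binding sites.
#' @param n_samples number of parameter draws.
#' @param seed integer seed (identical seeds give identical clouds).
#' @param r log10 half-range of the weight draws (default 3).
#' @param p_min positions below this are flagged as degenerate (default
#'   0.05).
#' @return data frame with columns `p`, `s`, `degenerate`, plus attributes
#'   `max_s_regular` (max steepness among non-degenerate points) and
#'   `seed`.
#' @export
sample_ps_region <- function(m, n_samples, seed, r = 3, p_min = 0.05) {
  set.seed(seed)
  n_states <- 2^(m + 1)
  bits <- as.matrix(expand.grid(rep(list(0:1), m + 1)))[, (m + 1):1,
                                                        drop = FALSE]
  b_in <- rowSums(bits[, seq_len(m), drop = FALSE])
  out_bound <- bits[, m + 1] == 1
  res <- matrix(NA_real_, n_samples, 2)
  for (k in seq_len(n_samples)) {
    cw <- 10^stats::runif(n_states, -r, r)
    num <- vapply(0:m, function(d) sum(cw[b_in == d & out_bound]),
                  numeric(1))
    den <- vapply(0:m, function(d) sum(cw[b_in == d]), numeric(1))
    rf <- new_response_fn(num, den)
    ps <- tryCatch(position_steepness(rf), lf_error = function(e) NULL)
    if (!is.null(ps)) res[k, ] <- c(ps$p, ps$s)
  }
  out <- data.frame(p = res[, 1], s = res[, 2])
  out$degenerate <- !is.na(out$p) & out$p < p_min
  keep <- !is.na(out$p) & !out$degenerate
  attr(out, "max_s_regular") <- if (any(keep)) max(out$s[keep]) else NA_real_
  attr(out, "seed") <- seed
  out
}
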