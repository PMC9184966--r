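# Sparse multivariate polynomials with numeric coefficients.
#
# Edge labels in the linear framework are positive sums of monomials in named
# rate parameters (and at most one input symbol), and every Matrix-Tree
# quantity derived from them -- the tree polynomials rho_i, response-function
# numerators and denominators, aggregated enzyme parameters -- is again such a
# polynomial. This file implements the small exact algebra those objects need:
# construction, addition, multiplication, evaluation, collection by powers of
# one symbol, and a rewriting step used to reduce polynomials modulo a
# binomial relation such as the cycle condition k1 k2 k3 k4 = k5 k6 k7 k8.
#
# Representation: a polynomial is a named numeric vector; names are canonical
# monomial keys ("1" for the constant term, otherwise "a^2*b" with symbols in
# lexicographic order). Canonical keys make equality and printing
# deterministic.

#' Label-algebra polynomials
#'
#' Edge labels and every Matrix-Tree quantity derived from them are sparse
#' multivariate polynomials with positive coefficients. A polynomial is
#' represented as a named numeric vector whose names are canonical monomial
#' keys (`"1"` for the constant term, otherwise e.g. `"k1^2*x"` with symbols
#' in lexicographic order), which makes printing and equality deterministic.
#' `poly_sym` / `poly_const` construct atoms, `poly_add` / `poly_mul` (and
#' the list folds `poly_sum` / `poly_prod`) combine them, `poly_eval`
#' evaluates at a named numeric assignment, `poly_substitute` binds a subset
#' of symbols, `poly_collect` collects by powers of one symbol,
#' `poly_degree` reports the degree in one symbol and `poly_format` renders
#' a deterministic string.
#'
#' @param s symbol name.
#' @param c numeric constant.
#' @param p,q polynomials.
#' @param ps list of polynomials.
#' @param values named numeric vector of symbol values.
#' @param sym symbol name.
#' @param tol relative tolerance for coefficient comparison (0 = exact).
#' @name label_algebra
NULL

mono_key <- function(exps) {
  exps <- exps[exps != 0]
  if (length(exps) == 0) return("1")
  exps <- exps[order(names(exps), method = "radix")]
  paste(ifelse(exps == 1L, names(exps),
               paste0(names(exps), "^", exps)), collapse = "*")
}

key_exps <- function(key) {
  if (key == "1") return(integer(0))
  parts <- strsplit(key, "*", fixed = TRUE)[[1]]
  has_pow <- grepl("^", parts, fixed = TRUE)
  syms <- ifelse(has_pow, sub("\\^.*$", "", parts), parts)
  exps <- rep(1L, length(parts))
  exps[has_pow] <- as.integer(sub("^.*\\^", "", parts[has_pow]))
  stats::setNames(exps, syms)
}

#' @rdname label_algebra
#' @export
poly_zero <- function() stats::setNames(numeric(0), character(0))

#' @rdname label_algebra
#' @export
poly_const <- function(c) {
  if (c == 0) return(poly_zero())
  stats::setNames(as.numeric(c), "1")
}

#' @rdname label_algebra
#' @export
poly_sym <- function(s) stats::setNames(1, s)

#' @rdname label_algebra
#' @export
poly_is_zero <- function(p) length(p) == 0

#' @noRd
poly_canon <- function(p) {
  p <- p[p != 0]
  if (length(p) == 0) return(poly_zero())
  p[order(names(p), method = "radix")]
}

#' @rdname label_algebra
#' @export
poly_add <- function(p, q) {
  if (length(p) == 0) return(poly_canon(q))
  if (length(q) == 0) return(poly_canon(p))
  keys <- union(names(p), names(q))
  out <- stats::setNames(numeric(length(keys)), keys)
  out[names(p)] <- p
  out[names(q)] <- out[names(q)] + q
  poly_canon(out)
}

#' @rdname label_algebra
#' @export
poly_sum <- function(ps) Reduce(poly_add, ps, poly_zero())

#' @rdname label_algebra
#' @export
poly_scale <- function(p, c) poly_canon(p * c)

#' @rdname label_algebra
#' @export
poly_mul <- function(p, q) {
  if (length(p) == 0 || length(q) == 0) return(poly_zero())
  pe <- lapply(names(p), key_exps)
  qe <- lapply(names(q), key_exps)
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(p)) {
    for (j in seq_along(q)) {
      e <- pe[[i]]
      f <- qe[[j]]
      if (length(f)) {
        shared <- intersect(names(e), names(f))
        e[shared] <- e[shared] + f[shared]
        e <- c(e, f[setdiff(names(f), shared)])
      }
      k <- mono_key(e)
      prev <- acc[[k]]
      acc[[k]] <- if (is.null(prev)) p[[i]] * q[[j]] else prev + p[[i]] * q[[j]]
    }
  }
  keys <- ls(acc, sorted = FALSE)
  poly_canon(stats::setNames(vapply(keys, function(k) acc[[k]], numeric(1)), keys))
}

#' @rdname label_algebra
#' @export
poly_prod <- function(ps) Reduce(poly_mul, ps, poly_const(1))

#' @rdname label_algebra
#' @export
poly_vars <- function(p) {
  if (length(p) == 0) return(character(0))
  sort(unique(unlist(lapply(names(p), function(k) names(key_exps(k))))))
}

#' @rdname label_algebra
#' @export
poly_eval <- function(p, values) {
  if (length(p) == 0) return(0)
  missing <- setdiff(poly_vars(p), names(values))
  if (length(missing) > 0) {
    lf_stop("UnboundParameter",
            paste0("no value bound for symbol(s): ",
                   paste(missing, collapse = ", ")),
            symbols = missing)
  }
  tot <- 0
  for (i in seq_along(p)) {
    e <- key_exps(names(p)[i])
    tot <- tot + p[[i]] * prod(values[names(e)]^e)
  }
  tot
}

#' @rdname label_algebra
#' @export
poly_degree <- function(p, sym) {
  if (length(p) == 0) return(-Inf)
  max(vapply(names(p), function(k) {
    e <- key_exps(k)
    if (sym %in% names(e)) e[[sym]] else 0L
  }, integer(1)))
}

# Collect p by powers of `sym`: returns a list of coefficient polynomials,
# element d + 1 holding the coefficient of sym^d.
#' @rdname label_algebra
#' @export
poly_collect <- function(p, sym) {
  d <- max(0L, poly_degree(p, sym))
  out <- replicate(d + 1L, poly_zero(), simplify = FALSE)
  for (i in seq_along(p)) {
    e <- key_exps(names(p)[i])
    k <- if (sym %in% names(e)) e[[sym]] else 0L
    rest <- e[names(e) != sym]
    term <- stats::setNames(p[[i]], mono_key(rest))
    out[[k + 1L]] <- poly_add(out[[k + 1L]], term)
  }
  out
}

# Substitute numeric values for a subset of symbols, keeping the rest symbolic.
#' @rdname label_algebra
#' @export
poly_substitute <- function(p, values) {
  if (length(p) == 0) return(p)
  out <- poly_zero()
  for (i in seq_along(p)) {
    e <- key_exps(names(p)[i])
    bound <- names(e) %in% names(values)
    coef <- p[[i]]
    if (any(bound)) coef <- coef * prod(values[names(e)[bound]]^e[bound])
    out <- poly_add(out, stats::setNames(coef, mono_key(e[!bound])))
  }
  out
}

#' @rdname label_algebra
#' @export
poly_equal <- function(p, q, tol = 0) {
  d <- poly_add(p, poly_scale(q, -1))
  if (length(d) == 0) return(TRUE)
  scale <- max(abs(c(p, q, 1)))
  all(abs(d) <= tol * scale)
}

# Reduce p modulo the binomial relation top = rep (both monomial exponent
# vectors): every monomial divisible by `top` is rewritten by dividing out
# `top` and multiplying in `rep`. With `top` lexicographically above `rep`
# the rewriting terminates; a zero normal form certifies membership in the
# ideal generated by (top - rep).
#' @rdname label_algebra
#' @export
poly_reduce_binomial <- function(p, top, rep) {
  repeat {
    changed <- FALSE
    for (i in seq_along(p)) {
      e <- key_exps(names(p)[i])
      full <- stats::setNames(integer(length(top)), names(top))
      full[intersect(names(e), names(top))] <-
        e[intersect(names(e), names(top))]
      if (all(full >= top)) {
        e2 <- e
        for (s in names(top)) {
          e2[s] <- (if (s %in% names(e2)) e2[[s]] else 0L) - top[[s]]
        }
        for (s in names(rep)) {
          e2[s] <- (if (s %in% names(e2)) e2[[s]] else 0L) + rep[[s]]
        }
        coef <- p[[i]]
        p <- p[-i]
        p <- poly_add(p, stats::setNames(coef, mono_key(e2)))
        changed <- TRUE
        break
      }
    }
    if (!changed) return(p)
  }
}

#' @rdname label_algebra
#' @export
poly_format <- function(p) {
  if (length(p) == 0) return("0")
  terms <- vapply(seq_along(p), function(i) {
    k <- names(p)[i]
    c0 <- p[[i]]
    if (k == "1") return(format(c0))
    if (c0 == 1) return(k)
    paste0(format(c0), "*", k)
  }, character(1))
  paste(terms, collapse = " + ")
}

# ---- label grammar ---------------------------------------------------------

# Parse a label expression restricted to {symbols, positive numbers, +, *,
# parentheses} into a polynomial. Subtraction and division are rejected so
# that positivity for positive symbol assignments is guaranteed
# syntactically.
#' Parse a label expression
#'
#' Parses the restricted label grammar (symbols, positive numbers, `+`,
#' `*`, parentheses) into a polynomial; subtraction and division are
#' rejected so labels are guaranteed positive for positive symbol values.
#'
#' @param text label string, e.g. `"k2*x"` or `"koff + kcat"`.
#' @return a polynomial (see [label_algebra]).
#' @export
parse_label <- function(text) {
  expr <- tryCatch(str2lang(text), error = function(e) NULL)
  if (is.null(expr)) {
    lf_stop("UnparseableLabel", paste0("cannot parse label: '", text, "'"),
            label = text)
  }
  walk <- function(e) {
    if (is.numeric(e)) {
      if (e <= 0) {
        lf_stop("UnparseableLabel",
                paste0("non-positive literal in label: '", text, "'"),
                label = text)
      }
      return(poly_const(e))
    }
    if (is.symbol(e)) return(poly_sym(as.character(e)))
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (op == "(") return(walk(e[[2]]))
      if (op == "+" && length(e) == 3) {
        return(poly_add(walk(e[[2]]), walk(e[[3]])))
      }
      if (op == "*" && length(e) == 3) {
        return(poly_mul(walk(e[[2]]), walk(e[[3]])))
      }
      lf_stop("UnparseableLabel",
              paste0("operator '", op, "' not allowed in label: '", text, "'"),
              label = text)
    }
    lf_stop("UnparseableLabel", paste0("cannot parse label: '", text, "'"),
            label = text)
  }
  p <- walk(expr)
  if (poly_is_zero(p)) {
    lf_stop("UnparseableLabel", paste0("label is identically zero: '", text, "'"),
            label = text)
  }
  p
}
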