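#' @title Sparse bivariate polynomials and the index operator calculus
#'
#' @description
#' The M-polynomial of a molecular graph, M(G; x, y) = sum over degree pairs
#' s <= t of m_st x^s y^t (m_st = number of edges whose endpoint degrees are
#' {s, t}), is a generating polynomial from which every standard degree-based
#' topological index can be extracted by a short chain of differential /
#' integral operators.  `bipoly` is the sparse container: a set of terms
#' c * x^i * y^j with exact rational coefficients and exponents.  Exponents
#' are normally positive integers but may become negative or zero transiently
#' under the exponent-shift operator, and fractional under fractional-power
#' operators.
#'
#' @name bipoly
NULL

new_bipoly <- function(i, j, coef, exact = TRUE) {
  i <- rational(i); j <- rational(j); coef <- rational(coef)
  stopifnot(length(i) == length(j), length(i) == length(coef))
  # combine duplicate exponent pairs, drop zero coefficients
  key <- paste(as.character(i), as.character(j))
  if (anyDuplicated(key)) {
    ord <- order(key)
    i <- i[ord]; j <- j[ord]; coef <- coef[ord]; key <- key[ord]
    keep <- !duplicated(key)
    idx <- cumsum(keep)
    cn <- rep(0, max(idx)); cd <- rep(1, max(idx))
    acc <- rational(cn, cd)
    for (k in seq_along(key)) {
      t <- idx[k]
      s <- acc[t] + coef[k]
      acc$num[t] <- s$num; acc$den[t] <- s$den
    }
    i <- i[keep]; j <- j[keep]; coef <- acc
  }
  nz <- coef$num != 0
  structure(list(i = i[nz], j = j[nz], coef = coef[nz]),
            class = "bipoly", exact = exact)
}

#' Construct a bivariate polynomial term by term
#'
#' @param i,j numeric or rational exponent vectors of x and y.
#' @param coef numeric or rational coefficients.
#' @return a `bipoly`.
#' @examples
#' bipoly(c(1, 1), c(2, 3), c(2, 8))   # 2 x y^2 + 8 x y^3
#' @export
bipoly <- function(i = numeric(), j = numeric(), coef = numeric()) {
  new_bipoly(i, j, coef)
}

n_terms <- function(p) length(p$coef)

#' @export
print.bipoly <- function(x, ...) {
  if (n_terms(x) == 0) {
    cat("<bipoly> 0\n")
    return(invisible(x))
  }
  term <- function(k) {
    c_ <- as.character(x$coef[k])
    xs <- as.character(x$i[k]); ys <- as.character(x$j[k])
    out <- if (c_ == "1" && (xs != "0" || ys != "0")) "" else c_
    if (xs != "0") out <- paste0(out, if (nzchar(out)) " " else "",
                                 if (xs == "1") "x" else paste0("x^", xs))
    if (ys != "0") out <- paste0(out, if (nzchar(out)) " " else "",
                                 if (ys == "1") "y" else paste0("y^", ys))
    out
  }
  cat("<bipoly> ", paste(vapply(seq_len(n_terms(x)), term, character(1)),
                         collapse = " + "), "\n", sep = "")
  invisible(x)
}

bp_add <- function(p, q) {
  new_bipoly(r_c(p$i, q$i), r_c(p$j, q$j), r_c(p$coef, q$coef),
             exact = attr(p, "exact") && attr(q, "exact"))
}

bp_scale <- function(p, a) {
  new_bipoly(p$i, p$j, p$coef * rational(a), exact = attr(p, "exact"))
}

#' Evaluate a bivariate polynomial
#'
#' @param p a `bipoly`.
#' @param x,y evaluation point (defaults 1, 1; after the diagonal
#'   substitution operator the polynomial is univariate in x and `y` is
#'   irrelevant because all y-exponents are zero).
#' @return a double.
#' @export
bp_eval <- function(p, x = 1, y = 1) {
  if (n_terms(p) == 0) return(0)
  sum(as.numeric(p$coef) * x^as.numeric(p$i) * y^as.numeric(p$j))
}

#' Exact rational evaluation at x = y = 1 (sum of coefficients)
#' @param p a `bipoly`.
#' @return a `rational` scalar.
#' @export
bp_eval1 <- function(p) {
  if (n_terms(p) == 0) return(rational(0))
  sum(p$coef)
}

#' Build the M-polynomial from a degree-pair edge partition
#'
#' Term (s, t) carries the number of edges whose endpoint degrees are
#' {s, t}; evaluation at x = y = 1 recovers the total edge count.
#'
#' @param partition an [edge_partition].
#' @return a `bipoly`.
#' @examples
#' p <- edge_partition_counts(s = c(1, 1), t = c(2, 3), count = c(1, 8))
#' mpolynomial(p)
#' @export
mpolynomial <- function(partition) {
  partition <- as_edge_partition(partition)
  bipoly(partition$s, partition$t, partition$count)
}

rat_scalar_pow <- function(r, alpha) {
  # r^alpha: exact when alpha integer, floating fallback otherwise
  if (alpha == round(alpha)) {
    list(v = r^alpha, exact = TRUE)
  } else {
    base <- as.numeric(r)
    if (base < 0)
      stop("fractional power of a negative exponent base is undefined")
    list(v = base^alpha, exact = FALSE)
  }
}

apply_one <- function(p, tag, alpha = NULL) {
  i <- p$i; j <- p$j; coef <- p$coef
  exact <- attr(p, "exact")
  need_alpha <- tag %in% c("Q", "Dx^a", "Dy^a", "Sx^a", "Sy^a")
  if (need_alpha && is.null(alpha))
    stop("operator ", tag, " requires a parameter alpha")
  check_nonzero <- function(e, var) {
    bad <- which(e$num == 0)
    if (length(bad))
      stop(sprintf(
        "operator S%s undefined on term %s * x^%s y^%s: zero %s-exponent",
        var, as.character(coef[bad[1]]), as.character(i[bad[1]]),
        as.character(j[bad[1]]), var))
  }
  pow_terms <- function(e, a, invert = FALSE) {
    # per-term multiply coef by e^a (or divide when invert)
    out <- coef
    ex <- exact
    for (k in seq_len(n_terms(p))) {
      r <- rat_scalar_pow(e[k], a)
      # inexact powers carry the double value verbatim (no rationalisation)
      v <- if (r$exact) r$v else rational(r$v)
      ex <- ex && r$exact
      out_k <- if (invert) out[k] / v else out[k] * v
      out$num[k] <- out_k$num; out$den[k] <- out_k$den
    }
    list(coef = out, exact = ex)
  }
  switch(tag,
    "Dx" = new_bipoly(i, j, coef * i, exact),
    "Dy" = new_bipoly(i, j, coef * j, exact),
    "Sx" = { check_nonzero(i, "x"); new_bipoly(i, j, coef / i, exact) },
    "Sy" = { check_nonzero(j, "y"); new_bipoly(i, j, coef / j, exact) },
    "J"  = new_bipoly(i + j, rational(rep(0, n_terms(p))), coef, exact),
    "Q"  = new_bipoly(i + rational_like(alpha), j, coef, exact),
    "Dx^a" = { r <- pow_terms(i, alpha); new_bipoly(i, j, r$coef, r$exact) },
    "Dy^a" = { r <- pow_terms(j, alpha); new_bipoly(i, j, r$coef, r$exact) },
    "Sx^a" = { check_nonzero(i, "x")
               r <- pow_terms(i, alpha, invert = TRUE)
               new_bipoly(i, j, r$coef, r$exact) },
    "Sy^a" = { check_nonzero(j, "y")
               r <- pow_terms(j, alpha, invert = TRUE)
               new_bipoly(i, j, r$coef, r$exact) },
    stop("unknown operator tag: ", tag)
  )
}

rational_like <- function(a) {
  if (inherits(a, "rational")) a else rational_from_double(a)
}

rational_from_double <- function(v, tol = 1e-12, max_den = 1e6) {
  # continued-fraction rationalisation; falls back to v/1 "inexact" storage
  if (v == round(v)) return(rational(v))
  x <- v; n0 <- 0; d0 <- 1; n1 <- 1; d1 <- 0
  for (k in 1:64) {
    a <- floor(x)
    n2 <- a * n1 + n0; d2 <- a * d1 + d0
    if (d2 > max_den) break
    n0 <- n1; d0 <- d1; n1 <- n2; d1 <- d2
    if (abs(n1 / d1 - v) < tol) return(rational(n1, d1))
    fr <- x - a
    if (fr < tol) break
    x <- 1 / fr
  }
  structure(list(num = v, den = 1), class = "rational")
}

#' Apply one calculus operator to a bivariate polynomial
#'
#' Per-term action on c * x^i * y^j:
#' * `Dx` (x d/dx): c * i; `Dy`: c * j.
#' * `Sx` (integral of g(t,y)/t from 0 to x): c / i, requiring i != 0
#'   (likewise `Sy` on j).
#' * `Dx^a` / `Sx^a`: c * i^alpha and c / i^alpha (and the y analogues).
#' * `J`: diagonal substitution g(x, x), collapsing the term to x^(i+j).
#' * `Q` (alpha): multiply by x^alpha, shifting i to i + alpha.
#'
#' Chains are applied right to left as conventionally written; e.g. the
#' augmented Zagreb chain Sx^3 Q(-2) J Dx^3 Dy^3 applies Dy^3 first.
#'
#' @param p a `bipoly`.
#' @param tag one of `"Dx"`, `"Dy"`, `"Sx"`, `"Sy"`, `"J"`, `"Q"`,
#'   `"Dx^a"`, `"Dy^a"`, `"Sx^a"`, `"Sy^a"`.
#' @param alpha rational/numeric parameter for `Q` and the `^a` forms.
#' @return a `bipoly`.
#' @export
apply_operator <- function(p, tag, alpha = NULL) {
  stopifnot(inherits(p, "bipoly"))
  apply_one(p, tag, alpha)
}

#' Apply an operator chain (rightmost operator first)
#'
#' @param p a `bipoly`.
#' @param chain character vector of operator tags, written left to right.
#' @param alpha parameter forwarded to parametrised operators.
#' @return a `bipoly`.
#' @export
apply_chain <- function(p, chain, alpha = NULL) {
  stopifnot(length(chain) >= 1)
  for (tag in rev(chain)) p <- apply_one(p, tag, alpha)
  p
}

#' Derive a topological index from the M-polynomial by operator calculus
#'
#' Builds M(G; x, y) from the edge partition and applies the standard
#' operator chain for the requested index:
#' \describe{
#'   \item{M1}{(Dx + Dy) at x = y = 1}
#'   \item{M2}{(Dx Dy) at x = y = 1}
#'   \item{mM2}{(Sx Sy) at x = y = 1}
#'   \item{Ralpha}{(Dx^a Dy^a) at x = y = 1}
#'   \item{RRalpha}{(Sx^a Sy^a) at x = y = 1}
#'   \item{SDD}{(Dx Sy + Sx Dy) at x = y = 1}
#'   \item{H}{2 (Sx J) at x = 1}
#'   \item{I}{(Sx J Dx Dy) at x = 1}
#'   \item{AZI}{(Sx^3 Q(-2) J Dx^3 Dy^3) at x = 1}
#' }
#' The AZI chain is undefined on (1, 1) degree pairs: after J and Q(-2) the
#' corresponding term has x-exponent zero and Sx^3 raises the
#' undefined-operator error (the per-edge kernel has denominator
#' (d_u + d_v - 2)^3 = 0).
#'
#' @param partition an [edge_partition].
#' @param name index identifier, one of
#'   `"M1","M2","mM2","Ralpha","RRalpha","SDD","H","I","AZI"`.
#' @param alpha exponent parameter, required for `Ralpha`/`RRalpha`.
#' @return a double.
#' @examples
#' p <- edge_partition_counts(s = 1, t = 2, count = 2)  # path a-b-c
#' index_from_operators(p, "M1")  # 6
#' @export
index_from_operators <- function(partition, name, alpha = NULL) {
  m <- mpolynomial(partition)
  switch(match.arg(name, index_names()),
    M1  = bp_eval(bp_add(apply_one(m, "Dx"), apply_one(m, "Dy"))),
    M2  = bp_eval(apply_chain(m, c("Dx", "Dy"))),
    mM2 = bp_eval(apply_chain(m, c("Sx", "Sy"))),
    Ralpha = {
      if (is.null(alpha)) stop("Ralpha requires alpha")
      bp_eval(apply_chain(m, c("Dx^a", "Dy^a"), alpha))
    },
    RRalpha = {
      if (is.null(alpha)) stop("RRalpha requires alpha")
      bp_eval(apply_chain(m, c("Sx^a", "Sy^a"), alpha))
    },
    SDD = bp_eval(bp_add(apply_chain(m, c("Dx", "Sy")),
                         apply_chain(m, c("Sx", "Dy")))),
    H   = 2 * bp_eval(apply_chain(m, c("Sx", "J")), x = 1),
    I   = bp_eval(apply_chain(m, c("Sx", "J", "Dx", "Dy")), x = 1),
    AZI = {
      p <- apply_chain(m, c("Dx^a", "Dy^a"), alpha = 3)
      p <- apply_one(p, "J")
      p <- apply_one(p, "Q", alpha = -2)
      p <- apply_one(p, "Sx^a", alpha = 3)
      bp_eval(p, x = 1)
    }
  )
}

#' Serialise a bivariate polynomial to JSON
#'
#' Terms are written as objects `{"i": "num/den", "j": ..., "coeff": ...}`
#' with rationals as strings, so the round trip is exact.
#'
#' @param p a `bipoly`.
#' @return a JSON string.
#' @export
bipoly_to_json <- function(p) {
  terms <- lapply(seq_len(n_terms(p)), function(k) {
    list(i = as.character(p$i[k]), j = as.character(p$j[k]),
         coeff = as.character(p$coef[k]))
  })
  jsonlite::toJSON(terms, auto_unbox = TRUE)
}

#' @rdname bipoly_to_json
#' @param json a JSON string produced by `bipoly_to_json`.
#' @export
bipoly_from_json <- function(json) {
  terms <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (length(terms) == 0) return(bipoly())
  new_bipoly(
    parse_rational(vapply(terms, `[[`, "", "i")),
    parse_rational(vapply(terms, `[[`, "", "j")),
    parse_rational(vapply(terms, `[[`, "", "coeff"))
  )
}
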