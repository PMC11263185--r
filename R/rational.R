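#' @title Exact rational arithmetic
#' @description A minimal vectorised rational-number layer used by the
#'   M-polynomial engine and the closed-form machinery.  Numerators and
#'   denominators are kept as doubles holding exact integers (all quantities
#'   arising from degree-based index calculus on chemical graphs are tiny);
#'   every operation reduces by the gcd so equality is structural.
#'   Conversion to floating point happens only at final evaluation.
#' @name rational
NULL

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    r <- a %% b
    a <- ifelse(b > 0, b, a)
    b <- ifelse(b > 0, r, 0)
  }
  a
}

#' Construct a rational vector
#'
#' @param num numeric vector of integer-valued numerators.
#' @param den numeric vector of integer-valued denominators (recycled).
#' @return an object of class `rational`.
#' @examples
#' rational(6, 4)            # 3/2
#' rational(1:3, 3)          # 1/3, 2/3, 1
#' @export
rational <- function(num, den = 1) {
  if (inherits(num, "rational")) return(num)
  stopifnot(is.numeric(num), is.numeric(den))
  if (any(den == 0)) stop("rational: zero denominator")
  if (length(num) == 0)
    return(structure(list(num = numeric(), den = numeric()),
                     class = "rational"))
  n <- max(length(num), length(den))
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  num <- num * sign(den)
  den <- abs(den)
  # non-integer inputs (arising only from irrational kernels under
  # fractional alpha) are stored as value/1 without reduction: the class
  # degrades gracefully to floating point there
  frac <- num != round(num) | den != round(den)
  if (any(frac)) {
    num[frac] <- num[frac] / den[frac]
    den[frac] <- 1
  }
  g <- rep(1, n)
  g[!frac] <- gcd2(num[!frac], den[!frac])
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rational")
}

r_len <- function(x) length(x$num)

r_recycle <- function(x, y) {
  n <- max(r_len(x), r_len(y))
  list(
    x = rational(rep_len(x$num, n), rep_len(x$den, n)),
    y = rational(rep_len(y$num, n), rep_len(y$den, n))
  )
}

#' @export
Ops.rational <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(rational(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rational")
  }
  e1 <- if (inherits(e1, "rational")) e1 else rational(e1)
  e2r <- inherits(e2, "rational")
  if (.Generic == "^") {
    # exponent must be a plain integer-valued numeric; exactness preserved
    p <- if (e2r) as.numeric(e2) else e2
    if (any(p != round(p)))
      stop("rational ^: non-integer exponent; use floating point explicitly")
    n <- max(r_len(e1), length(p))
    p <- rep_len(p, n)
    nn <- rep_len(e1$num, n); dd <- rep_len(e1$den, n)
    num <- ifelse(p >= 0, nn^p, dd^abs(p))
    den <- ifelse(p >= 0, dd^p, nn^abs(p))
    if (any(den == 0)) stop("rational ^: zero raised to a negative power")
    return(rational(num, den))
  }
  e2 <- if (e2r) e2 else rational(e2)
  b <- r_recycle(e1, e2)
  x <- b$x; y <- b$y
  switch(.Generic,
    "+" = rational(x$num * y$den + y$num * x$den, x$den * y$den),
    "-" = rational(x$num * y$den - y$num * x$den, x$den * y$den),
    "*" = rational(x$num * y$num, x$den * y$den),
    "/" = {
      if (any(y$num == 0)) stop("rational division by zero")
      rational(x$num * y$den, x$den * y$num)
    },
    "==" = x$num == y$num & x$den == y$den,
    "!=" = !(x$num == y$num & x$den == y$den),
    "<"  = x$num * y$den <  y$num * x$den,
    ">"  = x$num * y$den >  y$num * x$den,
    "<=" = x$num * y$den <= y$num * x$den,
    ">=" = x$num * y$den >= y$num * x$den,
    stop(.Generic, " not defined for rational")
  )
}

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
as.character.rational <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%.0f", x$num),
         sprintf("%.0f/%.0f", x$num, x$den))
}

#' @export
format.rational <- function(x, ...) as.character(x)

#' @export
print.rational <- function(x, ...) {
  cat("<rational> ", paste(as.character(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.rational <- function(x) r_len(x)

#' @export
`[.rational` <- function(x, i) rational(x$num[i], x$den[i])

#' @export
sum.rational <- function(..., na.rm = FALSE) {
  xs <- list(...)
  acc <- rational(0)
  for (x in xs) {
    x <- rational(x)
    for (k in seq_len(r_len(x))) acc <- acc + x[k]
  }
  acc
}

r_c <- function(...) {
  xs <- lapply(list(...), rational)
  rational(unlist(lapply(xs, `[[`, "num")), unlist(lapply(xs, `[[`, "den")))
}

#' Parse "num/den" strings into a rational vector
#'
#' @param s character vector such as `"3/2"` or `"-7"`.
#' @return a `rational`.
#' @export
parse_rational <- function(s) {
  parts <- strsplit(as.character(s), "/", fixed = TRUE)
  num <- vapply(parts, function(p) as.numeric(p[[1]]), numeric(1))
  den <- vapply(parts, function(p) if (length(p) > 1) as.numeric(p[[2]]) else 1,
                numeric(1))
  rational(num, den)
}
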