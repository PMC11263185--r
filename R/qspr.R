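#' @title QSPR regression of properties on topological indices
#'
#' @description
#' Quantitative structure-property relationship models relating one
#' physicochemical property P to one topological index TI at a time, in
#' three forms: linear P = A + B*TI, quadratic P = A + B*TI + C*TI^2, and
#' logarithmic P = A + B*ln(TI) (natural log).  Fits are ordinary least
#' squares; reporting follows the multiple-R convention: r = sqrt(r^2) is
#' nonnegative even for negative slopes, F = (r^2/k) / ((1-r^2)/(n-k-1))
#' with k predictors, and p is the upper tail of F(k, n-k-1).
#' @name qspr
NULL

qspr_forms <- function() c("linear", "quadratic", "logarithmic")

#' Fit one property-index regression
#'
#' @param form `"linear"`, `"quadratic"` or `"logarithmic"`.
#' @param x index values (all positive for the logarithmic form).
#' @param y property values.
#' @return an object of class `qspr_fit`: list with `form`, coefficients
#'   `A`, `B` (and `C` for quadratic), `r`, `r_squared`, `F`, `p`, `n_obs`,
#'   and the underlying `lm` fit.
#' @examples
#' fit_qspr("linear", x = c(1, 2, 3, 4, 5), y = c(2.1, 3.9, 6.2, 8.1, 9.9))
#' @export
fit_qspr <- function(form, x, y) {
  form <- match.arg(form, qspr_forms())
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(y) != length(x)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  k <- if (form == "quadratic") 2L else 1L
  n <- length(x)
  if (n < k + 2) stop("need at least ", k + 2, " observations for the ",
                      form, " form")
  if (stats::var(x) == 0) stop("degenerate fit: zero variance in x")
  if (form == "logarithmic" && any(x <= 0))
    stop("logarithmic form requires all index values > 0")
  dat <- switch(form,
    linear      = data.frame(y = y, x1 = x),
    quadratic   = data.frame(y = y, x1 = x, x2 = x^2),
    logarithmic = data.frame(y = y, x1 = log(x)))
  mod <- stats::lm(y ~ ., data = dat)
  cf <- stats::coef(mod)
  sse <- sum(stats::residuals(mod)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  r2 <- min(max(r2, 0), 1)
  Fst <- if (r2 >= 1) Inf else (r2 / k) / ((1 - r2) / (n - k - 1))
  p <- stats::pf(Fst, k, n - k - 1, lower.tail = FALSE)
  structure(list(
    form = form, A = unname(cf[1]), B = unname(cf[2]),
    C = if (form == "quadratic") unname(cf[3]) else NA_real_,
    r = sqrt(r2), r_squared = r2, F = Fst, p = p, n_obs = n, lm = mod),
    class = "qspr_fit")
}

#' @export
print.qspr_fit <- function(x, ...) {
  eq <- switch(x$form,
    linear = sprintf("P = %.3f + %.3f TI", x$A, x$B),
    quadratic = sprintf("P = %.3f + %.3f TI + %.3f TI^2", x$A, x$B, x$C),
    logarithmic = sprintf("P = %.3f + %.3f ln(TI)", x$A, x$B))
  cat("<qspr_fit> ", eq, "\n", sprintf(
    "  r = %.3f  r^2 = %.3f  F = %.3f  p = %.4g  n = %d",
    x$r, x$r_squared, x$F, x$p, x$n_obs), "\n", sep = "")
  invisible(x)
}

#' Batch property-index regression report
#'
#' Fits every (property, index, form) combination: by default the 5
#' packaged properties x 7 indices x 3 forms = 105 models.  The default
#' index input is the as-published table (what the original models were
#' fitted to); `recomputed = TRUE` switches to indices recomputed from the
#' partitions.  The physically implausible published raffinose density is
#' excluded from density fits unless `exclude_anomalous_density = FALSE`.
#'
#' @param properties data frame with a `structure` column and property
#'   columns; defaults to [load_properties()].
#' @param indices data frame with a `structure` column and index columns;
#'   defaults to [load_published_indices()].
#' @param forms subset of `c("linear", "quadratic", "logarithmic")`.
#' @param recomputed use [recomputed_indices()] instead of the published
#'   table (only when `indices` is not supplied).
#' @param exclude_anomalous_density drop raffinose from density fits.
#' @return data frame with columns `property, index, form, A, B, C, r, r2,
#'   F, p, n`.
#' @export
qspr_report <- function(properties = NULL, indices = NULL,
                        forms = qspr_forms(), recomputed = FALSE,
                        exclude_anomalous_density = TRUE) {
  if (is.null(properties)) properties <- load_properties()
  if (is.null(indices))
    indices <- if (recomputed) recomputed_indices() else
      load_published_indices()
  forms <- vapply(forms, function(f) match.arg(f, qspr_forms()), "")
  if (!"structure" %in% names(properties) ||
      !"structure" %in% names(indices))
    stop("both tables need a 'structure' column")
  properties$structure <- canon_structure(properties$structure)
  indices$structure <- canon_structure(indices$structure)
  common <- intersect(properties$structure, indices$structure)
  if (length(common) < 3)
    stop("tables align on ", length(common),
         " structures; at least 3 are required")
  properties <- properties[match(common, properties$structure), ]
  indices <- indices[match(common, indices$structure), ]
  prop_cols <- setdiff(names(properties), "structure")
  idx_cols <- setdiff(names(indices), "structure")
  rows <- list()
  for (pcol in prop_cols) for (icol in idx_cols) for (f in forms) {
    keep <- rep(TRUE, length(common))
    if (pcol == "density" && exclude_anomalous_density)
      keep <- common != "raffinose"
    fit <- fit_qspr(f, indices[[icol]][keep], properties[[pcol]][keep])
    rows[[length(rows) + 1]] <- data.frame(
      property = pcol, index = icol, form = f,
      A = fit$A, B = fit$B, C = fit$C,
      r = fit$r, r2 = fit$r_squared, F = fit$F, p = fit$p, n = fit$n_obs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic (index, property) data for a known model
#'
#' Draws x uniformly on a positive range and sets y = model(x) plus
#' independent Gaussian noise; used for coefficient-recovery and
#' calibration checks of the fitting code.
#'
#' @param n number of observations (>= 5).
#' @param form model form; see [qspr_forms()].
#' @param coefficients named vector with `A`, `B` (and `C` for quadratic).
#' @param noise_sd standard deviation of the additive noise (>= 0).
#' @param seed integer seed; identical seeds give identical data.
#' @param x_range positive range from which x is drawn (default 1 to 50).
#' @return list with numeric vectors `x` and `y`.
#' @export
synthetic_qspr_data <- function(n, form, coefficients, noise_sd = 0,
                                seed = 1, x_range = c(1, 50)) {
  stopifnot(n >= 5, noise_sd >= 0, x_range[1] > 0, x_range[2] > x_range[1])
  form <- match.arg(form, qspr_forms())
  A <- coefficients[["A"]]; B <- coefficients[["B"]]
  C <- if (form == "quadratic") coefficients[["C"]] else 0
  with_seed(seed, {
    x <- stats::runif(n, x_range[1], x_range[2])
    mu <- switch(form,
      linear = A + B * x,
      quadratic = A + B * x + C * x^2,
      logarithmic = A + B * log(x))
    y <- mu + stats::rnorm(n, sd = noise_sd)
    list(x = x, y = y)
  })
}
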