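#' @title Parametric polysaccharide graph families
#'
#' @description
#' Guar gum is a galactomannan polysaccharide; its hydroxypropyl (HPG),
#' carboxymethyl (CMG) and carboxymethyl-hydroxypropyl (CMHPG) derivatives
#' are the industrially common variants.  Modelled as hydrogen-suppressed
#' repeat-unit graphs indexed by the repeat count n, their degree-pair edge
#' partitions are linear in n, which makes every degree-based index linear
#' in n with an exact rational closed form (see [closed_form()]).  The
#' families are defined directly by their partition formulas; HPG and CMG
#' share one partition and are two display names for the same object.
#' @name families
NULL

family_defs <- function() {
  lin <- function(s, t, slope, intercept)
    data.frame(s = s, t = t, slope = slope, intercept = intercept)
  list(
    guar_gum = lin(c(1, 1, 2, 2, 3), c(2, 3, 2, 3, 3),
                   slope = c(0, 7, 2, 14, 9), intercept = c(1, 1, 0, -1, 0)),
    hpg      = lin(c(1, 1, 2, 2, 3), c(2, 3, 2, 3, 3),
                   slope = c(2, 7, 4, 14, 12), intercept = c(1, 1, 0, -1, 0)),
    cmhpg    = lin(c(1, 1, 2, 2, 3), c(2, 3, 2, 3, 3),
                   slope = c(3, 6, 5, 15, 12), intercept = c(1, 1, 0, -1, 0))
  )
}

#' Names of the built-in polysaccharide families
#' @return character vector: `guar_gum`, `hpg`, `cmg`, `cmhpg`.
#' @export
family_names <- function() c("guar_gum", "hpg", "cmg", "cmhpg")

#' Parametric edge partition of a polysaccharide family
#'
#' Each degree pair maps to a count linear in the repeat count n:
#' \describe{
#'   \item{guar_gum}{(1,2): 1, (1,3): 7n+1, (2,2): 2n, (2,3): 14n-1,
#'     (3,3): 9n}
#'   \item{hpg / cmg}{(1,2): 2n+1, (1,3): 7n+1, (2,2): 4n, (2,3): 14n-1,
#'     (3,3): 12n}
#'   \item{cmhpg}{(1,2): 3n+1, (1,3): 6n+1, (2,2): 5n, (2,3): 15n-1,
#'     (3,3): 12n}
#' }
#'
#' @param name one of `"guar_gum"`, `"hpg"`, `"cmg"`, `"cmhpg"`
#'   (case-insensitive; `hpg` and `cmg` alias the same partition).
#' @return an object of class `parametric_partition` with fields `family`
#'   (the canonical key) and `counts` (data frame `s`, `t`, `slope`,
#'   `intercept`).
#' @examples
#' family_partition("guar_gum")
#' @export
family_partition <- function(name) {
  key <- tolower(as.character(name)[1])
  if (!key %in% family_names())
    stop("unknown family '", name, "'; valid names: ",
         paste(family_names(), collapse = ", "))
  canonical <- if (key == "cmg") "hpg" else key
  structure(list(family = canonical, display = key,
                 counts = family_defs()[[canonical]]),
            class = "parametric_partition")
}

#' @export
print.parametric_partition <- function(x, ...) {
  cat("<parametric_partition> family:", x$display,
      if (x$display != x$family) paste0("(= ", x$family, ")"), "\n")
  for (k in seq_len(nrow(x$counts))) {
    r <- x$counts[k, ]
    cat(sprintf("  (%d,%d): %s\n", r$s, r$t,
                if (r$slope == 0) r$intercept else
                  paste0(r$slope, "n", if (r$intercept > 0)
                    paste0("+", r$intercept) else
                      if (r$intercept < 0) r$intercept else "")))
  }
  invisible(x)
}

#' Instantiate a parametric partition at a repeat count
#'
#' @param param a [family_partition()] result.
#' @param n integer repeat count, >= 1 (the counts 14n-1 etc. must stay
#'   nonnegative integers).
#' @return an [edge_partition].
#' @examples
#' instantiate(family_partition("guar_gum"), 1)  # 33 edges in total
#' @export
instantiate <- function(param, n) {
  stopifnot(inherits(param, "parametric_partition"))
  if (length(n) != 1 || n < 1 || n != round(n))
    stop("repeat count n must be a single integer >= 1")
  counts <- param$counts$slope * n + param$counts$intercept
  new_edge_partition(param$counts$s, param$counts$t, counts)
}

#' Per-n index table for a family (the data behind family comparisons)
#'
#' @param name family name.
#' @param n_range integer vector of repeat counts.
#' @param indices index identifiers (see [index_names()]).
#' @param alpha forwarded to `Ralpha`/`RRalpha`.
#' @param digits presentation rounding; `NA` for full precision.
#' @return data frame with columns `family`, `n`, one column per index;
#'   every column is exactly linear in n.
#' @export
family_index_table <- function(name, n_range = 1:5,
                               indices = c("H", "I", "AZI", "M1", "M2",
                                           "mM2", "SDD"),
                               alpha = NULL, digits = 4) {
  fam <- family_partition(name)
  parts <- lapply(n_range, function(n) instantiate(fam, n))
  names(parts) <- as.character(n_range)
  tab <- index_table(parts, indices = indices, alpha = alpha, digits = digits)
  data.frame(family = fam$display, n = n_range,
             tab[setdiff(names(tab), "structure")],
             check.names = FALSE)
}
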