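#' @title Packaged carbohydrate fixtures
#'
#' @description
#' Degree-pair edge partitions, physicochemical properties, and an
#' as-published index table for eight small carbohydrates (arabinose,
#' galactose, maltose, sucrose, sorbose, ribose, hydroxymethyl furfural,
#' raffinose).  The data ship as plain CSV under `extdata` so the
#' command-line interface can treat them like any user-supplied input.
#' The canonical name for hydroxymethyl furfural is `hmf`; `hmp` is
#' accepted as an alias where names are looked up.
#' @name carbo_data
NULL

extdata <- function(file) {
  path <- system.file("extdata", file, package = "mpolyindex")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

canon_structure <- function(x) {
  x <- tolower(x)
  x[x == "hmp"] <- "hmf"
  x
}

#' Load the packaged carbohydrate edge partitions
#'
#' @return named list of [edge_partition] objects (eight structures).
#' @examples
#' partition_size(load_partitions()$arabinose)  # 10
#' @export
load_partitions <- function() {
  df <- utils::read.csv(extdata("carbohydrate_partitions.csv"))
  out <- lapply(split(df, df$structure), function(d)
    edge_partition_counts(d$s, d$t, d$count))
  out[unique(df$structure)]
}

#' Load the packaged physicochemical property table
#'
#' Columns: density (g/cm^3), bp (boiling point, deg C), mp (melting point,
#' deg C), mw (molecular weight, g/mol), ws (water solubility, g/L).  The
#' raffinose density is preserved exactly as published (884.8 g/cm^3)
#' although it is physically implausible by three orders of magnitude;
#' density regressions exclude it by default (see [qspr_report()]).
#'
#' @return data frame keyed by `structure`.
#' @export
load_properties <- function() {
  utils::read.csv(extdata("carbohydrate_properties.csv"))
}

#' Load the as-published index table
#'
#' The published table verbatim, including its internal inconsistencies
#' with the published edge partitions (see [audit_published_indices()]).
#' This is the default regression input of [qspr_report()], since it is
#' what the original property models were fitted to.
#'
#' @return data frame keyed by `structure` with columns
#'   `H, I, AZI, M1, M2, mM2, SDD`.
#' @export
load_published_indices <- function() {
  utils::read.csv(extdata("published_indices.csv"))
}

#' Recompute the index table from the packaged partitions
#'
#' @param digits presentation rounding (default 4, half-up).
#' @return data frame in the same layout as [load_published_indices()].
#' @export
recomputed_indices <- function(digits = 4) {
  index_table(load_partitions(), digits = digits)
}

#' Audit the published index table against the partitions
#'
#' Recomputes every cell of the index table from the packaged edge
#' partitions in exact rational arithmetic and diffs it against the
#' published values at 4-decimal presentation.  Twelve cells disagree:
#' galactose M1, maltose M2, sorbose H and I, ribose AZI, raffinose mM2,
#' and the whole hydroxymethyl-furfural row except H.
#'
#' @return data frame with columns `structure`, `index`, `published`,
#'   `recomputed` — one row per deviating cell.
#' @export
audit_published_indices <- function() {
  pub <- load_published_indices()
  rec <- recomputed_indices()
  idx <- setdiff(names(pub), "structure")
  rows <- list()
  for (k in seq_len(nrow(pub))) {
    st <- pub$structure[k]
    r <- rec[rec$structure == st, ]
    for (i in idx) {
      if (abs(pub[[i]][k] - r[[i]]) > 1e-9)
        rows[[length(rows) + 1]] <- data.frame(
          structure = st, index = i,
          published = pub[[i]][k], recomputed = r[[i]])
    }
  }
  if (length(rows) == 0)
    return(data.frame(structure = character(), index = character(),
                      published = numeric(), recomputed = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
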