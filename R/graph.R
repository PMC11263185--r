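#' @title Hydrogen-suppressed molecular graphs
#'
#' @description
#' A molecular graph here is the hydrogen-suppressed skeleton: a simple
#' undirected graph whose vertices are heavy atoms and whose degrees count
#' heavy-atom neighbours only.  Every degree-based index in this package
#' depends on the graph solely through its degree-pair edge partition, so
#' vertex identifiers are opaque strings and element labels are purely
#' informational.
#' @name molecular_graph
NULL

norm_edges <- function(from, to) {
  a <- ifelse(from <= to, from, to)
  b <- ifelse(from <= to, to, from)
  e <- unique(data.frame(from = a, to = b, stringsAsFactors = FALSE))
  e[order(e$from, e$to), , drop = FALSE]
}

#' Construct a molecular graph from an edge list
#'
#' The graph must be simple: self-loops are rejected, duplicate edges
#' (multi-bonds) are collapsed to one.  The vertex set is taken from the
#' edge endpoints, so every vertex has degree at least one.  Disconnected
#' input is allowed with a warning: every index here is edge-local.
#'
#' @param from,to character (or coercible) vectors of edge endpoints.
#' @param labels optional named character vector mapping vertex identifiers
#'   to element symbols (informational only).
#' @return an object of class `molecular_graph`.
#' @examples
#' g <- molecular_graph(c("a", "b"), c("b", "c"))  # path a-b-c
#' degrees(g)
#' @export
molecular_graph <- function(from, to, labels = NULL) {
  from <- as.character(from); to <- as.character(to)
  stopifnot(length(from) == length(to))
  if (length(from) == 0) stop("empty graph: no edges")
  loop <- from == to
  if (any(loop))
    stop("self-loop at vertex '", from[which(loop)[1]], "' is not allowed")
  edges <- norm_edges(from, to)
  vertices <- sort(unique(c(edges$from, edges$to)))
  g <- structure(list(vertices = vertices, edges = edges, labels = labels),
                 class = "molecular_graph")
  ig <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!igraph::is_connected(ig))
    warning("graph is disconnected (", igraph::count_components(ig),
            " components); degree-based indices remain well-defined")
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", length(x$vertices), " vertices, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Vertex degrees of a molecular graph
#'
#' @param graph a [molecular_graph].
#' @return named integer vector: heavy-atom neighbour count per vertex.
#' @export
degrees <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  tab <- table(c(graph$edges$from, graph$edges$to))
  d <- as.integer(tab)
  names(d) <- names(tab)
  d[graph$vertices]
}

# ---- edge partition -------------------------------------------------------

new_edge_partition <- function(s, t, count) {
  s <- as.integer(s); t <- as.integer(t); count <- as.numeric(count)
  if (any(count != round(count)) || any(count < 0))
    stop("edge partition counts must be nonnegative integers")
  lo <- pmin(s, t); hi <- pmax(s, t)
  if (any(lo < 1)) stop("degrees in an edge partition must be >= 1")
  df <- aggregate(count ~ s + t,
                  data = data.frame(s = lo, t = hi, count = count), FUN = sum)
  df <- df[df$count > 0, , drop = FALSE]
  df <- df[order(df$s, df$t), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("edge_partition", "data.frame"))
}

#' Construct a degree-pair edge partition from explicit counts
#'
#' @param s,t integer degree vectors; keys are normalised so s <= t.
#' @param count nonnegative integer edge counts per pair.
#' @return an `edge_partition` (a data frame with columns `s`, `t`, `count`).
#' @examples
#' edge_partition_counts(s = c(1, 2), t = c(3, 3), count = c(4, 2))
#' @export
edge_partition_counts <- function(s, t, count) new_edge_partition(s, t, count)

#' Coerce to an edge partition
#'
#' @param x an `edge_partition`, a data frame with columns `s`, `t`,
#'   `count`, or a [molecular_graph].
#' @return an `edge_partition`.
#' @export
as_edge_partition <- function(x) {
  if (inherits(x, "edge_partition")) return(x)
  if (inherits(x, "molecular_graph")) return(edge_partition(x))
  if (is.data.frame(x) && all(c("s", "t", "count") %in% names(x)))
    return(new_edge_partition(x$s, x$t, x$count))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to edge_partition")
}

#' Degree-pair edge partition of a molecular graph
#'
#' Groups the edges by the unordered degree pair {d_u, d_v} of their
#' endpoints; the partition is the universal input of every index in this
#' package and is invariant under vertex relabelling.
#'
#' @param graph a [molecular_graph].
#' @return an `edge_partition`; total count equals the number of edges.
#' @examples
#' edge_partition(molecular_graph(c("a", "b"), c("b", "c")))  # {(1,2): 2}
#' @export
edge_partition <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  d <- degrees(graph)
  du <- d[graph$edges$from]
  dv <- d[graph$edges$to]
  new_edge_partition(pmin(du, dv), pmax(du, dv), rep(1, length(du)))
}

#' Total number of edges in a partition
#' @param partition an `edge_partition`.
#' @return integer edge count.
#' @export
partition_size <- function(partition) {
  sum(as_edge_partition(partition)$count)
}

# ---- file formats ---------------------------------------------------------

#' Read a molecular graph from an edge-list text file
#'
#' One edge per line, two whitespace-separated vertex tokens; `#` starts a
#' comment; blank lines ignored; duplicate lines collapse to one edge.
#'
#' @param path file path.
#' @return a [molecular_graph].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) stop("empty graph: no edges in '", path, "'")
  from <- character(length(keep)); to <- character(length(keep))
  for (k in seq_along(keep)) {
    tok <- strsplit(trimws(lines[keep[k]]), "[[:space:]]+")[[1]]
    if (length(tok) != 2)
      stop("malformed edge-list line ", keep[k], " in '", path,
           "': expected two vertex tokens, got ", length(tok))
    if (tok[1] == tok[2])
      stop("malformed edge-list line ", keep[k], " in '", path,
           "': self-loop at vertex '", tok[1], "'")
    from[k] <- tok[1]; to[k] <- tok[2]
  }
  molecular_graph(from, to)
}

#' Read / write an edge partition as CSV
#'
#' The format is a plain CSV with header `s,t,count` and integer cells;
#' the round trip is bit-exact.
#'
#' @param path file path.
#' @return `read_partition_csv`: an `edge_partition`.
#' @export
read_partition_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "integer")
  if (!all(c("s", "t", "count") %in% names(df)))
    stop("partition CSV '", path, "' must have header s,t,count")
  new_edge_partition(df$s, df$t, df$count)
}

#' @rdname read_partition_csv
#' @param partition an `edge_partition`.
#' @export
write_partition_csv <- function(partition, path) {
  partition <- as_edge_partition(partition)
  utils::write.csv(as.data.frame(partition)[c("s", "t", "count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- random chemical graphs ----------------------------------------------

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a seeded random chemical graph
#'
#' Produces a connected simple graph with all degrees in [1, max_degree],
#' emulating a hydrogen-suppressed organic skeleton (valence cap 4 by
#' default).  A random spanning tree is grown under the degree cap, then a
#' random number of extra edges are added where the cap allows, so trees,
#' rings and fused rings all occur.  Output is a deterministic function of
#' the seed.
#'
#' @param n_vertices number of heavy atoms, >= 2.
#' @param max_degree maximum degree, in [2, 4].
#' @param seed integer seed.
#' @return a [molecular_graph] with vertices `v1 ... vn`.
#' @export
random_chemical_graph <- function(n_vertices, max_degree = 4, seed = 1) {
  stopifnot(n_vertices >= 2)
  if (max_degree < 2 || max_degree > 4)
    stop("max_degree must be in [2, 4]")
  with_seed(seed, {
    deg <- integer(n_vertices)
    from <- integer(0); to <- integer(0)
    for (v in 2:n_vertices) {
      open <- which(deg[seq_len(v - 1)] < max_degree)
      if (length(open) == 0)
        stop("infeasible degree constraint while growing the tree")
      u <- if (length(open) == 1) open else sample(open, 1)
      from <- c(from, u); to <- c(to, v)
      deg[u] <- deg[u] + 1; deg[v] <- deg[v] + 1
    }
    n_extra <- sample(0:max(1, n_vertices %/% 3), 1)
    have <- paste(from, to)
    tries <- 0
    while (n_extra > 0 && tries < 50 * n_vertices) {
      tries <- tries + 1
      uv <- sort(sample.int(n_vertices, 2))
      key <- paste(uv[1], uv[2])
      if (key %in% have) next
      if (deg[uv[1]] >= max_degree || deg[uv[2]] >= max_degree) next
      from <- c(from, uv[1]); to <- c(to, uv[2])
      deg[uv[1]] <- deg[uv[1]] + 1; deg[uv[2]] <- deg[uv[2]] + 1
      have <- c(have, key)
      n_extra <- n_extra - 1
    }
    molecular_graph(paste0("v", from), paste0("v", to))
  })
}

# ---- optional chemistry-format ingestion ---------------------------------

strip_hydrogens <- function(atoms, bonds) {
  # atoms: data.frame(id, symbol); bonds: data.frame(a1, a2)
  heavy <- atoms$id[atoms$symbol != "H"]
  keep <- bonds$a1 %in% heavy & bonds$a2 %in% heavy
  bonds <- bonds[keep, , drop = FALSE]
  if (nrow(bonds) == 0) stop("no heavy-atom bonds after hydrogen suppression")
  labels <- stats::setNames(atoms$symbol, atoms$id)
  molecular_graph(bonds$a1, bonds$a2, labels = labels[unique(c(bonds$a1, bonds$a2))])
}

#' Read a molecule file / SMILES string into a hydrogen-suppressed graph
#'
#' Convenience interface only (requires the suggested ChemmineR /
#' ChemmineOB packages): the molecule is converted to its heavy-atom
#' skeleton, bond orders are discarded, and all downstream computation uses
#' the degree-pair partition as with any other input.
#'
#' @param path path to a MOL (V2000) / SDF file.
#' @return a [molecular_graph] with element labels.
#' @export
read_mol_file <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("MOL ingestion requires the ChemmineR package")
  sdf <- ChemmineR::read.SDFset(path)[[1]]
  sdf_to_graph(sdf)
}

#' @rdname read_mol_file
#' @param smiles a SMILES string.
#' @export
parse_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("SMILES ingestion requires the ChemmineR and ChemmineOB packages")
  sdf <- ChemmineR::smiles2sdf(smiles)[[1]]
  sdf_to_graph(sdf)
}

sdf_to_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  symbol <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(id = paste0("a", seq_along(symbol)), symbol = symbol,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = paste0("a", bb[, 1]), a2 = paste0("a", bb[, 2]),
                      stringsAsFactors = FALSE)
  strip_hydrogens(atoms, bonds)
}
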