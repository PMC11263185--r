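# Brute-force oracles kept independent of the package internals: they work
# from plain degree lookups and double arithmetic, never from the rational
# engine or the operator chains they are used to check.

# per-edge kernel in plain doubles
oracle_kernel <- function(name, s, t, alpha = NULL) {
  switch(name,
    M1 = s + t, M2 = s * t, mM2 = 1 / (s * t),
    SDD = s / t + t / s, H = 2 / (s + t), I = s * t / (s + t),
    AZI = (s * t / (s + t - 2))^3,
    Ralpha = (s * t)^alpha, RRalpha = (s * t)^(-alpha))
}

# index of a partition by plain double summation
oracle_index <- function(partition, name, alpha = NULL) {
  df <- as.data.frame(partition)
  sum(df$count * oracle_kernel(name, df$s, df$t, alpha))
}

# edge partition by per-edge degree lookup over the raw edge data frame
oracle_partition <- function(graph) {
  e <- graph$edges
  deg <- table(c(e$from, e$to))
  d1 <- as.integer(deg[e$from]); d2 <- as.integer(deg[e$to])
  key <- paste(pmin(d1, d2), pmax(d1, d2))
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  data.frame(s = as.integer(parts[, 1]), t = as.integer(parts[, 2]),
             count = as.integer(tab))
}

alpha_free_indices <- c("M1", "M2", "mM2", "SDD", "H", "I", "AZI")

# run code under a seed without disturbing the session RNG state
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# a small partition with no (1,1) pairs, used across tests
toy_partition <- function() {
  edge_partition_counts(s = c(1, 1, 2, 2, 3), t = c(2, 3, 2, 3, 3),
                        count = c(1, 8, 2, 13, 9))
}
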