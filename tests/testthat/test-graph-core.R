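test_that("degrees count heavy-atom neighbours", {
  path <- molecular_graph(c("a", "b"), c("b", "c"))
  expect_equal(degrees(path), c(a = 1L, b = 2L, c = 1L))
  single <- molecular_graph("a", "b")
  expect_equal(degrees(single), c(a = 1L, b = 1L))
  cyc4 <- molecular_graph(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
  expect_true(all(degrees(cyc4) == 2L))
})

test_that("graph construction enforces simplicity", {
  expect_error(molecular_graph("a", "a"), "self-loop")
  expect_error(molecular_graph(character(), character()), "empty")
  # duplicate and reversed edges collapse to one
  g <- molecular_graph(c("a", "b", "a"), c("b", "a", "b"))
  expect_equal(nrow(g$edges), 1L)
  expect_warning(molecular_graph(c("a", "c"), c("b", "d")), "disconnected")
})

test_that("edge_partition matches trivial cases and sums to |E|", {
  path <- molecular_graph(c("a", "b"), c("b", "c"))
  ep <- edge_partition(path)
  expect_equal(as.data.frame(ep),
               data.frame(s = 1L, t = 2L, count = 2))
  star <- molecular_graph(rep("c0", 3), c("l1", "l2", "l3"))
  eps <- edge_partition(star)
  expect_equal(as.data.frame(eps),
               data.frame(s = 1L, t = 3L, count = 3))
})

test_that("edge_partition equals brute-force per-edge degree lookup", {
  for (seed in c(1, 2, 42)) {
    g <- random_chemical_graph(12, max_degree = 4, seed = seed)
    got <- as.data.frame(edge_partition(g))
    want <- oracle_partition(g)
    got <- got[order(got$s, got$t), ]
    want <- want[order(want$s, want$t), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got$count, want$count)
    expect_equal(got$s, want$s)
    expect_equal(got$t, want$t)
  }
})

test_that("random chemical graphs respect constraints over many seeds", {
  for (seed in 1:200) {
    g <- random_chemical_graph(sample(c(5, 8, 12, 20), 1), 4, seed = seed)
    d <- degrees(g)
    expect_true(all(d >= 1 & d <= 4))
    expect_equal(sum(d), 2L * nrow(g$edges))
    expect_equal(partition_size(edge_partition(g)), nrow(g$edges))
  }
})

test_that("random graph generation is deterministic and degree-capped", {
  g1 <- random_chemical_graph(10, 4, seed = 1)
  g2 <- random_chemical_graph(10, 4, seed = 1)
  expect_identical(g1$edges, g2$edges)
  g3 <- random_chemical_graph(2, 4, seed = 99)
  expect_equal(nrow(g3$edges), 1L)
  g4 <- random_chemical_graph(30, 3, seed = 5)
  expect_true(max(degrees(g4)) <= 3)
  expect_error(random_chemical_graph(10, 1, seed = 1), "max_degree")
})

test_that("edge partitions are invariant under vertex relabelling", {
  for (seed in c(3, 11, 27)) {
    g <- random_chemical_graph(15, 4, seed = seed)
    perm <- with_seed_test(seed, sample(g$vertices))
    names(perm) <- g$vertices
    h <- molecular_graph(unname(perm[g$edges$from]),
                         unname(perm[g$edges$to]))
    expect_equal(as.data.frame(edge_partition(g)),
                 as.data.frame(edge_partition(h)))
  }
})

test_that("edge-list files round-trip with comments and duplicates", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# a comment", "a b", "", "b c  # trailing", "a b"), f)
  g <- read_edge_list(f)
  expect_equal(sort(g$vertices), c("a", "b", "c"))
  expect_equal(nrow(g$edges), 2L)

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a b", "a a"), f2)
  expect_error(read_edge_list(f2), "line 2.*self-loop")
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines("# nothing", f3)
  expect_error(read_edge_list(f3), "empty")
})

test_that("partition CSV round-trips bit-exact", {
  p <- toy_partition()
  f <- withr::local_tempfile(fileext = ".csv")
  write_partition_csv(p, f)
  expect_identical(readLines(f)[1], "s,t,count")
  expect_equal(as.data.frame(read_partition_csv(f)), as.data.frame(p))
})

test_that("partition constructor validates and normalises", {
  expect_error(edge_partition_counts(0, 2, 1), ">= 1")
  expect_error(edge_partition_counts(1, 2, -1), "nonnegative")
  p <- edge_partition_counts(c(3, 1), c(1, 3), c(2, 2))  # unordered keys
  expect_equal(as.data.frame(p), data.frame(s = 1L, t = 3L, count = 4))
})

test_that("MOL ingestion builds the hydrogen-suppressed skeleton", {
  # ethanol C-C-O with explicit hydrogens: heavy skeleton is the 3-path
  mol <- c(
    "ethanol", "  synthetic", "",
    "  9  8  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0000    1.4000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    1.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000   -1.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0000   -1.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000   -1.5000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.0000    1.4000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "  1  4  1  0  0  0  0",
    "  1  5  1  0  0  0  0",
    "  1  6  1  0  0  0  0",
    "  2  7  1  0  0  0  0",
    "  2  8  1  0  0  0  0",
    "  3  9  1  0  0  0  0",
    "M  END", "$$$$")
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(mol, f)
  g <- read_mol_file(f)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(as.data.frame(edge_partition(g)),
               data.frame(s = 1L, t = 2L, count = 2))
})
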