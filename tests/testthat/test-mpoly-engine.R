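test_that("rational arithmetic is exact and reduced", {
  expect_equal(as.character(rational(6, 4)), "3/2")
  expect_true(rational(1, 3) + rational(1, 6) == rational(1, 2))
  expect_true(rational(2, 3) * rational(9, 4) == rational(3, 2))
  expect_true(rational(1, 2)^-2 == rational(4))
  expect_true(rational(-3, -6) == rational(1, 2))
  expect_error(rational(1, 0), "zero denominator")
  expect_equal(as.numeric(sum(rational(c(1, 1, 1), c(2, 3, 6)))), 1)
  expect_equal(as.character(parse_rational(c("3/2", "-7"))), c("3/2", "-7"))
})

test_that("mpolynomial carries the partition counts", {
  # guar-gum family at n = 1
  m <- mpolynomial(toy_partition())
  expect_equal(bp_eval(m, 1, 1), 33)  # normalisation: total edge count
  j <- jsonlite::fromJSON(bipoly_to_json(m))
  expect_equal(j$coeff, c("1", "8", "2", "13", "9"))
  expect_equal(j$i, c("1", "1", "2", "2", "3"))
  expect_equal(j$j, c("2", "3", "2", "3", "3"))

  p2 <- edge_partition_counts(1, 2, 2)
  m2 <- mpolynomial(p2)
  expect_equal(bp_eval(m2, 2, 3), 2 * 2 * 3^2)  # 2 x y^2 at (2,3)
})

test_that("operators act termwise on monomials", {
  m <- bipoly(1, 2, 1)  # x y^2
  expect_equal(bp_eval(apply_operator(m, "Dx"), 2, 3), bp_eval(m, 2, 3))
  expect_equal(bp_eval(apply_operator(m, "Dy")), 2)
  expect_equal(bp_eval(apply_operator(m, "Sy")), 1 / 2)
  # exponent bookkeeping: J then Q(-2) on x y^2 gives x^1
  p <- apply_operator(m, "J")
  expect_equal(as.numeric(p$i), 3)
  expect_equal(as.numeric(p$j), 0)
  p <- apply_operator(p, "Q", alpha = -2)
  expect_equal(as.numeric(p$i), 1)
  p <- apply_operator(p, "Sx")
  expect_equal(bp_eval(p, x = 2), 2)
})

test_that("Sx rejects zero exponents in the integrated variable", {
  m <- bipoly(0, 2, 5)
  expect_error(apply_operator(m, "Sx"), "zero x-exponent")
  expect_error(apply_operator(bipoly(1, 0, 5), "Sy"), "zero y-exponent")
  # this is exactly how AZI surfaces its undefined case on (1,1) edges
  p11 <- edge_partition_counts(1, 1, 3)
  expect_error(index_from_operators(p11, "AZI"), "zero x-exponent")
  expect_error(direct_index(p11, "AZI"), "undefined")
})

test_that("Dx and Sx are mutually inverse on positive x-exponents", {
  for (seed in 1:20) {
    p <- with_seed_test(seed, {
      k <- sample(3:6, 1)
      bipoly(sample(1:5, k, replace = TRUE), sample(0:5, k, replace = TRUE),
             sample(-9:9, k, replace = TRUE))
    })
    ds <- apply_chain(p, c("Dx", "Sx"))
    sd <- apply_chain(p, c("Sx", "Dx"))
    for (x in c(1, 2)) for (y in c(1, 3)) {
      expect_equal(bp_eval(ds, x, y), bp_eval(p, x, y))
      expect_equal(bp_eval(sd, x, y), bp_eval(p, x, y))
    }
  }
})

test_that("Q composes additively and J commutes with scaling", {
  p <- bipoly(c(1, 2), c(2, 3), c(4, -7))
  q1 <- apply_operator(apply_operator(p, "Q", 2), "Q", -5)
  q2 <- apply_operator(p, "Q", -3)
  expect_equal(bp_eval(q1, 2, 3), bp_eval(q2, 2, 3))
  j1 <- apply_operator(mpolyindex:::bp_scale(p, 3), "J")
  j2 <- mpolyindex:::bp_scale(apply_operator(p, "J"), 3)
  expect_equal(bp_eval(j1, 2), bp_eval(j2, 2))
})

test_that("(Dx + Dy) at (1,1) equals the M1 edge sum on random partitions", {
  for (seed in 1:200) {
    df <- with_seed_test(seed, {
      k <- sample(1:6, 1)
      data.frame(s = sample(1:4, k, replace = TRUE),
                 t = sample(1:4, k, replace = TRUE),
                 count = sample(1:20, k, replace = TRUE))
    })
    part <- edge_partition_counts(df$s, df$t, df$count)
    expect_equal(index_from_operators(part, "M1"),
                 oracle_index(part, "M1"))
    expect_equal(bp_eval(mpolynomial(part)), partition_size(part))
  }
})

test_that("operator route equals direct route on random graphs", {
  alphas <- c(-1, -1 / 2, 1 / 2, 1, 2)
  for (seed in 1:50) {
    part <- edge_partition(random_chemical_graph(
      with_seed_test(seed, sample(6:25, 1)), 4, seed = seed))
    for (nm in alpha_free_indices) {
      expect_equal(index_from_operators(part, nm), direct_index(part, nm),
                   tolerance = 1e-12)
      expect_equal(direct_index(part, nm), oracle_index(part, nm),
                   tolerance = 1e-12)
    }
    for (a in alphas) {
      expect_equal(index_from_operators(part, "Ralpha", a),
                   direct_index(part, "Ralpha", a), tolerance = 1e-12)
      expect_equal(index_from_operators(part, "RRalpha", a),
                   direct_index(part, "RRalpha", a), tolerance = 1e-12)
    }
  }
})

test_that("bipoly JSON serialisation round-trips exactly", {
  p <- bipoly(c(1, 2, 3), c(2, 3, 3), c(5, -13, 9))
  p <- apply_operator(p, "Sx")  # introduce non-integer coefficients
  q <- bipoly_from_json(bipoly_to_json(p))
  expect_equal(as.character(q$coef), as.character(p$coef))
  expect_equal(as.character(q$i), as.character(p$i))
  expect_equal(bp_eval(q, 2, 5), bp_eval(p, 2, 5))
  expect_equal(bp_eval(bipoly_from_json(bipoly_to_json(bipoly()))), 0)
})
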