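test_that("instance validation separates invalid sums from malformed input", {
  v <- validateInstance(toyInstance())
  expect_true(v$valid)
  expect_equal(unname(v$sums), c(5, 5, 5))

  bad <- ddpInstance(c(1, 4), c(2, 3), c(1, 1, 4))
  expect_false(validateInstance(bad)$valid)
  expect_equal(unname(validateInstance(bad)$sums), c(5, 5, 6))

  expect_error(ddpInstance(numeric(0), 2, 2), "empty")
  expect_error(ddpInstance(c(-1, 4), c(2, 1), c(1, 2)), "positive")
  expect_error(ddpInstance(c(1.5, 4), c(2, 3.5), c(1, 1, 3.5)), "integer")
})

test_that("accumulative summation and step difference invert each other", {
  expect_equal(accumulativeSummation(c(1, 2, 3)), c(1, 3, 6))
  expect_equal(accumulativeSummation(5), 5)
  expect_equal(accumulativeSummation(c(1, 4)), c(1, 5))
  expect_error(accumulativeSummation(numeric(0)), "empty")

  expect_equal(stepDifference(c(1, 3, 6)), c(2, 3))
  expect_equal(stepDifference(5), numeric(0))
  expect_error(stepDifference(c(3, 1)), "non-decreasing")

  set.seed(42)
  for (i in 1:25) {
    x <- sample.int(50, sample(2:10, 1), replace = TRUE)
    expect_equal(stepDifference(accumulativeSummation(x)), x[-1])
  }
})

test_that("implied spectrum reproduces the simultaneous digest", {
  inst <- toyInstance()
  expect_equal(impliedSpectrum(inst, mappingPair(1:2, 1:2))$values,
               c(1, 1, 3))
  expect_equal(impliedSpectrum(inst, mappingPair(2:1, 1:2))$values,
               c(1, 2, 2))

  # conservation and length across random instances and random mappings
  set.seed(7)
  for (i in 1:20) {
    g <- randomSmallInstance()
    inst <- g$instance
    p <- length(fragmentsA(inst)); q <- length(fragmentsB(inst))
    mp <- mappingPair(sample(p), sample(q))
    sp <- impliedSpectrum(inst, mp)
    expect_equal(sum(sp$values), sum(fragmentsA(inst)))
    expect_length(sp$values, length(fragmentsC(inst)))
    expect_equal(sort(sp$raw), sp$values)
  }
})

test_that("fitness is 1/(1+D) and exactly 1 only at a solution", {
  inst <- toyInstance()
  expect_identical(plainFitness(inst, mappingPair(1:2, 1:2)), 1)
  expect_equal(plainFitness(inst, mappingPair(2:1, 1:2)), 1 / 3)

  one <- ddpInstance(5, 5, 5)
  expect_identical(plainFitness(one, mappingPair(1L, 1L)), 1)

  expect_true(verifySolution(inst, mappingPair(1:2, 1:2)))
  expect_false(verifySolution(inst, mappingPair(2:1, 1:2)))
  bad <- ddpInstance(c(1, 4), c(2, 3), c(1, 1, 4))
  expect_error(verifySolution(bad, mappingPair(1:2, 1:2)), "invalid")
})

test_that("brute force oracle enumerates all maximisers", {
  bf <- bruteForceSolve(toyInstance())
  expect_identical(bf$fitness, 1)
  sols <- vapply(bf$solutions, function(mp)
    paste(c(mp@mu, mp@nu), collapse = ""), "")
  expect_true("1212" %in% sols)

  # duplicate fragments in B make nu irrelevant: all 4 pairs optimal
  dup <- ddpInstance(c(1, 3), c(2, 2), c(1, 1, 2))
  expect_length(bruteForceSolve(dup)$solutions, 4L)

  one <- ddpInstance(5, 5, 5)
  expect_length(bruteForceSolve(one)$solutions, 1L)

  expect_error(bruteForceSolve(toyInstance(), cap = 1), "cap")
})

test_that("plaintext distances match an independent R-level recomputation", {
  # independent oracle: recompute D from first principles in R
  oracle <- function(inst, mp) {
    sites <- sort(c(cumsum(fragmentsA(inst)[mp@mu]),
                    cumsum(fragmentsB(inst)[mp@nu])))
    d <- sort(diff(c(0, sites)))
    d <- d[-seq_len(length(d) - length(fragmentsC(inst)))]
    sum(abs(d - fragmentsC(inst)))
  }
  set.seed(13)
  for (i in 1:20) {
    g <- randomSmallInstance()
    inst <- g$instance
    p <- length(fragmentsA(inst)); q <- length(fragmentsB(inst))
    mp <- mappingPair(sample(p), sample(q))
    expect_equal(ddpDistance(inst, mp), oracle(inst, mp))
  }
})
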