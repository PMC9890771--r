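test_that("initial population is the uniform superposition", {
  cfg <- gaConfig(N = 50)
  pop <- initPopulation(cfg, 4, 5)
  expect_length(pop, 50L)
  ch <- pop[[1]]
  expect_equal(cos(ch@theta)^2 + sin(ch@theta)^2, rep(1, length(ch@theta)))
  expect_equal(sin(ch@theta)^2, rep(0.5, length(ch@theta)))
  expect_identical(ch@b, cipherDDP:::.bitsPerPosition(4, 5))
})

test_that("measurement decodes any bit pattern into a valid mapping", {
  cfg <- gaConfig()
  ch <- initPopulation(cfg, 3, 4)[[1]]

  forced <- ch
  forced@theta[] <- 0            # alpha = 1 everywhere: all-zero keys
  set.seed(1)
  m0 <- measureChromosome(forced)
  expect_identical(m0$mapping@mu, 1:3)  # ties broken by position index
  expect_identical(m0$mapping@nu, 1:4)

  forced@theta[] <- pi / 2       # beta = 1: all-ones keys, again ties
  m1 <- measureChromosome(forced)
  expect_identical(m1$mapping@mu, 1:3)
  expect_identical(m1$mapping@nu, 1:4)

  # fuzz: every measurement of a random chromosome is a permutation pair
  set.seed(2)
  for (i in 1:200) {
    ch@theta <- runif(length(ch@theta), 0, pi / 2)
    mp <- measureChromosome(ch)$mapping
    expect_true(validObject(mp))
  }
})

test_that("R and compiled random-key decoders agree", {
  set.seed(3)
  for (i in 1:50) {
    p <- sample(1:6, 1); q <- sample(1:6, 1)
    b <- cipherDDP:::.bitsPerPosition(p, q)
    bits <- sample(0:1, (p + q) * b, replace = TRUE)
    rdec <- cipherDDP:::.decodeBits(bits, p, q, b)
    cdec <- cipherDDP:::cpp_decode_bits(bits, p, q, b)
    expect_identical(rdec@mu, cdec$mu)
    expect_identical(rdec@nu, cdec$nu)
  }
})

test_that("uniform measurement matches the exact tie-aware distribution", {
  # oracle: enumerate all key triples for p = 3 positions at b bits and
  # tally the permutation each decodes to (ties broken by index)
  p <- 3L; b <- cipherDDP:::.bitsPerPosition(3, 1)
  keySpace <- 2^b
  perms <- apply(expand.grid(k1 = 0:(keySpace - 1), k2 = 0:(keySpace - 1),
                             k3 = 0:(keySpace - 1)), 1, function(k)
    paste(order(k), collapse = ""))
  expected <- table(perms) / length(perms)

  cfg <- gaConfig()
  ch <- initPopulation(cfg, 3, 1)[[1]]
  set.seed(4)
  draws <- replicate(10000,
    paste(measureChromosome(ch)$mapping@mu, collapse = ""))
  got <- table(factor(draws, levels = names(expected))) / length(draws)
  sig <- sqrt(as.numeric(expected) * (1 - as.numeric(expected)) / 10000)
  expect_true(all(abs(as.numeric(got) - as.numeric(expected)) <= 3.5 * sig))
})

test_that("rotation converges toward the target and preserves norms", {
  cfg <- gaConfig()
  ch <- initPopulation(cfg, 2, 2)[[1]]
  target <- rep(1L, length(ch@theta))
  steps <- ceiling(pi / (2 * cfg@dtheta))
  for (s in seq_len(steps)) ch <- rotateChromosome(ch, target, cfg)
  expect_true(all(sin(ch@theta)^2 >= 0.999 - 1e-9))
  expect_equal(cos(ch@theta)^2 + sin(ch@theta)^2,
               rep(1, length(ch@theta)), tolerance = 1e-9)
  # saturation: a further rotation is a no-op
  more <- rotateChromosome(ch, target, cfg)
  expect_equal(more@theta, ch@theta)
})

test_that("crossover and mutation behave at the probability extremes", {
  cfg0 <- gaConfig(pc = 0, pm = 0)
  cfg1 <- gaConfig(pc = 1, pm = 1)
  a <- initPopulation(cfg0, 3, 3)[[1]]
  b <- a; b@theta <- rev(seq_along(b@theta)) / length(b@theta)

  set.seed(5)
  off <- crossoverChromosomes(a, b, cfg0)
  expect_identical(off[[1]]@theta, a@theta)
  expect_identical(off[[2]]@theta, b@theta)

  off <- crossoverChromosomes(a, b, cfg1)
  joined <- c(off[[1]]@theta, off[[2]]@theta)
  expect_equal(sort(joined), sort(c(a@theta, b@theta)))

  expect_identical(mutateChromosome(a, cfg0)@theta, a@theta)
  # pm = 1 flips exactly one qubit (alpha/beta swap); flipping the same
  # qubit again restores the original amplitudes
  mut <- mutateChromosome(b, cfg1)
  j <- which(mut@theta != b@theta)
  expect_length(j, 1L)
  expect_equal(mut@theta[j], pi / 2 - b@theta[j])
  mut@theta[j] <- pi / 2 - mut@theta[j]
  expect_equal(mut@theta, b@theta)
})

test_that("selection keeps the best individual and signals termination", {
  cfg <- gaConfig(N = 10)
  pop <- initPopulation(cfg, 3, 3)
  pop <- lapply(seq_along(pop), function(i) {
    ch <- pop[[i]]; ch@theta[1] <- i / 20; ch  # make individuals tagged
  })
  fit <- c(0.2, 0.5, 0.9, 0.1, 0.3, 0.2, 0.4, 0.6, 0.05, 0.15)
  set.seed(30)
  sel <- selectSurvivors(pop, fit, cfg)
  expect_identical(sel$best, 3L)
  expect_identical(sel$survivors[[1]]@theta, pop[[3]]@theta)
  expect_false(sel$terminate)
  expect_length(sel$survivors, 10L)
  # a fitness-1 individual triggers the termination verdict
  expect_true(selectSurvivors(pop, replace(fit, 4, 1), cfg)$terminate)
  # all-equal fitness: tournament reduces to uniform survivor draws, so
  # many distinct individuals survive rather than one taking over
  sel2 <- selectSurvivors(pop, rep(0.5, 10), cfg)
  tags <- vapply(sel2$survivors[-1], function(ch) ch@theta[1], numeric(1))
  expect_gte(length(unique(tags)), 4L)
})

test_that("encrypted fitness certifies solutions and ranks like plaintext", {
  set.seed(6)
  sess <- encryptInstance(toyInstance())
  good <- encryptedFitness(sess$enc, mappingPair(1:2, 1:2))
  expect_identical(good$fitness, 1)
  expect_lte(good$residual, sess$enc@params$T)
  bad <- encryptedFitness(sess$enc, mappingPair(2:1, 1:2))
  expect_lt(bad$fitness, 1)
  expect_gt(bad$residual, good$residual)

  # ranking equivalence over all mappings, a handful of random instances
  set.seed(7)
  for (i in 1:10) {
    g <- randomSmallInstance(4)
    inst <- g$instance
    p <- length(fragmentsA(inst)); q <- length(fragmentsB(inst))
    enc <- encryptInstance(inst)$enc
    mus <- allPerms(p); nus <- allPerms(q)
    D <- cipherDDP:::cpp_pairwise_distance(fragmentsA(inst),
                                           fragmentsB(inst),
                                           fragmentsC(inst), mus, nus)
    res <- cipherDDP:::cpp_pairwise_residual(enc@Ac, enc@Bc, enc@Cc,
                                             mus, nus)
    expect_true(rankingsAgree(D, res, 2 * enc@params$T))
  }
})

test_that("the solver finds exact mappings and is seed-deterministic", {
  set.seed(8)
  sess <- encryptInstance(toyInstance())
  cfg <- gaConfig(gMax = 500, seed = 42)
  sol <- solveEncrypted(sess$enc, cfg)
  expect_identical(sol@fitness, 1)
  expect_true(verifySolution(toyInstance(), sol@mapping))

  sol2 <- solveEncrypted(sess$enc, cfg)
  expect_identical(sol@mapping@mu, sol2@mapping@mu)
  expect_identical(sol@mapping@nu, sol2@mapping@nu)
  expect_identical(sol@generations, sol2@generations)

  # single-candidate degenerate instance terminates in generation 1
  one <- ddpInstance(5, 5, 5)
  set.seed(9)
  s1 <- solveEncrypted(encryptInstance(one)$enc, gaConfig(seed = 1))
  expect_identical(s1@generations, 1L)
  expect_identical(s1@fitness, 1)

  # the solver interface accepts only the encrypted payload
  expect_error(solveEncrypted(toyInstance(), cfg))
})

test_that("encrypted and plaintext searches follow identical trajectories", {
  set.seed(10)
  for (i in 1:6) {
    g <- generateInstance(sample(5:9, 1))
    inst <- g$instance
    enc <- encryptInstance(inst)$enc
    cfg <- gaConfig(gMax = 300, seed = 100 + i)
    se <- solveEncrypted(enc, cfg)
    sp <- solvePlaintext(inst, cfg)
    expect_identical(se@mapping@mu, sp@mapping@mu)
    expect_identical(se@mapping@nu, sp@mapping@nu)
    expect_identical(se@generations, sp@generations)
    expect_identical(se@fitness == 1, sp@fitness == 1)
  }
})

test_that("best-so-far fitness is monotone along the search", {
  set.seed(11)
  g <- generateInstance(12)
  enc <- encryptInstance(g$instance)$enc
  set.seed(12)
  raw <- cipherDDP:::cpp_qiga_encrypted(enc@Ac, enc@Bc, enc@Cc,
                                        enc@params$T, 30L, 400L, 0.85, 0.5,
                                        0.025 * pi, 0.001, 0.999, 100L)
  expect_true(all(diff(raw$trace) <= 1e-12))
})
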