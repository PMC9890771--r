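test_that("keygen respects the key constraints and is reproducible", {
  set.seed(1); k1 <- ophiKeygen(3, LMax = 10)
  set.seed(1); k2 <- ophiKeygen(3, LMax = 10)
  expect_identical(k1@k, k2@k)
  expect_error(ophiKeygen(1), "at least")

  set.seed(2)
  for (i in 1:50) {
    key <- ophiKeygen(sample(2:6, 1), LMax = sample(5:50, 1))
    expect_true(all(key@k > 0 & key@k <= 2^10))
    expect_equal(key@budget$RBound,
                 min(key@k) * key@budget$pMin / (2 * key@budget$LMax))
  }
})

test_that("encryption matches the hand-computed example and fresh bounds", {
  key <- forcedKey()
  ct <- ophiEncrypt(key, 10, r = c(0.2, 0.3))
  expect_equal(ct@c, c(20.2, 30.3, 2.5))
  expect_identical(ct@depth, 1L)

  # zero plaintext: every component below k_i * pMin
  set.seed(3)
  key <- ophiKeygen(3, LMax = 20)
  z <- ophiEncrypt(key, 0)
  expect_true(all(z@c[1:2] < key@k[1:2] * key@budget$pMin))

  # probabilistic: fresh encryptions of one plaintext never coincide
  a <- ophiEncrypt(key, 7); b <- ophiEncrypt(key, 7)
  expect_true(all(a@c != b@c))

  # fresh-ciphertext bounds k_i*m < c_i < k_i*(m + pMin), many draws
  set.seed(4)
  for (i in 1:200) {
    m <- sample(0:1000, 1)
    ct <- ophiEncrypt(key, m)
    lo <- key@k[1:2] * m
    hi <- key@k[1:2] * (m + key@budget$pMin)
    expect_true(all(ct@c[1:2] > lo | m == 0) && all(ct@c[1:2] < hi))
  }
})

test_that("homomorphic addition and subtraction are componentwise exact", {
  key <- forcedKey()
  x <- ophiEncrypt(key, 10, r = c(0.2, 0.3))
  y <- ophiEncrypt(key, 5, r = c(0.1, 0.1))
  s <- ophiAdd(x, y)
  expect_equal(s@c, c(30.3, 45.4, 3.5))
  expect_identical(s@depth, 2L)
  # the sum IS the encryption of 15 under noise (0.3, 0.4)
  expect_equal(s@c, ophiEncrypt(key, 15, r = c(0.3, 0.4))@c)

  d <- ophiSubtract(ophiEncrypt(key, 15, r = c(0.3, 0.4)), y)
  expect_equal(d@c, c(20.2, 30.3, 2.5))

  z <- ophiSubtract(x, x)
  expect_equal(z@c[1:2], c(0, 0))

  expect_error(ophiAdd(x, y, LMax = 1), "budget")

  # homomorphism identity over many random keys/plaintexts/noises
  set.seed(5)
  for (i in 1:200) {
    key <- ophiKeygen(3, LMax = 10)
    m1 <- sample(0:500, 1); m2 <- sample(0:500, 1)
    e1 <- ophiEncrypt(key, m1); e2 <- ophiEncrypt(key, m2)
    r12 <- (e1@c[1:2] - key@k[1:2] * m1) + (e2@c[1:2] - key@k[1:2] * m2)
    expect_equal(ophiAdd(e1, e2)@c,
                 c(key@k[1:2] * (m1 + m2) + r12, key@k[3] * sum(r12)),
                 tolerance = 1e-9)
  }
})

test_that("comparison reproduces plaintext order within budget", {
  set.seed(6)
  key <- ophiKeygen(3, LMax = 10)
  for (i in 1:500) {
    m <- sample.int(1000, 2)  # sampling without replacement: distinct
    x <- ophiEncrypt(key, m[1]); y <- ophiEncrypt(key, m[2])
    expect_identical(ophiCompare(x, y),
                     if (m[1] > m[2]) "greater" else "less")
  }
  # a ciphertext is never strictly ordered against itself
  x <- ophiEncrypt(key, 10)
  expect_identical(ophiCompare(x, x), "indistinguishable")
  # equal plaintexts: the verdict is noise-decided, so over many fresh
  # pairs both orders appear (no systematic direction)
  v <- replicate(200, ophiCompare(ophiEncrypt(key, 4), ophiEncrypt(key, 4)))
  expect_true(all(v %in% c("less", "greater", "indistinguishable")))
  expect_true(sum(v == "greater") > 0 && sum(v == "less") > 0)
})

test_that("order survives homomorphic accumulation up to the budget", {
  set.seed(7)
  for (rep in 1:30) {
    L <- sample(2:12, 1)
    key <- ophiKeygen(3, LMax = L)
    sum1 <- Reduce(ophiAdd, lapply(seq_len(L), function(i) ophiEncrypt(key, 1)))
    sum0 <- Reduce(ophiAdd, lapply(seq_len(L), function(i) ophiEncrypt(key, 0)))
    expect_identical(ophiCompare(sum1, sum0), "greater")
  }
})

test_that("ciphertext sorting recovers plaintext multiset order", {
  set.seed(8)
  key <- ophiKeygen(3, LMax = 10)
  for (rep in 1:100) {
    m <- sample(0:30, sample(3:8, 1), replace = TRUE)
    cts <- lapply(m, function(v) ophiEncrypt(key, v))
    srt <- ophiSort(cts)
    # plaintext values in sorted order; duplicates adjacent (their
    # internal order is noise-decided and carries no information)
    expect_equal(m[srt$permutation], sort(m))
  }
  sorted <- lapply(c(1, 3, 5), function(v) ophiEncrypt(key, v))
  expect_equal(ophiSort(sorted)$permutation, 1:3)
})

test_that("permutation operator reorders without touching ciphertexts", {
  set.seed(9)
  key <- ophiKeygen(3, LMax = 5)
  cts <- lapply(c(4, 7, 2), function(v) ophiEncrypt(key, v))
  expect_identical(ophiPermute(cts, 1:3), cts)
  perm <- c(3, 1, 2)
  inv <- order(perm)
  expect_identical(ophiPermute(ophiPermute(cts, perm), inv), cts)
  expect_error(ophiPermute(cts, c(1, 1, 2)), "permutation")
})

test_that("instance encryption builds a coherent public payload", {
  set.seed(10)
  sess <- encryptInstance(toyInstance())
  enc <- sess$enc
  expect_equal(nrow(enc@Ac) + nrow(enc@Bc) + nrow(enc@Cc), 7L)
  expect_equal(enc@params$n, 3L)
  expect_true(enc@params$T > 0)

  # C is stored ascending, so sorting its ciphertexts preserves the
  # plaintext order (duplicates may swap, which changes nothing)
  srt <- ophiSort(cipherDDP:::.ciphertextList(enc@Cc))
  Cv <- fragmentsC(toyInstance())
  expect_equal(Cv[srt$permutation], Cv)

  bad <- ddpInstance(c(1, 4), c(2, 3), c(1, 1, 4))
  expect_error(encryptInstance(bad), "invalid")
})

test_that("session files round-trip exactly", {
  set.seed(11)
  dir <- withr::local_tempdir()
  inst <- toyInstance()
  f <- file.path(dir, "inst.json")
  writeDDPInstance(inst, f)
  expect_equal(fragmentsC(readDDPInstance(f)), fragmentsC(inst))

  csv <- file.path(dir, "inst.csv")
  writeLines(c("A,4,1", "B,2,3", "C,1,1,3"), csv)
  expect_equal(fragmentsA(readDDPInstance(csv)), c(1, 4))

  sess <- encryptInstance(inst)
  kf <- file.path(dir, "key.json")
  writeOPHIKey(sess$key, kf)
  k2 <- readOPHIKey(kf)
  expect_equal(k2@k, sess$key@k)
  expect_equal(k2@budget$RBound, sess$key@budget$RBound)

  ef <- file.path(dir, "enc.json")
  writeEncryptedInstance(sess$enc, ef)
  e2 <- readEncryptedInstance(ef)
  expect_equal(e2@Ac, sess$enc@Ac)
  expect_equal(e2@params$T, sess$enc@params$T)

  mf <- file.path(dir, "map.json")
  writeMapping(list(mu = c(2, 1), nu = c(1, 2), fitness = 0.5), mf)
  m <- readMapping(mf)
  expect_identical(m$mapping@mu, c(2L, 1L))
  expect_equal(m$fitness, 0.5)
})
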