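test_that("stage 1 refuses invalid instances and is seed-reproducible", {
  dir <- withr::local_tempdir()
  instF <- file.path(dir, "inst.json")
  writeDDPInstance(toyInstance(), instF)

  k1 <- file.path(dir, "k1.json"); e1 <- file.path(dir, "e1.json")
  k2 <- file.path(dir, "k2.json"); e2 <- file.path(dir, "e2.json")
  stage1Protect(instF, k1, e1, seed = 7)
  stage1Protect(instF, k2, e2, seed = 7)
  expect_identical(readLines(e1), readLines(e2))

  enc <- readEncryptedInstance(e1)
  expect_equal(nrow(enc@Ac) + nrow(enc@Bc) + nrow(enc@Cc), 7L)
  expect_equal(ncol(enc@Ac), 3L)

  badF <- file.path(dir, "bad.json")
  jsonlite::write_json(list(A = c(1, 4), B = c(2, 3), C = c(1, 1, 4)), badF)
  expect_error(stage1Protect(badF, k1, e1), "invalid")
})

test_that("stage 3 solves from the public file alone", {
  dir <- withr::local_tempdir()
  instF <- file.path(dir, "inst.json")
  writeDDPInstance(toyInstance(), instF)
  keyF <- file.path(dir, "key.json"); encF <- file.path(dir, "enc.json")
  stage1Protect(instF, keyF, encF, seed = 1)

  # server role: an isolated directory holding only the public payload
  serverDir <- withr::local_tempdir()
  serverEnc <- file.path(serverDir, "enc.json")
  file.copy(encF, serverEnc)
  mapF <- file.path(serverDir, "map.json")
  sol <- withr::with_dir(serverDir,
    stage3Solve("enc.json", "map.json", gaConfig(gMax = 500, seed = 2)))
  expect_true(file.exists(mapF))
  expect_identical(sol@fitness, 1)

  verdict <- stage5Extract(instF, mapF)
  expect_true(verdict$accepted)
  expect_equal(sum(verdict$map$A), 5)
  expect_equal(max(verdict$map$sites), 5)

  # tampering with the ciphertext counts is caught on load
  x <- jsonlite::read_json(encF, simplifyVector = TRUE)
  x$A_c <- x$A_c[1, , drop = FALSE]
  badF <- file.path(dir, "tampered.json")
  jsonlite::write_json(x, badF, auto_unbox = TRUE, digits = NA)
  expect_error(stage3Solve(badF, mapF), "rows|schema")
})

test_that("stage 5 rejects mappings that do not fit", {
  dir <- withr::local_tempdir()
  instF <- file.path(dir, "inst.json")
  writeDDPInstance(toyInstance(), instF)
  mapF <- file.path(dir, "map.json")

  writeMapping(list(mu = c(2, 1), nu = c(1, 2)), mapF)
  v <- stage5Extract(instF, mapF)
  expect_false(v$accepted)
  expect_equal(v$distance, 2)

  # mapping sized for a different instance
  writeMapping(list(mu = c(2, 1, 3), nu = c(1, 2)), mapF)
  expect_error(stage5Extract(instF, mapF), "dimensions")
})

test_that("the end-to-end pipeline succeeds and audits its artifacts", {
  r <- runPipeline(toyInstance(), cfg = gaConfig(gMax = 500),
                   cryptoSeed = 3, gaSeed = 4)
  expect_true(r$success)
  expect_identical(r$attempts, 1L)
  expect_true(all(file.exists(unlist(r$files))))

  # identically seeded sessions produce interchangeable mapping files
  r2 <- runPipeline(toyInstance(), cfg = gaConfig(gMax = 500),
                    cryptoSeed = 3, gaSeed = 4)
  expect_identical(readLines(r$files$map), readLines(r2$files$map))
  v <- stage5Extract(r$files$instance, r2$files$map)
  expect_true(v$accepted)
})

test_that("a lazy server is rejected and retried", {
  set.seed(20)
  g <- generateInstance(16)  # large enough that random hits are negligible
  r <- runPipeline(g$instance, cfg = gaConfig(gMax = 100),
                   cryptoSeed = 5, gaSeed = 6, retries = 2, lazy = TRUE)
  expect_false(r$success)
  expect_identical(r$attempts, 3L)
})

test_that("round trip: small generated instances always solve", {
  set.seed(21)
  ok <- logical(10)
  for (i in 1:10) {
    g <- randomSmallInstance()
    r <- runPipeline(g$instance, cfg = gaConfig(),
                     cryptoSeed = 100 + i, gaSeed = 200 + i)
    ok[i] <- r$success
  }
  expect_true(all(ok))
})
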