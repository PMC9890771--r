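# Five-stage outsourcing session. The business logic separates two roles:
# the data owner (stages 1 and 5) holds the instance and the key; the
# compute server (stage 3) sees only the encrypted-instance file and
# returns a mapping file. Stages 2 and 4 are the public transfers, here
# simply the files changing hands. "Cloud" is simulated as in-process
# calls with file handoff; the contribution is the protocol and the math,
# not deployment.

#' Stage 1: protect the instance
#'
#' Owner side. Validates the instance (an invalid one — mismatched
#' multiset totals — is refused), generates a fresh key with the
#' instance-sized noise budget, encrypts every fragment, and writes the
#' secret key file and the public encrypted-instance file.
#'
#' @param instanceFile owner's instance file (JSON or CSV).
#' @param keyFile output path for the secret key (owner-private).
#' @param encFile output path for the encrypted instance (public).
#' @param n sub-ciphertexts per plaintext (default 3).
#' @param seed optional seed making key and noise draws reproducible.
#' @return Invisibly, a list with the public parameters.
#' @export
stage1Protect <- function(instanceFile, keyFile, encFile, n = 3,
                          seed = NULL) {
  inst <- readDDPInstance(instanceFile)
  if (!isValidInstance(inst))
    stop("invalid instance: multiset totals ",
         paste(instanceSums(inst), collapse = "/"), " differ; not encrypted")
  if (!is.null(seed)) set.seed(seed)
  sess <- encryptInstance(inst, n = n)
  writeOPHIKey(sess$key, keyFile)
  writeEncryptedInstance(sess$enc, encFile)
  invisible(sess$enc@params)
}

#' Stage 3: solve over ciphertexts
#'
#' Server side. Reads only the public encrypted-instance file — the
#' process never touches the key or the plaintext instance — runs the
#' QIGA, and writes the mapping file. The \code{lazy} flag emulates a
#' lazy server that skips the computation and returns a random mapping;
#' it exists so the owner-side rejection path can be exercised.
#'
#' @param encFile public encrypted-instance file.
#' @param mapFile output path for the mapping file (public).
#' @param cfg a \linkS4class{GAConfig}.
#' @param lazy emit a uniformly random mapping instead of solving.
#' @return Invisibly, the \linkS4class{DDPSolution} (or the random
#'   mapping list when lazy).
#' @export
stage3Solve <- function(encFile, mapFile, cfg = gaConfig(), lazy = FALSE) {
  enc <- readEncryptedInstance(encFile)
  if (lazy) {
    if (!is.na(cfg@seed)) set.seed(cfg@seed)
    out <- list(mu = sample.int(enc@params$p), nu = sample.int(enc@params$q),
                fitness = NA, residual = NA, generations = 0L)
    writeMapping(out, mapFile)
    return(invisible(out))
  }
  sol <- solveEncrypted(enc, cfg)
  writeMapping(sol, mapFile)
  invisible(sol)
}

#' Stage 5: extract and verify the solution
#'
#' Owner side. Combines the returned mapping sequences with the original
#' plaintext instance, recomputes the implied simultaneous-digest
#' spectrum, and accepts iff it reproduces C exactly. On acceptance the
#' ordered fragment arrangement — the physical map — is emitted; on
#' rejection the owner asks the server to recompute.
#'
#' @param instanceFile owner's instance file.
#' @param mapFile mapping file returned by the server.
#' @return A list with \code{accepted} (logical), \code{distance} (the
#'   plaintext L1 distance) and, when accepted, \code{map}: the
#'   arrangement of A, of B, and the merged cut-site coordinates.
#' @export
stage5Extract <- function(instanceFile, mapFile) {
  inst <- readDDPInstance(instanceFile)
  m <- readMapping(mapFile)
  mp <- m$mapping
  if (length(mp@mu) != length(inst@A) || length(mp@nu) != length(inst@B))
    stop("mapping does not match the instance dimensions")
  d <- ddpDistance(inst, mp)
  out <- list(accepted = d == 0, distance = d)
  if (out$accepted) {
    out$map <- list(
      A = inst@A[mp@mu], B = inst@B[mp@nu],
      sites = sort(unique(c(accumulativeSummation(inst@A[mp@mu]),
                            accumulativeSummation(inst@B[mp@nu])))))
  }
  out
}

#' Run a full outsourcing session
#'
#' Chains stages 1, 3 and 5 in-process with file handoff, retrying the
#' solve on rejection (the lazy-server countermeasure) up to
#' \code{retries} times. All randomness flows through two named seeds:
#' \code{cryptoSeed} (key and noise) and \code{gaSeed} (the search; each
#' retry increments it).
#'
#' @param instance a \linkS4class{DDPInstance} or a path to an instance
#'   file.
#' @param cfg a \linkS4class{GAConfig}.
#' @param n sub-ciphertexts per plaintext.
#' @param cryptoSeed,gaSeed the two session seeds.
#' @param retries additional solve attempts after a rejection.
#' @param lazy emulate a lazy server (all attempts return random
#'   mappings).
#' @param dir directory for the session artifacts (kept for audit).
#' @return A list: \code{success}, \code{attempts}, \code{generations},
#'   \code{residual}, \code{mapping}, \code{map} (when successful),
#'   \code{files}, and the two seeds.
#' @examples
#' set.seed(1)
#' g <- generateInstance(6, 40)
#' runPipeline(g$instance, cfg = gaConfig(gMax = 500),
#'             cryptoSeed = 1, gaSeed = 2)$success
#' @export
runPipeline <- function(instance, cfg = gaConfig(), n = 3, cryptoSeed = 1,
                        gaSeed = 2, retries = 3, lazy = FALSE,
                        dir = tempfile("ddp-session-")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(instance = file.path(dir, "instance.json"),
                key = file.path(dir, "key.json"),
                enc = file.path(dir, "instance.enc.json"),
                map = file.path(dir, "mapping.json"))
  if (is(instance, "DDPInstance")) {
    writeDDPInstance(instance, files$instance)
  } else {
    file.copy(instance, files$instance, overwrite = TRUE)
  }
  stage1Protect(files$instance, files$key, files$enc, n = n,
                seed = cryptoSeed)
  verdict <- NULL
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    cfg@seed <- as.integer(gaSeed + attempts - 1L)
    stage3Solve(files$enc, files$map, cfg, lazy = lazy)
    verdict <- stage5Extract(files$instance, files$map)
    if (verdict$accepted || attempts > retries) break
  }
  m <- readMapping(files$map)
  list(success = verdict$accepted, attempts = attempts,
       generations = m$generations, residual = m$residual,
       mapping = m$mapping, map = verdict$map, files = files,
       cryptoSeed = cryptoSeed, gaSeed = gaSeed)
}
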