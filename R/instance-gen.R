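# Synthetic double digest experiment: random cut sites on an integer
# molecule, fragment multisets read off the three digests.

#' Generate a random DDP instance
#'
#' Emulates a double digest experiment on a molecule of integer length
#' \code{length}: \code{t - 1} distinct interior cut sites are sampled
#' uniformly, and each is attributed to the first enzyme, the second, or
#' (when \code{allowCoincident}) both. \code{A} and \code{B} are the
#' sorted gaps between consecutive sites of each enzyme (molecule ends
#' included), \code{C} the sorted gaps of the union, so
#' \code{sum(A) = sum(B) = sum(C) = length} holds by construction and the
#' true cut order is a fitness-1 mapping. Without coincident sites
#' \code{p + q = t + 1}; each shared site adds one zero-length artifact
#' the solver has to discard.
#'
#' The default molecule length \code{100 * t} gives mean fragment length
#' 100, i.e. mostly distinct lengths. Shorter molecules produce heavy
#' duplication and therefore many equivalent solutions; see the package
#' vignette for how strongly this drives solver success.
#'
#' @param t number of simultaneous-digest fragments (>= 3).
#' @param length total molecule length (default \code{100 * t}).
#' @param allowCoincident allow the two enzymes to share cut sites
#'   (default FALSE); shared sites are drawn with probability
#'   \code{shareProb} each.
#' @param shareProb per-site probability of a shared site when
#'   \code{allowCoincident} (default 0.1).
#' @return A list with \code{instance} (the \linkS4class{DDPInstance})
#'   and \code{truth} (the generating \linkS4class{MappingPair};
#'   diagnostics only, never given to the solver).
#' @examples
#' set.seed(1)
#' g <- generateInstance(10)
#' verifySolution(g$instance, g$truth)  # TRUE by construction
#' @export
generateInstance <- function(t, length = 100 * t, allowCoincident = FALSE,
                             shareProb = 0.1) {
  if (t < 3) stop("t must be at least 3")
  if (length < t + 1) stop("molecule length must exceed t")
  sites <- sort(sample.int(length - 1L, t - 1L))
  if (allowCoincident) {
    cls <- sample(c("a", "b", "ab"), t - 1L, replace = TRUE,
                  prob = c((1 - shareProb) / 2, (1 - shareProb) / 2,
                           shareProb))
  } else {
    cls <- sample(c("a", "b"), t - 1L, replace = TRUE)
  }
  aSites <- sites[cls %in% c("a", "ab")]
  bSites <- sites[cls %in% c("b", "ab")]
  gapsA <- diff(c(0, aSites, length))
  gapsB <- diff(c(0, bSites, length))
  gapsC <- diff(c(0, sites, length))
  list(instance = ddpInstance(gapsA, gapsB, gapsC),
       truth = mappingPair(rank(gapsA, ties.method = "first"),
                           rank(gapsB, ties.method = "first")))
}

# deterministic per-run sub-seeds below 2^31
.subSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Success-rate experiment on random instances
#'
#' For each requested simultaneous-digest size \code{t}, generates one
#' random instance and runs the full five-stage pipeline (encrypt, solve
#' over ciphertexts, verify on plaintexts) \code{runs} times with
#' distinct GA seeds. A run succeeds when the owner-side verification
#' accepts the returned mapping.
#'
#' @param tValues integer vector of simultaneous-digest sizes.
#' @param runs pipeline runs per size (default 25).
#' @param cfg a \linkS4class{GAConfig} (its seed slot is ignored; per-run
#'   seeds are derived from \code{seed}).
#' @param n sub-ciphertexts per plaintext (default 3).
#' @param seed master seed for instance generation, encryption and the
#'   per-run GA seeds.
#' @param length molecule length as a function of t (default
#'   \code{function(t) 100 * t}).
#' @return A data.frame with columns t, runs, successes, success_rate,
#'   mean_generations, mean_residual.
#' @export
successRateExperiment <- function(tValues, runs = 25, cfg = gaConfig(),
                                  n = 3, seed = 1,
                                  length = function(t) 100 * t) {
  rows <- lapply(seq_along(tValues), function(i) {
    t <- tValues[i]
    seeds <- .subSeeds(seed + 7919L * i, runs + 2L)
    set.seed(seeds[1L])
    inst <- generateInstance(t, length(t))$instance
    set.seed(seeds[2L])
    enc <- encryptInstance(inst, n = n)$enc
    ok <- logical(runs); gens <- numeric(runs); res <- numeric(runs)
    for (r in seq_len(runs)) {
      cfg@seed <- seeds[2L + r]
      sol <- solveEncrypted(enc, cfg)
      ok[r] <- verifySolution(inst, sol@mapping)
      gens[r] <- sol@generations
      res[r] <- sol@residual
    }
    data.frame(t = t, runs = runs, successes = sum(ok),
               success_rate = mean(ok), mean_generations = mean(gens),
               mean_residual = mean(res))
  })
  do.call(rbind, rows)
}

#' Paired encrypted-vs-plaintext solver comparison
#'
#' Runs the ciphertext-domain solver and the identical plaintext-domain
#' solver on the same instances with the same GA seeds. Because the
#' encrypted residual ordering reproduces the plaintext distance
#' ordering (and ties agree within the public threshold band), the two
#' arms make identical search decisions; any rate difference is
#' measurement noise. The difference is reported with its binomial
#' standard error.
#'
#' @inheritParams successRateExperiment
#' @return A data.frame with columns t, runs, rate_encrypted,
#'   rate_plaintext, difference, se_difference.
#' @export
compareWithPlaintext <- function(tValues, runs = 25, cfg = gaConfig(),
                                 n = 3, seed = 1,
                                 length = function(t) 100 * t) {
  rows <- lapply(seq_along(tValues), function(i) {
    t <- tValues[i]
    seeds <- .subSeeds(seed + 104729L * i, runs + 2L)
    set.seed(seeds[1L])
    inst <- generateInstance(t, length(t))$instance
    set.seed(seeds[2L])
    enc <- encryptInstance(inst, n = n)$enc
    okE <- logical(runs); okP <- logical(runs)
    for (r in seq_len(runs)) {
      cfg@seed <- seeds[2L + r]
      okE[r] <- verifySolution(inst, solveEncrypted(enc, cfg)@mapping)
      cfg@seed <- seeds[2L + r]
      okP[r] <- verifySolution(inst, solvePlaintext(inst, cfg)@mapping)
    }
    pe <- mean(okE); pp <- mean(okP)
    data.frame(t = t, runs = runs, rate_encrypted = pe,
               rate_plaintext = pp, difference = pe - pp,
               se_difference = sqrt(pe * (1 - pe) / runs +
                                    pp * (1 - pp) / runs))
  })
  do.call(rbind, rows)
}
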