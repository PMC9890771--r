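# Quantum-inspired genetic algorithm over encrypted (or plaintext) DDP
# instances. Candidate mapping pairs are encoded probabilistically in
# qubit-amplitude chromosomes; measurement collapses each qubit and the
# resulting bit strings are decoded into permutations by random-key
# ranking. The generation loop (measure, evaluate, select, rotate,
# crossover, mutate) runs in compiled code; the chromosome-level
# operations below are the reference implementations of the individual
# operators.

.bitsPerPosition <- function(p, q) {
  m <- max(p, q)
  3L + max(0L, as.integer(ceiling(log2(m))))
}

# reflected-Gray decoding of one position's b bits (MSB first) into its
# random key; Gray coding puts adjacent key values one bit flip apart, so
# a single quantum NOT shifts a fragment by one rank
.grayToInt <- function(bits) {
  bin <- integer(length(bits))
  bin[1L] <- bits[1L]
  for (j in seq_along(bits)[-1L]) bin[j] <- bitwXor(bin[j - 1L], bits[j])
  sum(bin * 2^(rev(seq_along(bits)) - 1L))
}

.decodeBits <- function(bits, p, q, b) {
  keys <- vapply(seq_len(p + q), function(pos)
    .grayToInt(bits[(pos - 1L) * b + seq_len(b)]), numeric(1))
  mappingPair(order(keys[seq_len(p)]), order(keys[p + seq_len(q)]))
}

#' Initialise a QIGA population
#'
#' Every qubit starts in the uniform superposition
#' \eqn{(\alpha, \beta) = (1/\sqrt 2, 1/\sqrt 2)}, so the first
#' measurements decode to uniformly random permutation pairs.
#'
#' @param cfg a \linkS4class{GAConfig}.
#' @param p,q permutation sizes of the instance.
#' @return A list of \code{cfg@N} \linkS4class{QubitChromosome}s.
#' @export
initPopulation <- function(cfg, p, q) {
  stopifnot(is(cfg, "GAConfig"))
  b <- .bitsPerPosition(p, q)
  proto <- new("QubitChromosome", theta = rep(pi / 4, (p + q) * b),
               p = as.integer(p), q = as.integer(q), b = b)
  rep(list(proto), cfg@N)
}

#' Measure a chromosome
#'
#' Collapses every qubit (1 with probability \eqn{\beta^2}) and decodes
#' the per-position bit strings into a mapping pair by random-key
#' ranking: position keys are the Gray-decoded b-bit integers, and the
#' permutation is their rank order with ties broken by position index.
#' Any bit string decodes to a valid permutation pair.
#'
#' @param ch a \linkS4class{QubitChromosome}.
#' @return A list with \code{mapping} (a \linkS4class{MappingPair}) and
#'   \code{bits} (the measured 0/1 vector, needed as a rotation target).
#' @export
measureChromosome <- function(ch) {
  stopifnot(is(ch, "QubitChromosome"))
  bits <- as.integer(runif(length(ch@theta)) < sin(ch@theta)^2)
  list(mapping = .decodeBits(bits, ch@p, ch@q, ch@b), bits = bits)
}

#' Quantum rotation gate
#'
#' Rotates every qubit by \code{dtheta} toward the bit value the best
#' individual's measurement took at that qubit, clamped so that
#' \eqn{\beta^2} stays inside \code{cfg@clamp} (the saturation guard that
#' keeps a residual flip probability alive). Rotation is orthogonal, so
#' \eqn{\alpha^2 + \beta^2 = 1} is preserved exactly.
#'
#' @param ch a \linkS4class{QubitChromosome}.
#' @param targetBits 0/1 vector from the attractor's measurement.
#' @param cfg a \linkS4class{GAConfig}.
#' @return The rotated \linkS4class{QubitChromosome}.
#' @export
rotateChromosome <- function(ch, targetBits, cfg) {
  stopifnot(is(ch, "QubitChromosome"), is(cfg, "GAConfig"),
            length(targetBits) == length(ch@theta))
  lo <- asin(sqrt(cfg@clamp[1])); hi <- asin(sqrt(cfg@clamp[2]))
  th <- ch@theta + ifelse(targetBits == 1L, cfg@dtheta, -cfg@dtheta)
  ch@theta <- pmin(hi, pmax(lo, th))
  ch
}

#' Quantum crossover
#'
#' With probability \code{pc}, the two chromosomes exchange their
#' amplitude pairs from a uniformly chosen point to the end (point 0
#' swaps the entire chromosomes); otherwise the offspring are clones.
#'
#' @param a,b \linkS4class{QubitChromosome}s with the same gene layout.
#' @param cfg a \linkS4class{GAConfig}.
#' @return A list of the two offspring.
#' @export
crossoverChromosomes <- function(a, b, cfg) {
  stopifnot(identical(length(a@theta), length(b@theta)))
  if (runif(1) < cfg@pc) {
    nq <- length(a@theta)
    point <- sample.int(nq, 1L) - 1L
    idx <- (point + 1L):nq
    tmp <- a@theta[idx]
    a@theta[idx] <- b@theta[idx]
    b@theta[idx] <- tmp
  }
  list(a, b)
}

#' Quantum mutation
#'
#' With probability \code{pm}, one uniformly chosen qubit undergoes a
#' quantum NOT: its amplitudes \eqn{(\alpha, \beta)} are swapped
#' (\eqn{\theta \to \pi/2 - \theta}). Applying the same mutation twice
#' restores the original chromosome.
#'
#' @param ch a \linkS4class{QubitChromosome}.
#' @param cfg a \linkS4class{GAConfig}.
#' @return The (possibly) mutated \linkS4class{QubitChromosome}.
#' @export
mutateChromosome <- function(ch, cfg) {
  if (runif(1) < cfg@pm) {
    j <- sample.int(length(ch@theta), 1L)
    ch@theta[j] <- pi / 2 - ch@theta[j]
  }
  ch
}

#' Quantum selection operator
#'
#' Builds the next parent population from the current one: the
#' chromosome holding the best fitness always survives (elitism), the
#' remaining \code{N - 1} slots are filled by binary tournament on
#' fitness, and the termination verdict is returned alongside (an exact
#' solution was measured, i.e. fitness 1, or the generation budget is
#' exhausted elsewhere).
#'
#' @param population list of \linkS4class{QubitChromosome}s.
#' @param fitness numeric vector, one fitness per chromosome.
#' @param cfg a \linkS4class{GAConfig}.
#' @return A list with \code{survivors} (same length as the input),
#'   \code{best} (index of the best individual) and \code{terminate}
#'   (logical: a fitness-1 individual is present).
#' @export
selectSurvivors <- function(population, fitness, cfg) {
  stopifnot(is.list(population), length(population) == length(fitness),
            is(cfg, "GAConfig"))
  N <- length(population)
  best <- which.max(fitness)
  survivors <- vector("list", N)
  survivors[[1]] <- population[[best]]
  for (s in seq_len(N - 1L)) {
    ab <- sample.int(N, 2L, replace = TRUE)
    win <- if (fitness[ab[2]] > fitness[ab[1]]) ab[2] else ab[1]
    survivors[[s + 1L]] <- population[[win]]
  }
  list(survivors = survivors, best = best,
       terminate = any(fitness >= 1))
}

#' Ciphertext-domain fitness of a mapping
#'
#' Evaluates a candidate mapping pair using only ciphertext operations:
#' permute the encrypted fragments, accumulate homomorphic sums into
#' encrypted cut sites, merge-sort the sites, take homomorphic step
#' differences, drop the \code{p + q - t} smallest (the zero-length
#' artifacts, recognisable by order alone), and sum the componentwise
#' absolute differences to the encrypted C. Neither the key nor any
#' plaintext is touched. A residual at or below the public threshold
#' \code{T} certifies an exact reconstruction (fitness 1); otherwise the
#' fitness is \code{1 / (1 + residual / (2 T))}, a monotone score whose
#' ordering across mappings matches the plaintext fitness ordering.
#'
#' @param enc an \linkS4class{EncryptedInstance}.
#' @param mp a \linkS4class{MappingPair}.
#' @return A list with \code{fitness} and \code{residual}.
#' @export
encryptedFitness <- function(enc, mp) {
  stopifnot(is(enc, "EncryptedInstance"), is(mp, "MappingPair"))
  pr <- enc@params
  if (length(mp@mu) != pr$p || length(mp@nu) != pr$q)
    stop("mapping pair does not match the instance dimensions")
  res <- cpp_encrypted_residual(enc@Ac, enc@Bc, enc@Cc, mp@mu, mp@nu)
  list(fitness = if (res <= pr$T) 1 else 1 / (1 + res / (2 * pr$T)),
       residual = res)
}

.asSolution <- function(raw, encrypted, Tpub = NULL) {
  fit <- if (raw$solved) 1
         else if (encrypted) 1 / (1 + raw$value / (2 * Tpub))
         else 1 / (1 + raw$value)
  new("DDPSolution", mapping = mappingPair(raw$mu, raw$nu),
      fitness = fit, residual = raw$value,
      generations = as.integer(raw$generations), encrypted = encrypted)
}

#' Run the QIGA solver
#'
#' \code{solveEncrypted} is the compute-server entry point: it sees only
#' the public-channel payload (ciphertexts and public parameters) and
#' returns the best mapping pair found, terminating as soon as a
#' measurement reaches fitness 1 (residual at noise level) or after
#' \code{gMax} generations. \code{solvePlaintext} runs the identical
#' search loop on a plaintext instance; it exists for paired comparison
#' experiments quantifying the cost of privacy protection.
#'
#' @param enc an \linkS4class{EncryptedInstance}.
#' @param inst a valid \linkS4class{DDPInstance}.
#' @param cfg a \linkS4class{GAConfig}; \code{cfg@seed}, when not NA,
#'   seeds the RNG for a reproducible search.
#' @return A \linkS4class{DDPSolution}.
#' @examples
#' set.seed(7)
#' sess <- encryptInstance(ddpInstance(c(1, 4), c(2, 3), c(1, 1, 3)))
#' solveEncrypted(sess$enc, gaConfig(gMax = 200, seed = 1))
#' @export
solveEncrypted <- function(enc, cfg = gaConfig()) {
  stopifnot(is(enc, "EncryptedInstance"), is(cfg, "GAConfig"))
  pr <- enc@params
  if (pr$p + pr$q - pr$t < 1L)
    stop("inconsistent instance: p + q - t < 1")
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  raw <- cpp_qiga_encrypted(enc@Ac, enc@Bc, enc@Cc, pr$T, cfg@N, cfg@gMax,
                            cfg@pc, cfg@pm, cfg@dtheta, cfg@clamp[1],
                            cfg@clamp[2], cfg@restartAfter)
  .asSolution(raw, TRUE, pr$T)
}

#' @rdname solveEncrypted
#' @export
solvePlaintext <- function(inst, cfg = gaConfig()) {
  stopifnot(is(inst, "DDPInstance"), is(cfg, "GAConfig"))
  if (!isValidInstance(inst))
    stop("instance is invalid (multiset totals differ)")
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  raw <- cpp_qiga_plain(inst@A, inst@B, inst@C, cfg@N, cfg@gMax, cfg@pc,
                        cfg@pm, cfg@dtheta, cfg@clamp[1], cfg@clamp[2],
                        cfg@restartAfter)
  .asSolution(raw, FALSE)
}
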