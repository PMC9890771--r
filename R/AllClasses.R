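#' @useDynLib cipherDDP, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats cor rnorm runif setNames quantile qnorm qunif sd
#' @importFrom graphics abline
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# DDPInstance
# ---------------------------------------------------------------------------

#' Double digest problem instance
#'
#' A DDP instance holds the three fragment-length multisets read off the
#' gels of a double digest experiment: \code{A} (digestion by the first
#' enzyme), \code{B} (second enzyme) and \code{C} (simultaneous digestion).
#' Lengths are positive integers in an arbitrary unit and are stored in
#' non-decreasing order. An instance whose multisets do not share a common
#' total is representable (the experiment can produce one through read-out
#' errors) but is rejected before encryption; see
#' \code{\link{isValidInstance}}.
#'
#' @slot A,B,C numeric vectors of positive integer fragment lengths,
#'   non-decreasing.
#'
#' @seealso \code{\link{ddpInstance}}, \code{\link{validateInstance}}
#' @export
setClass("DDPInstance",
  representation(A = "numeric", B = "numeric", C = "numeric"))

setValidity("DDPInstance", function(object) {
  for (nm in c("A", "B", "C")) {
    v <- slot(object, nm)
    if (length(v) == 0L)
      return(sprintf("multiset %s is empty", nm))
    if (any(!is.finite(v)) || any(v <= 0))
      return(sprintf("multiset %s must contain positive finite lengths", nm))
    if (any(v != round(v)))
      return(sprintf("multiset %s must contain integer lengths", nm))
    if (is.unsorted(v))
      return(sprintf("multiset %s must be stored in non-decreasing order", nm))
  }
  TRUE
})

#' Create a DDP instance
#'
#' Fragment lengths may be given in any order; they are normalised to
#' non-decreasing order on construction. Empty multisets or non-positive,
#' non-integer lengths raise a malformed-instance error. Mismatched totals
#' do not: they make the instance \emph{invalid} rather than malformed
#' (\code{\link{isValidInstance}} returns \code{FALSE}).
#'
#' @param A,B,C numeric vectors of positive integer fragment lengths.
#' @return A \linkS4class{DDPInstance}.
#' @examples
#' inst <- ddpInstance(A = c(1, 4), B = c(2, 3), C = c(1, 1, 3))
#' isValidInstance(inst)
#' @export
ddpInstance <- function(A, B, C) {
  new(Class = "DDPInstance", A = as.numeric(sort(A)), B = as.numeric(sort(B)),
      C = as.numeric(sort(C)))
}

setMethod("show", "DDPInstance", function(object) {
  s <- instanceSums(object)
  cat(sprintf("DDPInstance: p=%d q=%d t=%d; sums A/B/C = %s (%s)\n",
              length(object@A), length(object@B), length(object@C),
              paste(s, collapse = "/"),
              if (isValidInstance(object)) "valid" else "INVALID"))
})

# ---------------------------------------------------------------------------
# MappingPair
# ---------------------------------------------------------------------------

#' Pair of mapping sequences
#'
#' The solution format of the double digest problem: \code{mu} is a
#' permutation of the indices \code{1..p} of \code{A} and \code{nu} a
#' permutation of \code{1..q} of \code{B}. Position \code{i} of the
#' reconstructed physical map carries fragment \code{mu[i]} of \code{A}
#' (and analogously for \code{nu}). Mapping pairs carry no length
#' information, which is why a compute server may return them in the clear.
#'
#' @slot mu,nu integer permutations (1-based).
#' @export
setClass("MappingPair", representation(mu = "integer", nu = "integer"))

setValidity("MappingPair", function(object) {
  for (nm in c("mu", "nu")) {
    v <- slot(object, nm)
    if (length(v) == 0L || !identical(sort(v), seq_along(v)))
      return(sprintf("%s is not a permutation of 1..%d", nm, length(v)))
  }
  TRUE
})

#' @param mu,nu integer permutations of \code{1..p} and \code{1..q}.
#' @rdname MappingPair-class
#' @export
mappingPair <- function(mu, nu) {
  new("MappingPair", mu = as.integer(mu), nu = as.integer(nu))
}

setMethod("show", "MappingPair", function(object) {
  cat("MappingPair\n  mu:", paste(object@mu, collapse = " "),
      "\n  nu:", paste(object@nu, collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# OPHIKey
# ---------------------------------------------------------------------------

#' Secret key of the order-preserving homomorphic index scheme
#'
#' Holds the per-coordinate multipliers \code{k[1..n]} together with the
#' noise budget under which ciphertexts remain comparable. The key never
#' leaves the data owner; nothing in the package can invert a ciphertext
#' with or without it (the scheme has no decryption algorithm).
#'
#' @slot k positive reals, each in (0, 2^10].
#' @slot budget named list with elements \code{pMin} (minimum distance
#'   between distinct plaintexts), \code{LMax} (maximum number of fresh
#'   encryptions folded into any ciphertext by homomorphic addition) and
#'   \code{RBound} (per-encryption cap on the total noise R).
#' @export
setClass("OPHIKey", representation(k = "numeric", budget = "list"))

setValidity("OPHIKey", function(object) {
  k <- object@k
  if (length(k) < 2L) return("key must have at least 2 components")
  if (any(k <= 0) || any(k > 2^10)) return("key components must lie in (0, 2^10]")
  if (sum(k[-length(k)]) == 0) return("k_1 + ... + k_{n-1} must be non-zero")
  b <- object@budget
  need <- c("pMin", "LMax", "RBound")
  if (!all(need %in% names(b))) return("budget must have pMin, LMax, RBound")
  if (b$pMin <= 0 || b$LMax < 1) return("budget requires pMin > 0 and LMax >= 1")
  expect <- min(k) * b$pMin / (2 * b$LMax)
  if (abs(b$RBound - expect) > 1e-9 * expect)
    return("RBound must equal min(k) * pMin / (2 * LMax)")
  TRUE
})

setMethod("show", "OPHIKey", function(object) {
  cat(sprintf("OPHIKey: n=%d components <secret>; budget pMin=%g LMax=%d RBound=%.3g\n",
              length(object@k), object@budget$pMin,
              as.integer(object@budget$LMax), object@budget$RBound))
})

# ---------------------------------------------------------------------------
# Ciphertext
# ---------------------------------------------------------------------------

#' Ciphertext of one fragment length
#'
#' An n-component real vector: \code{c[i] = k[i] * m + r[i]} for
#' \code{i <= n-1} and \code{c[n] = k[n] * sum(r)}, where \code{m} is the
#' plaintext and \code{r} a fresh positive noise vector. Order comparisons
#' use only the first \code{n-1} components; the last one carries the noise
#' checksum and is never compared. \code{depth} counts how many fresh
#' encryptions have been folded into the ciphertext by homomorphic
#' addition or subtraction (the noise budget bookkeeping).
#'
#' @slot c numeric vector of sub-ciphertexts.
#' @slot depth integer addition depth (1 for a fresh encryption).
#' @export
setClass("Ciphertext", representation(c = "numeric", depth = "integer"))

setValidity("Ciphertext", function(object) {
  if (length(object@c) < 2L) return("ciphertext needs at least 2 components")
  if (object@depth < 1L) return("depth must be >= 1")
  TRUE
})

setMethod("show", "Ciphertext", function(object) {
  cat(sprintf("Ciphertext: n=%d depth=%d [%s]\n", length(object@c),
              object@depth,
              paste(formatC(object@c, digits = 6, format = "g"),
                    collapse = ", ")))
})

# ---------------------------------------------------------------------------
# EncryptedInstance
# ---------------------------------------------------------------------------

#' Encrypted DDP instance (the public channel payload)
#'
#' Row \code{i} of \code{Ac} is the ciphertext of the i-th (ascending)
#' fragment of \code{A}, and likewise for \code{Bc}, \code{Cc}. The
#' \code{params} list carries the key-free public parameters \code{n},
#' \code{p}, \code{q}, \code{t} and the acceptance threshold \code{T}:
#' a ciphertext-domain residual at or below \code{T} is noise-level, i.e.
#' the candidate mapping reproduces \code{C} exactly. \code{T} leaks only
#' a bound on the noise scale, not the key or any plaintext.
#'
#' @slot Ac,Bc,Cc numeric matrices (fragments x n sub-ciphertexts).
#' @slot params named list: n, p, q, t, T.
#' @export
setClass("EncryptedInstance",
  representation(Ac = "matrix", Bc = "matrix", Cc = "matrix",
                 params = "list"))

setValidity("EncryptedInstance", function(object) {
  pr <- object@params
  need <- c("n", "p", "q", "t", "T")
  if (!all(need %in% names(pr))) return("params must have n, p, q, t, T")
  if (ncol(object@Ac) != pr$n || ncol(object@Bc) != pr$n ||
      ncol(object@Cc) != pr$n)
    return("ciphertext matrices must have n columns")
  if (nrow(object@Ac) != pr$p || nrow(object@Bc) != pr$q ||
      nrow(object@Cc) != pr$t)
    return("ciphertext matrix rows must match p, q, t")
  if (pr$T <= 0) return("acceptance threshold T must be positive")
  TRUE
})

setMethod("show", "EncryptedInstance", function(object) {
  pr <- object@params
  cat(sprintf("EncryptedInstance: p=%d q=%d t=%d, n=%d sub-ciphertexts, T=%.4g\n",
              pr$p, pr$q, pr$t, pr$n, pr$T))
})

# ---------------------------------------------------------------------------
# GAConfig
# ---------------------------------------------------------------------------

#' Search parameters of the quantum-inspired genetic algorithm
#'
#' @slot N population size.
#' @slot gMax maximum number of generations.
#' @slot pc crossover probability.
#' @slot pm mutation probability (per chromosome, single-qubit NOT).
#' @slot dtheta rotation-gate step in radians.
#' @slot clamp two saturation bounds on the measured-1 probability
#'   \eqn{\beta^2}; rotation never pushes a qubit outside them.
#' @slot restartAfter generations without improvement before the
#'   population collapses back to uniform superposition (stagnation
#'   catastrophe); 0 disables restarts.
#' @slot seed integer seed, or NA to leave the RNG state alone.
#' @export
setClass("GAConfig",
  representation(N = "integer", gMax = "integer", pc = "numeric",
                 pm = "numeric", dtheta = "numeric", clamp = "numeric",
                 restartAfter = "integer", seed = "integer"))

setValidity("GAConfig", function(object) {
  if (object@N < 2L) return("population size N must be >= 2")
  if (object@gMax < 1L) return("gMax must be >= 1")
  if (object@pc < 0 || object@pc > 1 || object@pm < 0 || object@pm > 1)
    return("pc and pm must lie in [0, 1]")
  if (object@dtheta <= 0) return("dtheta must be positive")
  if (length(object@clamp) != 2L || object@clamp[1] <= 0 ||
      object@clamp[2] >= 1 || object@clamp[1] >= object@clamp[2])
    return("clamp must be increasing probabilities inside (0, 1)")
  TRUE
})

#' @param N population size (default 50).
#' @param gMax maximum evolutionary generation (default 10000).
#' @param pc crossover probability (default 0.85).
#' @param pm mutation probability (default 0.5).
#' @param dtheta rotation step in radians (default 0.025 * pi).
#' @param clamp saturation bounds on beta^2 (default c(0.001, 0.999)).
#' @param restartAfter stagnation catastrophe trigger (default 100).
#' @param seed optional integer seed for a reproducible search.
#' @rdname GAConfig-class
#' @export
gaConfig <- function(N = 50, gMax = 10000, pc = 0.85, pm = 0.5,
                     dtheta = 0.025 * pi, clamp = c(0.001, 0.999),
                     restartAfter = 100, seed = NA) {
  new("GAConfig", N = as.integer(N), gMax = as.integer(gMax),
      pc = as.numeric(pc), pm = as.numeric(pm), dtheta = as.numeric(dtheta),
      clamp = as.numeric(clamp), restartAfter = as.integer(restartAfter),
      seed = as.integer(seed))
}

setMethod("show", "GAConfig", function(object) {
  cat(sprintf(
    "GAConfig: N=%d gMax=%d pc=%.2f pm=%.2f dtheta=%.4f restartAfter=%d seed=%s\n",
    object@N, object@gMax, object@pc, object@pm, object@dtheta,
    object@restartAfter,
    if (is.na(object@seed)) "<none>" else object@seed))
})

# ---------------------------------------------------------------------------
# QubitChromosome
# ---------------------------------------------------------------------------

#' Qubit-amplitude chromosome
#'
#' Encodes a candidate mapping pair probabilistically. Each of the
#' \code{p + q} map positions carries \code{b} qubits; qubit \code{j} holds
#' an amplitude pair \eqn{(\alpha_j, \beta_j) = (\cos\theta_j,
#' \sin\theta_j)} and collapses to 1 with probability \eqn{\beta_j^2} on
#' measurement. The measured bit strings are decoded into permutations by
#' random-key ranking (see \code{\link{measureChromosome}}).
#'
#' @slot theta rotation angles, one per qubit, in \eqn{[0, \pi/2]}.
#' @slot p,q permutation sizes.
#' @slot b qubits per position.
#' @export
setClass("QubitChromosome",
  representation(theta = "numeric", p = "integer", q = "integer",
                 b = "integer"))

setValidity("QubitChromosome", function(object) {
  if (length(object@theta) != (object@p + object@q) * object@b)
    return("theta must have (p + q) * b entries")
  if (any(object@theta < 0 | object@theta > pi / 2))
    return("theta must lie in [0, pi/2]")
  TRUE
})

setMethod("show", "QubitChromosome", function(object) {
  cat(sprintf("QubitChromosome: %d positions x %d qubits (p=%d, q=%d)\n",
              object@p + object@q, object@b, object@p, object@q))
})

# ---------------------------------------------------------------------------
# DDPSolution
# ---------------------------------------------------------------------------

#' Solver output
#'
#' @slot mapping the best \linkS4class{MappingPair} found.
#' @slot fitness server-side fitness in (0, 1]; 1 means the residual is at
#'   noise level, i.e. an exact reconstruction of C.
#' @slot residual raw search-domain distance (ciphertext residual for the
#'   encrypted solver, integer L1 distance for the plaintext solver).
#' @slot generations generations consumed.
#' @slot encrypted whether the search ran over ciphertexts.
#' @export
setClass("DDPSolution",
  representation(mapping = "MappingPair", fitness = "numeric",
                 residual = "numeric", generations = "integer",
                 encrypted = "logical"))

setMethod("show", "DDPSolution", function(object) {
  cat(sprintf(
    "DDPSolution (%s domain): fitness=%.4g residual=%.4g generations=%d\n",
    if (object@encrypted) "ciphertext" else "plaintext",
    object@fitness, object@residual, object@generations))
  cat("  mu:", paste(object@mapping@mu, collapse = " "), "\n")
  cat("  nu:", paste(object@mapping@nu, collapse = " "), "\n")
})
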