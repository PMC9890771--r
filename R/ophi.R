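# Order-preserving homomorphic index scheme: a symmetric, probabilistic,
# decryption-free encoding of non-negative integers. A plaintext m becomes
# the n-vector c with c[i] = k[i]*m + r[i] (i <= n-1) and c[n] = k[n]*R,
# R = sum(r). Componentwise addition of ciphertexts encrypts the sum of
# the plaintexts; comparing the first n-1 components decides plaintext
# order whenever the accumulated noise stays within the key's budget.
#
# Noise budget. Fresh noise is capped by RBound = min(k)*pMin/(2*LMax):
# after folding up to LMax fresh encryptions into a ciphertext its noise
# is below min(k)*pMin/2, so two ciphertexts whose plaintexts differ by
# at least pMin still compare correctly on every coordinate. There is no
# decryption algorithm anywhere, by design.

.KEY_MEAN <- 512
.KEY_SD <- 170
.KEY_MAX <- 2^10

#' Generate a key vector
#'
#' Draws \code{n} per-coordinate multipliers from a normal distribution
#' (mean 512, sd 170), rejecting draws outside \code{(0, 2^10]}, and fixes
#' the noise budget: \code{RBound = min(k) * pMin / (2 * LMax)} so that
#' order comparisons survive up to \code{LMax} homomorphic accumulations
#' of plaintexts at least \code{pMin} apart.
#'
#' @param n number of sub-ciphertexts per plaintext (>= 2; default 3).
#' @param pMin minimum distance between distinct plaintexts (1 for
#'   integer fragment lengths).
#' @param LMax maximum number of fresh encryptions any ciphertext may
#'   accumulate.
#' @return An \linkS4class{OPHIKey}.
#' @examples
#' set.seed(1)
#' ophiKeygen(3, LMax = 10)
#' @export
ophiKeygen <- function(n = 3, pMin = 1, LMax = 100) {
  if (n < 2) stop("the key needs at least n = 2 components")
  k <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, .KEY_MEAN, .KEY_SD)
      if (x > 0 && x <= .KEY_MAX) break
    }
    k[i] <- x
  }
  new("OPHIKey", k = k,
      budget = list(pMin = pMin, LMax = as.integer(LMax),
                    RBound = min(k) * pMin / (2 * LMax)))
}

# vectorised fresh-noise draw: one row per plaintext, n-1 positive entries
# summing to R in (0, RBound); half-normal with scale RBound/(2*(n-1))
.drawNoise <- function(len, n, RBound) {
  r <- matrix(abs(rnorm(len * (n - 1), 0, RBound / (2 * (n - 1)))),
              len, n - 1)
  repeat {
    R <- rowSums(r)
    bad <- which(R <= 0 | R >= RBound)
    if (!length(bad)) return(r)
    r[bad, ] <- abs(rnorm(length(bad) * (n - 1), 0, RBound / (2 * (n - 1))))
  }
}

.encryptRows <- function(key, m) {
  n <- length(key@k)
  r <- .drawNoise(length(m), n, key@budget$RBound)
  cbind(outer(m, key@k[-n]) + r, key@k[n] * rowSums(r))
}

#' Encrypt one plaintext
#'
#' Fresh probabilistic encryption: two encryptions of the same value
#' differ in every coordinate. The noise vector may be forced (for unit
#' tests reproducing hand-computed ciphertexts); forced noise bypasses the
#' budget rejection step.
#'
#' @param key an \linkS4class{OPHIKey}.
#' @param m a single non-negative plaintext.
#' @param r optional forced noise vector of length \code{n - 1}.
#' @return A \linkS4class{Ciphertext} with \code{depth = 1}.
#' @examples
#' key <- new("OPHIKey", k = c(2, 3, 5),
#'            budget = list(pMin = 1, LMax = 1L, RBound = 1))
#' ophiEncrypt(key, 10, r = c(0.2, 0.3))  # [20.2, 30.3, 2.5]
#' @export
ophiEncrypt <- function(key, m, r = NULL) {
  stopifnot(is(key, "OPHIKey"), length(m) == 1L, m >= 0)
  n <- length(key@k)
  if (is.null(r)) {
    r <- .drawNoise(1L, n, key@budget$RBound)[1L, ]
  } else if (length(r) != n - 1L || any(r <= 0)) {
    stop("forced noise must be ", n - 1L, " positive values")
  }
  new(Class = "Ciphertext", c = c(key@k[-n] * m + r, key@k[n] * sum(r)),
      depth = 1L)
}

.checkSameShape <- function(x, y) {
  stopifnot(is(x, "Ciphertext"), is(y, "Ciphertext"))
  if (length(x@c) != length(y@c))
    stop("ciphertexts have different numbers of components")
}

#' Homomorphic addition and subtraction
#'
#' Componentwise sum (difference) of two ciphertexts under the same key
#' is a valid ciphertext of the sum (difference) of the plaintexts, with
#' the noises added (subtracted). The addition depth adds; when
#' \code{LMax} is supplied the operation refuses to exceed the budget.
#'
#' @param x,y \linkS4class{Ciphertext}s under the same key.
#' @param LMax optional depth budget to enforce.
#' @return A \linkS4class{Ciphertext}.
#' @export
ophiAdd <- function(x, y, LMax = NULL) {
  .checkSameShape(x, y)
  d <- x@depth + y@depth
  if (!is.null(LMax) && d > LMax)
    stop("addition depth budget exhausted (", d, " > LMax = ", LMax, ")")
  new(Class = "Ciphertext", c = x@c + y@c, depth = d)
}

#' @rdname ophiAdd
#' @export
ophiSubtract <- function(x, y, LMax = NULL) {
  .checkSameShape(x, y)
  d <- x@depth + y@depth
  if (!is.null(LMax) && d > LMax)
    stop("addition depth budget exhausted (", d, " > LMax = ", LMax, ")")
  new(Class = "Ciphertext", c = x@c - y@c, depth = d)
}

#' Order comparison of ciphertexts
#'
#' \code{x} is greater than \code{y} iff every one of the first
#' \code{n - 1} sub-ciphertexts is strictly greater (the last component
#' is a noise checksum and is never inspected). Within the noise budget
#' this reproduces plaintext order exactly for distinct plaintexts.
#' Equal plaintexts carry no order information: their fresh noises decide,
#' yielding either a noise-dominated verdict or — when the coordinates
#' disagree — \code{"indistinguishable"}. Swapping equal values never
#' changes a fragment multiset, so either outcome is harmless downstream.
#'
#' @param x,y \linkS4class{Ciphertext}s under the same key.
#' @return \code{"less"}, \code{"greater"} or \code{"indistinguishable"}.
#' @export
ophiCompare <- function(x, y) {
  .checkSameShape(x, y)
  n <- length(x@c)
  a <- x@c[-n]; b <- y@c[-n]
  if (all(a < b)) "less"
  else if (all(a > b)) "greater"
  else "indistinguishable"
}

#' Ciphertext sort
#'
#' Sorts a list of ciphertexts into ascending plaintext order. Distinct
#' plaintexts are ordered exactly (within the noise budget); duplicates
#' end up adjacent but in a noise-decided order, because equal plaintexts
#' carry no order information a sorter could recover (see
#' \code{\link{ophiCompare}}). Indistinguishable verdicts are treated as
#' ties and keep input order.
#'
#' @param xs list of \linkS4class{Ciphertext}s under one key.
#' @return A list with \code{permutation} (integer vector such that
#'   \code{xs[permutation]} is sorted) and \code{sorted} (the reordered
#'   list).
#' @export
ophiSort <- function(xs) {
  stopifnot(is.list(xs))
  perm <- integer(0)
  for (i in seq_along(xs)) {  # insertion keeping decided pairs ordered
    pos <- length(perm)
    while (pos >= 1L &&
           ophiCompare(xs[[perm[pos]]], xs[[i]]) == "greater") {
      pos <- pos - 1L
    }
    perm <- append(perm, i, after = pos)
  }
  list(permutation = perm, sorted = xs[perm])
}

#' Reorder ciphertexts
#'
#' Applies a permutation to a ciphertext list; the ciphertexts themselves
#' are untouched. This is the only operation the mapping sequences exert
#' on the encrypted data.
#'
#' @param xs list of \linkS4class{Ciphertext}s.
#' @param perm permutation of \code{seq_along(xs)}.
#' @return The reordered list.
#' @export
ophiPermute <- function(xs, perm) {
  stopifnot(is.list(xs))
  if (!identical(sort(as.integer(perm)), seq_along(xs)))
    stop("perm is not a permutation of 1..", length(xs))
  xs[perm]
}

#' Encrypt a DDP instance
#'
#' Encrypts every fragment of A, B and C under one key and assembles the
#' public-channel payload. The budget is sized for the solver's worst
#' case: \code{LMax = 4 * t * (p + q)} accumulations, which makes every
#' ciphertext comparison the solver performs (cut-site merging,
#' step-difference ordering, residual clustering) provably agree with the
#' plaintext computation. The public acceptance threshold is
#' \code{T = (n - 1) * t * (2 * max(p, q) + 1) * RBound}: any mapping
#' whose ciphertext residual is at most \code{T} reproduces C exactly,
#' and residuals of mappings with equal plaintext distance agree to
#' within \code{2 * T}.
#'
#' @param inst a valid \linkS4class{DDPInstance}.
#' @param key optional \linkS4class{OPHIKey}; by default a fresh key with
#'   the instance-sized budget is generated. A supplied key must satisfy
#'   \code{LMax >= p + q}; a budget below the instance-sized one warns
#'   that ciphertext-domain decisions are no longer guaranteed exact.
#' @param n number of sub-ciphertexts when generating a key (default 3).
#' @return A list with \code{enc} (the \linkS4class{EncryptedInstance})
#'   and \code{key} (the secret \linkS4class{OPHIKey}; owner-private).
#' @examples
#' set.seed(1)
#' sess <- encryptInstance(ddpInstance(c(1, 4), c(2, 3), c(1, 1, 3)))
#' sess$enc
#' @export
encryptInstance <- function(inst, key = NULL, n = 3) {
  stopifnot(is(inst, "DDPInstance"))
  if (!isValidInstance(inst))
    stop("refusing to encrypt an invalid instance (multiset totals differ)")
  p <- length(inst@A); q <- length(inst@B); t <- length(inst@C)
  if (p + q - t < 1L)
    stop("inconsistent instance: p + q - t < 1")
  LNeed <- 4L * t * (p + q)
  if (is.null(key)) {
    key <- ophiKeygen(n = n, pMin = 1, LMax = LNeed)
  } else {
    stopifnot(is(key, "OPHIKey"))
    if (key@budget$LMax < p + q)
      stop("key budget LMax must be at least p + q")
    if (key@budget$LMax < LNeed)
      warning("key budget below the instance-sized one; ciphertext-domain ",
              "decisions are no longer guaranteed to match the plaintext")
  }
  nC <- length(key@k)
  Tpub <- (nC - 1) * t * (2 * max(p, q) + 1) * key@budget$RBound
  enc <- new("EncryptedInstance",
             Ac = .encryptRows(key, inst@A),
             Bc = .encryptRows(key, inst@B),
             Cc = .encryptRows(key, inst@C),
             params = list(n = nC, p = p, q = q, t = t, T = Tpub))
  list(enc = enc, key = key)
}

# list-of-Ciphertext view of one encrypted multiset (row-major matrices
# are the storage format; the list view feeds the scalar ophi operations)
.ciphertextList <- function(mat) {
  lapply(seq_len(nrow(mat)), function(i)
    new(Class = "Ciphertext", c = mat[i, ], depth = 1L))
}
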