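# Shared fixtures, all built in code.

# the 5-unit toy molecule: cut sites {1} for the first enzyme, {2} for the
# second; unique solution class {((1,2),(1,2)), ((2,1),(2,1))} (reversal)
toyInstance <- function() ddpInstance(c(1, 4), c(2, 3), c(1, 1, 3))

# key with hand-picked components for exactly reproducible ciphertexts
forcedKey <- function(k = c(2, 3, 5), pMin = 1, LMax = 1L) {
  new("OPHIKey", k = k,
      budget = list(pMin = pMin, LMax = as.integer(LMax),
                    RBound = min(k) * pMin / (2 * LMax)))
}

# generator-produced instance with p, q <= maxPQ (for exhaustive checks)
randomSmallInstance <- function(maxPQ = 5) {
  repeat {
    t <- sample(5:9, 1)
    g <- generateInstance(t)
    p <- length(fragmentsA(g$instance))
    q <- length(fragmentsB(g$instance))
    if (p >= 2 && q >= 2 && p <= maxPQ && q <= maxPQ) return(g)
  }
}

allPerms <- function(n) cipherDDP:::.permutations(n)

# groupwise ordering check: residuals grouped by plaintext distance must
# form disjoint, correctly ordered bands (ties may order arbitrarily
# within a band)
rankingsAgree <- function(D, res, tieBand) {
  lev <- sort(unique(as.vector(D)))
  hi <- -Inf
  for (d in lev) {
    v <- res[D == d]
    if (min(v) <= hi) return(FALSE)          # bands overlap
    if (max(v) - min(v) > tieBand) return(FALSE)  # ties spread too far
    hi <- max(v)
  }
  TRUE
}
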