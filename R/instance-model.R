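# Plaintext model of the double digest problem: cut-site arithmetic,
# implied simultaneous-digest spectrum, fitness and owner-side verification.

#' Validate a DDP instance
#'
#' A well-formed instance is \emph{valid} when the three multisets share a
#' common total length (every digest cuts the same molecule). Mismatched
#' totals yield an invalid verdict, not an error; malformed multisets
#' (empty, non-positive, non-integer) never reach this point because the
#' class constructor rejects them.
#'
#' @param inst a \linkS4class{DDPInstance}.
#' @return A list with \code{valid} (logical) and \code{sums} (named
#'   totals of A, B, C).
#' @examples
#' validateInstance(ddpInstance(c(1, 4), c(2, 3), c(1, 1, 3)))
#' @export
validateInstance <- function(inst) {
  stopifnot(is(inst, "DDPInstance"))
  list(valid = isValidInstance(inst), sums = instanceSums(inst))
}

#' Accumulative summation
#'
#' Running prefix sums of an ordered fragment list: the cut-site
#' coordinates implied by laying the fragments end to end.
#'
#' @param v non-empty numeric vector.
#' @return Numeric vector of the same length; element i is
#'   \code{sum(v[1:i])}.
#' @examples
#' accumulativeSummation(c(1, 2, 3))  # 1 3 6
#' @export
accumulativeSummation <- function(v) {
  if (length(v) == 0L) stop("accumulative summation of an empty vector")
  cumsum(v)
}

#' Step difference
#'
#' Consecutive differences of an ordered coordinate list: the fragment
#' lengths between adjacent cut sites. Inverse of
#' \code{\link{accumulativeSummation}} up to the leading element.
#'
#' @param v non-empty, non-decreasing numeric vector.
#' @return Numeric vector of length \code{length(v) - 1}, all entries
#'   non-negative.
#' @examples
#' stepDifference(c(1, 3, 6))  # 2 3
#' @export
stepDifference <- function(v) {
  if (length(v) == 0L) stop("step difference of an empty vector")
  if (is.unsorted(v)) stop("step difference requires a non-decreasing input")
  diff(v)
}

# shared precondition helper
.checkMappingFits <- function(inst, mp) {
  stopifnot(is(inst, "DDPInstance"), is(mp, "MappingPair"))
  if (!isValidInstance(inst))
    stop("instance is invalid (multiset totals differ)")
  if (length(mp@mu) != length(inst@A) || length(mp@nu) != length(inst@B))
    stop("mapping pair does not match the instance dimensions")
  if (length(inst@A) + length(inst@B) - length(inst@C) < 1L)
    stop("inconsistent instance: p + q - t < 1, no duplicate terminal site")
}

#' Implied simultaneous-digest spectrum
#'
#' Arranging the fragments of A by \code{mu} and of B by \code{nu} places
#' the cut sites of both enzymes on the molecule; the gaps between
#' adjacent sites of the merged set are the fragment lengths a
#' simultaneous digest would have produced. Both accumulated-site lists
#' end at the total molecule length, so at least one of the p + q step
#' differences is a zero-length artifact; the \code{p + q - t} smallest
#' differences (the duplicated terminal and any interior coincidences)
#' are discarded, leaving exactly \code{t} values.
#'
#' @param inst a valid \linkS4class{DDPInstance}.
#' @param mp a \linkS4class{MappingPair} for the instance.
#' @return A list with \code{raw} (the retained step differences in
#'   positional order along the molecule) and \code{values} (the same
#'   multiset in ascending order).
#' @examples
#' inst <- ddpInstance(c(1, 4), c(2, 3), c(1, 1, 3))
#' impliedSpectrum(inst, mappingPair(1:2, 1:2))$values  # 1 1 3
#' @export
impliedSpectrum <- function(inst, mp) {
  .checkMappingFits(inst, mp)
  sites <- sort(c(accumulativeSummation(inst@A[mp@mu]),
                  accumulativeSummation(inst@B[mp@nu])))
  d <- stepDifference(c(0, sites))
  drop <- head(order(d), length(d) - length(inst@C))
  raw <- if (length(drop)) d[-drop] else d
  list(raw = raw, values = sort(raw))
}

#' Distance and fitness of a candidate mapping (plaintext domain)
#'
#' The distance D is the elementwise L1 difference between the ascending
#' implied spectrum and the observed multiset C; the fitness is
#' \code{1 / (1 + D)}, so a fitness of 1 certifies an exact
#' reconstruction.
#'
#' @param inst a valid \linkS4class{DDPInstance}.
#' @param mp a \linkS4class{MappingPair}.
#' @return \code{ddpDistance}: the non-negative integer D.
#'   \code{plainFitness}: the fitness in (0, 1].
#' @examples
#' inst <- ddpInstance(c(1, 4), c(2, 3), c(1, 1, 3))
#' plainFitness(inst, mappingPair(1:2, 1:2))       # 1
#' plainFitness(inst, mappingPair(2:1, 1:2))       # 1/3
#' @export
ddpDistance <- function(inst, mp) {
  .checkMappingFits(inst, mp)
  cpp_plain_distance(inst@A, inst@B, inst@C, mp@mu, mp@nu)
}

#' @rdname ddpDistance
#' @export
plainFitness <- function(inst, mp) 1 / (1 + ddpDistance(inst, mp))

#' Owner-side verification of a returned mapping
#'
#' The stage-5 acceptance check: a mapping is accepted iff its implied
#' spectrum reproduces C exactly (plaintext fitness 1). This is the "simple
#' calculation" that defeats a lazy server returning random mappings.
#'
#' @inheritParams ddpDistance
#' @return \code{TRUE} iff the mapping solves the instance exactly.
#' @export
verifySolution <- function(inst, mp) ddpDistance(inst, mp) == 0

# all permutations of 1..n, one per row (n <= 10 or so)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    idx <- r + seq_len(nrow(sub))
    out[idx, 1L] <- first
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Exhaustive solver (test oracle)
#'
#' Enumerates every permutation pair, evaluates the plaintext fitness, and
#' returns all maximisers. Only feasible for small instances; the
#' enumeration refuses to start beyond \code{cap} pairs.
#'
#' @param inst a valid \linkS4class{DDPInstance}.
#' @param cap maximum number of permutation pairs to enumerate
#'   (default 1e6).
#' @return A list with \code{fitness} (the maximum), \code{distance}
#'   (the corresponding D) and \code{solutions} (a list of
#'   \linkS4class{MappingPair}s attaining it).
#' @examples
#' bruteForceSolve(ddpInstance(c(1, 4), c(2, 3), c(1, 1, 3)))$fitness  # 1
#' @export
bruteForceSolve <- function(inst, cap = 1e6) {
  stopifnot(is(inst, "DDPInstance"))
  if (!isValidInstance(inst))
    stop("instance is invalid (multiset totals differ)")
  p <- length(inst@A); q <- length(inst@B)
  if (factorial(p) * factorial(q) > cap)
    stop("p! * q! exceeds the enumeration cap (", format(cap), ")")
  mus <- .permutations(p)
  nus <- .permutations(q)
  D <- cpp_pairwise_distance(inst@A, inst@B, inst@C, mus, nus)
  best <- min(D)
  idx <- which(D == best, arr.ind = TRUE)
  sols <- lapply(seq_len(nrow(idx)), function(i)
    mappingPair(mus[idx[i, 1], ], nus[idx[i, 2], ]))
  list(fitness = 1 / (1 + best), distance = best, solutions = sols)
}
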