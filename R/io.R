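# JSON (and CSV) serialization of the session artifacts. Instance and key
# files are owner-private; encrypted-instance and mapping files travel the
# public channel.

#' Read and write DDP instances
#'
#' JSON format: an object with arrays \code{A}, \code{B}, \code{C}
#' (any order on disk; normalised ascending on load). CSV alternative:
#' three rows whose first field is the multiset label, e.g.
#' \code{A,1,4}. The format is chosen by file extension.
#'
#' @param file path to a \code{.json} or \code{.csv} file.
#' @param inst a \linkS4class{DDPInstance}.
#' @return \code{readDDPInstance}: a \linkS4class{DDPInstance}.
#' @examples
#' readDDPInstance(system.file("extdata", "example-instance.json",
#'                             package = "cipherDDP"))
#' @export
readDDPInstance <- function(file) {
  if (grepl("\\.csv$", file, ignore.case = TRUE)) {
    rows <- strsplit(trimws(readLines(file)), ",")
    rows <- rows[vapply(rows, length, 1L) > 1L]
    lab <- toupper(vapply(rows, `[`, "", 1L))
    get <- function(nm) {
      i <- match(nm, lab)
      if (is.na(i)) stop("CSV instance file lacks a row labelled ", nm)
      as.numeric(rows[[i]][-1L])
    }
    return(ddpInstance(get("A"), get("B"), get("C")))
  }
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!all(c("A", "B", "C") %in% names(x)))
    stop("instance file must contain A, B and C")
  ddpInstance(x$A, x$B, x$C)
}

#' @rdname readDDPInstance
#' @export
writeDDPInstance <- function(inst, file) {
  stopifnot(is(inst, "DDPInstance"))
  jsonlite::write_json(list(A = inst@A, B = inst@B, C = inst@C), file,
                       digits = NA)
  invisible(file)
}

#' Read and write OPHI keys (owner-private)
#'
#' @param file path to a JSON key file.
#' @param key an \linkS4class{OPHIKey}.
#' @return \code{readOPHIKey}: an \linkS4class{OPHIKey}.
#' @export
readOPHIKey <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("OPHIKey", k = as.numeric(x$k),
      budget = list(pMin = x$budget$p_min,
                    LMax = as.integer(x$budget$L_max),
                    RBound = x$budget$R_bound))
}

#' @rdname readOPHIKey
#' @export
writeOPHIKey <- function(key, file) {
  stopifnot(is(key, "OPHIKey"))
  jsonlite::write_json(
    list(n = length(key@k), k = key@k,
         budget = list(p_min = key@budget$pMin, L_max = key@budget$LMax,
                       R_bound = key@budget$RBound)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read and write encrypted instances (public channel)
#'
#' @param file path to a JSON encrypted-instance file.
#' @param enc an \linkS4class{EncryptedInstance}.
#' @return \code{readEncryptedInstance}: an
#'   \linkS4class{EncryptedInstance}.
#' @export
readEncryptedInstance <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  need <- c("n", "public", "A_c", "B_c", "C_c")
  if (!all(need %in% names(x)))
    stop("malformed encrypted-instance file (schema error)")
  pr <- x$public
  asCt <- function(v) {
    if (is.matrix(v)) return(v)
    matrix(unlist(v), ncol = x$n, byrow = TRUE)  # list of row vectors
  }
  new("EncryptedInstance",
      Ac = asCt(x$A_c), Bc = asCt(x$B_c), Cc = asCt(x$C_c),
      params = list(n = as.integer(x$n), p = as.integer(pr$p),
                    q = as.integer(pr$q), t = as.integer(pr$t),
                    T = as.numeric(pr$T)))
}

#' @rdname readEncryptedInstance
#' @export
writeEncryptedInstance <- function(enc, file) {
  stopifnot(is(enc, "EncryptedInstance"))
  pr <- enc@params
  jsonlite::write_json(
    list(n = pr$n,
         public = list(p = pr$p, q = pr$q, t = pr$t, T = pr$T),
         A_c = enc@Ac, B_c = enc@Bc, C_c = enc@Cc),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read and write mapping files (public channel)
#'
#' @param file path to a JSON mapping file.
#' @param sol a \linkS4class{DDPSolution} (or a list with elements
#'   \code{mu}, \code{nu}, \code{fitness}).
#' @return \code{readMapping}: a list with \code{mapping} (a
#'   \linkS4class{MappingPair}), \code{fitness}, \code{residual} and
#'   \code{generations} (the last two NA when absent).
#' @export
readMapping <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!all(c("mu", "nu") %in% names(x)))
    stop("malformed mapping file (schema error)")
  list(mapping = mappingPair(x$mu, x$nu),
       fitness = if (is.null(x$fitness)) NA_real_ else x$fitness,
       residual = if (is.null(x$residual)) NA_real_ else x$residual,
       generations = if (is.null(x$generations)) NA_integer_
                     else as.integer(x$generations))
}

#' @rdname readMapping
#' @export
writeMapping <- function(sol, file) {
  if (is(sol, "DDPSolution")) {
    payload <- list(mu = sol@mapping@mu, nu = sol@mapping@nu,
                    fitness = sol@fitness, residual = sol@residual,
                    generations = sol@generations)
  } else {
    payload <- sol
  }
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
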