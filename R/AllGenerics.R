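#' @rdname DDPInstance-class
#' @param x a \linkS4class{DDPInstance}.
#' @export
setGeneric("fragmentsA", function(x) standardGeneric("fragmentsA"))

#' @rdname DDPInstance-class
#' @export
setGeneric("fragmentsB", function(x) standardGeneric("fragmentsB"))

#' @rdname DDPInstance-class
#' @export
setGeneric("fragmentsC", function(x) standardGeneric("fragmentsC"))

#' @rdname DDPInstance-class
#' @export
setGeneric("instanceSums", function(x) standardGeneric("instanceSums"))

#' @rdname DDPInstance-class
#' @export
setGeneric("isValidInstance", function(x) standardGeneric("isValidInstance"))

setMethod("fragmentsA", "DDPInstance", function(x) x@A)
setMethod("fragmentsB", "DDPInstance", function(x) x@B)
setMethod("fragmentsC", "DDPInstance", function(x) x@C)

setMethod("instanceSums", "DDPInstance", function(x)
  c(A = sum(x@A), B = sum(x@B), C = sum(x@C)))

setMethod("isValidInstance", "DDPInstance", function(x) {
  s <- instanceSums(x)
  s[["A"]] == s[["B"]] && s[["B"]] == s[["C"]]
})
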