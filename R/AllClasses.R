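#' SignatureSet: a regulator's up/down target-gene signature
#'
#' Holds the disjoint lists of genes called up- and downregulated by one
#' regulator (e.g. the DUX4 target signature obtained by concordance
#' filtering across constructs). The two lists are guaranteed disjoint and
#' free of duplicates.
#'
#' @slot regulator single character, name of the regulator (e.g. "DUX4").
#' @slot up character vector of upregulated target gene ids.
#' @slot down character vector of downregulated target gene ids.
#'
#' @seealso \code{\link{deriveDux4Signature}}, \code{\link{dux4Score}},
#'   \code{\link{writeSignatureGMT}}
#' @export
setClass("SignatureSet",
  representation(regulator = "character", up = "character", down = "character"),
  prototype(regulator = NA_character_, up = character(), down = character())
)

setValidity("SignatureSet", function(object) {
  msg <- NULL
  if (length(object@regulator) != 1L)
    msg <- c(msg, "'regulator' must be a single character string")
  if (anyDuplicated(object@up))
    msg <- c(msg, "duplicated ids in 'up'")
  if (anyDuplicated(object@down))
    msg <- c(msg, "duplicated ids in 'down'")
  common <- intersect(object@up, object@down)
  if (length(common))
    msg <- c(msg, sprintf("up and down lists overlap (e.g. '%s')", common[1L]))
  if (is.null(msg)) TRUE else msg
})

#' Construct a SignatureSet
#'
#' @param regulator regulator name.
#' @param up,down character vectors of gene ids; duplicates are removed
#'   preserving first occurrence. The two lists must be disjoint.
#' @return A \code{\linkS4class{SignatureSet}}.
#' @examples
#' SignatureSet("DUX4", up = c("Zscan4c", "Wnt7b"), down = c("Myog"))
#' @export
SignatureSet <- function(regulator, up = character(), down = character()) {
  new("SignatureSet", regulator = as.character(regulator),
      up = unique(as.character(up)), down = unique(as.character(down)))
}

#' @describeIn SignatureSet-class regulator name
#' @param object,x a \code{SignatureSet}.
#' @export
setGeneric("regulator", function(object) standardGeneric("regulator"))

#' @rdname SignatureSet-class
#' @export
setMethod("regulator", "SignatureSet", function(object) object@regulator)

#' @describeIn SignatureSet-class upregulated gene ids
#' @export
setGeneric("upGenes", function(object) standardGeneric("upGenes"))

#' @rdname SignatureSet-class
#' @export
setMethod("upGenes", "SignatureSet", function(object) object@up)

#' @describeIn SignatureSet-class downregulated gene ids
#' @export
setGeneric("downGenes", function(object) standardGeneric("downGenes"))

#' @rdname SignatureSet-class
#' @export
setMethod("downGenes", "SignatureSet", function(object) object@down)

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet for", object@regulator, "\n")
  cat("  up:  ", length(object@up), "genes",
      if (length(object@up)) paste0("(", paste(head(object@up, 4L), collapse = ", "),
                                    if (length(object@up) > 4L) ", ..." else "", ")"), "\n")
  cat("  down:", length(object@down), "genes",
      if (length(object@down)) paste0("(", paste(head(object@down, 4L), collapse = ", "),
                                      if (length(object@down) > 4L) ", ..." else "", ")"), "\n")
  invisible(NULL)
})

#' GeneSetCollection: named annotation gene sets
#'
#' A light container for GMT-style annotation collections: a named list of
#' character vectors of member gene ids, with one description per set.
#' Set names are unique and members are non-empty and duplicate-free.
#'
#' @slot sets named list of character vectors (member gene ids).
#' @slot descriptions character vector, one per set.
#'
#' @seealso \code{\link{readGMT}}, \code{\link{enrich}}
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character"),
  prototype(sets = list(), descriptions = character())
)

setValidity("GeneSetCollection", function(object) {
  msg <- NULL
  nm <- names(object@sets)
  if (length(object@sets) && (is.null(nm) || any(nm == "")))
    msg <- c(msg, "all sets must be named")
  if (anyDuplicated(nm))
    msg <- c(msg, sprintf("duplicate set name '%s'", nm[duplicated(nm)][1L]))
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "need exactly one description per set")
  if (length(object@sets)) {
    bad <- !vapply(object@sets, function(s) is.character(s) && length(s) > 0L,
                   logical(1L))
    if (any(bad))
      msg <- c(msg, sprintf("set '%s' is empty or not character", nm[bad][1L]))
    dup <- vapply(object@sets, anyDuplicated, integer(1L)) > 0L
    if (any(dup))
      msg <- c(msg, sprintf("set '%s' has duplicated members", nm[dup][1L]))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene ids. Duplicate members
#'   within a set are removed preserving order.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled empty strings if missing).
#' @return A \code{\linkS4class{GeneSetCollection}}.
#' @examples
#' GeneSetCollection(list(myogenesis = c("Myod1", "Myog"),
#'                        apoptosis  = c("Bcl2", "Trp53")))
#' @export
GeneSetCollection <- function(sets = list(), descriptions = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  new("GeneSetCollection", sets = sets, descriptions = as.character(descriptions))
}

#' @describeIn GeneSetCollection-class the named list of member vectors
#' @param object a \code{GeneSetCollection}.
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(object) object@sets)

#' @describeIn GeneSetCollection-class per-set description strings
#' @export
setGeneric("setDescriptions", function(object) standardGeneric("setDescriptions"))

#' @rdname GeneSetCollection-class
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(object)
  setNames(object@descriptions, names(object@sets)))

#' @rdname GeneSetCollection-class
#' @param x a \code{GeneSetCollection}.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname GeneSetCollection-class
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets\n")
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat("  set sizes:", min(sz), "-", max(sz),
        "(median", stats::median(sz), ")\n")
    cat("  names:", paste(head(names(object@sets), 5L), collapse = ", "),
        if (length(object@sets) > 5L) "..." else "", "\n")
  }
  invisible(NULL)
})
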