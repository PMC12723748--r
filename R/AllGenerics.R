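#' @describeIn DimerModel number of residues (all chains)
#' @param x,object a `DimerModel`, `ConfidenceBundle` or `LzipVerdict`
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @describeIn DimerModel chain identifiers in file order
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @describeIn ConfidenceBundle named list of half-open 0-based index ranges
#' @export
setGeneric("chainSpans", function(x) standardGeneric("chainSpans"))

#' @describeIn ConfidenceBundle per-residue pLDDT vector (0-100)
#' @export
setGeneric("plddt", function(x) standardGeneric("plddt"))

#' @describeIn ConfidenceBundle the square PAE matrix (Angstrom)
#' @export
setGeneric("pae", function(x) standardGeneric("pae"))

#' @describeIn LzipVerdict `TRUE` when the model is a valid parallel L-zip
#' @export
setGeneric("isValidLzip", function(x) standardGeneric("isValidLzip"))

#' @describeIn LzipVerdict reason codes for a broken verdict
#' @export
setGeneric("verdictReasons", function(x) standardGeneric("verdictReasons"))

#' @describeIn LzipVerdict number of contiguous interface heptads
#' @export
setGeneric("interfaceHeptads", function(x) standardGeneric("interfaceHeptads"))

#' @describeIn LzipVerdict `"parallel"`, `"antiparallel"` or `"none"`
#' @export
setGeneric("helixOrientation", function(x) standardGeneric("helixOrientation"))

#' @export
setMethod("nResidues", "DimerModel", function(x) nrow(x@residues))
#' @export
setMethod("nResidues", "ConfidenceBundle", function(x) length(x@plddt))
#' @export
setMethod("chainIds", "DimerModel", function(x) x@chainIds)
#' @export
setMethod("chainIds", "ConfidenceBundle", function(x) names(x@chainSpans))

#' @describeIn DimerModel chain spans of the concatenated residue index
#' @export
setMethod("chainSpans", "DimerModel", function(x) {
  res <- x@residues
  spans <- lapply(x@chainIds, function(ch) {
    g <- res$gindex[res$chain == ch]
    c(min(g), max(g) + 1L)
  })
  names(spans) <- x@chainIds
  spans
})
#' @export
setMethod("chainSpans", "ConfidenceBundle", function(x) x@chainSpans)
#' @export
setMethod("plddt", "ConfidenceBundle", function(x) x@plddt)
#' @export
setMethod("pae", "ConfidenceBundle", function(x) x@pae)
#' @export
setMethod("isValidLzip", "LzipVerdict", function(x) x@isValid)
#' @export
setMethod("verdictReasons", "LzipVerdict", function(x) x@reasons)
#' @export
setMethod("interfaceHeptads", "LzipVerdict", function(x) x@interfaceHeptads)
#' @export
setMethod("helixOrientation", "LzipVerdict", function(x) x@orientation)

#' @export
setMethod("show", "DimerModel", function(object) {
  res <- object@residues
  cat(sprintf("DimerModel: %d chain(s), %d residues\n",
              length(object@chainIds), nrow(res)))
  for (ch in object@chainIds) {
    r <- res[res$chain == ch, ]
    cat(sprintf("  chain %s: %d residues (%d-%d)\n", ch, nrow(r),
                min(r$resno), max(r$resno)))
  }
  if (nzchar(object@sourcePath))
    cat("  source:", object@sourcePath, "\n")
})

#' @export
setMethod("show", "ConfidenceBundle", function(object) {
  cat(sprintf("ConfidenceBundle: %d residues", length(object@plddt)))
  if (length(object@chainSpans))
    cat(sprintf(" in %d chain(s) [%s]", length(object@chainSpans),
                paste(names(object@chainSpans), collapse = ",")))
  cat("\n")
  cat(sprintf("  mean pLDDT %.1f; PAE %dx%d; ipTM %s\n",
              mean(object@plddt), nrow(object@pae), ncol(object@pae),
              if (length(object@iptm)) sprintf("%.3f", object@iptm) else "absent"))
})

#' @export
setMethod("show", "LzipVerdict", function(object) {
  if (object@isValid) {
    cat(sprintf("LzipVerdict: VALID parallel L-zip (%d interface heptads, %d contacts)\n",
                object@interfaceHeptads, object@contacts))
  } else {
    cat(sprintf("LzipVerdict: BROKEN [%s]\n",
                paste(object@reasons, collapse = ", ")))
    cat(sprintf("  orientation %s; contacts %d; interface heptads %d\n",
                object@orientation, object@contacts, object@interfaceHeptads))
  }
})
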