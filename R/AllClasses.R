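#' @import methods
NULL

STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA1_TO_3 <- structure(names(AA3_TO_1), names = unname(AA3_TO_1))

#' DimerModel: a parsed multi-chain protein structure
#'
#' Holds backbone atoms (N, CA, C, O, CB) of the standard amino-acid residues
#' of a predicted (or experimental) structure, organised per chain, together
#' with a residue-level table in concatenated chain order.  Residue numbering
#' follows the author numbering of the source file; all matrix work in the
#' package uses the 0-based concatenated index (`gindex` column).
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `ins`, `resid`
#'   (3-letter code), `elety` (atom name), `x`, `y`, `z`.
#' @slot residues data.frame with one row per residue, in concatenated chain
#'   order: `chain`, `resno`, `ins`, `resid`, `gindex` (0-based), CA
#'   coordinates `ca_x/ca_y/ca_z` and CB coordinates `cb_x/cb_y/cb_z`
#'   (`NA` when no CB atom is present, e.g. glycine).
#' @slot chainIds character vector of chain identifiers, in file order.
#' @slot sourcePath path the model was read from ("" for generated models).
#' @slot metadata free-form list; the synthetic generator stores its ground
#'   truth (orientation, register, axis trace) here.
#'
#' @seealso [readStructure()], [crickBackbone()]
#' @export
setClass("DimerModel",
  representation(atoms = "data.frame", residues = "data.frame",
                 chainIds = "character", sourcePath = "character",
                 metadata = "list"),
  prototype(sourcePath = "", metadata = list()))

setValidity("DimerModel", function(object) {
  msgs <- character()
  res <- object@residues
  if (length(object@chainIds) < 1L)
    msgs <- c(msgs, "model must contain at least one chain")
  need <- c("chain", "resno", "resid", "gindex", "ca_x", "ca_y", "ca_z")
  if (!all(need %in% names(res)))
    msgs <- c(msgs, paste("residue table lacks columns:",
                          paste(setdiff(need, names(res)), collapse = ", ")))
  else {
    if (nrow(res) && !identical(sort(res$gindex), 0:(nrow(res) - 1L)))
      msgs <- c(msgs, "gindex must be a bijection onto 0..N-1")
    for (ch in object@chainIds) {
      sub <- res[res$chain == ch, , drop = FALSE]
      rn <- sub$resno
      ins <- if (is.null(sub$ins)) rep("", nrow(sub)) else sub$ins
      if (length(rn) > 1L &&
          (any(diff(rn) < 0) || anyDuplicated(paste(rn, ins))))
        msgs <- c(msgs, sprintf("residue numbers not increasing in chain %s", ch))
    }
    if (any(!is.finite(as.matrix(res[, c("ca_x", "ca_y", "ca_z")]))))
      msgs <- c(msgs, "non-finite CA coordinates")
  }
  if (length(msgs)) msgs else TRUE
})

#' ConfidenceBundle: per-residue predictor confidence for one model
#'
#' Canonical container for AlphaFold/Boltz-style confidence output: a pLDDT
#' vector on the 0-100 scale, a square PAE matrix in Angstrom
#' (`pae[i, j]` = expected error at residue i when aligned on residue j),
#' an optional ipTM scalar, and the chain layout of the concatenated residue
#' index.
#'
#' @slot plddt numeric vector, one value per residue, in `[0, 100]`.
#' @slot pae square numeric matrix, Angstrom, entries >= 0.
#' @slot iptm numeric of length 0 (absent) or 1 (value in `[0, 1]`).
#' @slot chainSpans named list; each element `c(start, end)` is a half-open
#'   0-based index range, and the spans partition `0..N-1`.
#'
#' @seealso [readConfidence()], [synthConfidence()]
#' @export
setClass("ConfidenceBundle",
  representation(plddt = "numeric", pae = "matrix", iptm = "numeric",
                 chainSpans = "list"),
  prototype(iptm = numeric(0)))

setValidity("ConfidenceBundle", function(object) {
  msgs <- character()
  n <- length(object@plddt)
  if (!is.numeric(object@pae) || nrow(object@pae) != ncol(object@pae))
    msgs <- c(msgs, "pae must be a square numeric matrix")
  else if (nrow(object@pae) != n)
    msgs <- c(msgs, sprintf("plddt length (%d) != pae dimension (%d)",
                            n, nrow(object@pae)))
  if (any(object@pae < 0, na.rm = TRUE))
    msgs <- c(msgs, "pae entries must be >= 0")
  if (any(object@plddt < 0 | object@plddt > 100, na.rm = TRUE))
    msgs <- c(msgs, "plddt values must lie in [0, 100]")
  if (length(object@iptm) > 1L)
    msgs <- c(msgs, "iptm must have length 0 or 1")
  if (length(object@iptm) == 1L &&
      (!is.finite(object@iptm) || object@iptm < 0 || object@iptm > 1))
    msgs <- c(msgs, "iptm must lie in [0, 1]")
  sp <- object@chainSpans
  if (length(sp)) {
    idx <- unlist(lapply(sp, function(s) seq.int(s[1], s[2] - 1L)),
                  use.names = FALSE)
    if (!identical(sort(as.integer(idx)), 0:(n - 1L)))
      msgs <- c(msgs, "chainSpans must partition 0..N-1")
  }
  if (length(msgs)) msgs else TRUE
})

#' LzipVerdict: classification of one dimer model
#'
#' Result of [classifyLzip()]: whether the model is a valid parallel leucine
#' zipper, and if not, why.  Reason codes are a subset of `"no_helix_pair"`,
#' `"antiparallel"`, `"minimal_contact"`, `"too_short"`,
#' `"wrong_leu_orientation"`.  A model is valid iff the reason set is empty,
#' and a valid model always has at least one interface heptad.
#'
#' @slot isValid logical scalar.
#' @slot reasons character vector of reason codes (empty when valid).
#' @slot orientation `"parallel"`, `"antiparallel"` or `"none"`.
#' @slot interhelixAngle degrees between the paired helix axes (NA when no
#'   helix pair was found).
#' @slot contacts number of interchain CB-CB contacts in the paired helices.
#' @slot interfaceHeptads number of contiguous heptads on the registered
#'   interface (minimum over the two chains).
#' @slot registerA,registerB heptad assignments (lists as returned by
#'   [assignHeptadRegister()]); empty lists when undetermined.
#' @slot details list with the selected helix segments and contact table.
#'
#' @export
setClass("LzipVerdict",
  representation(isValid = "logical", reasons = "character",
                 orientation = "character", interhelixAngle = "numeric",
                 contacts = "integer", interfaceHeptads = "integer",
                 registerA = "list", registerB = "list", details = "list"),
  prototype(orientation = "none", interhelixAngle = NA_real_,
            contacts = 0L, interfaceHeptads = 0L,
            registerA = list(), registerB = list(), details = list()))

setValidity("LzipVerdict", function(object) {
  msgs <- character()
  allowed <- c("no_helix_pair", "antiparallel", "minimal_contact",
               "too_short", "wrong_leu_orientation")
  if (!all(object@reasons %in% allowed))
    msgs <- c(msgs, "unknown reason code")
  if (object@isValid != (length(object@reasons) == 0L))
    msgs <- c(msgs, "isValid must equal 'no reasons'")
  if (object@isValid && object@interfaceHeptads < 1L)
    msgs <- c(msgs, "a valid L-zip must span at least one interface heptad")
  if (length(msgs)) msgs else TRUE
})
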