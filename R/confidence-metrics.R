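#' Mean pLDDT over a residue region
#'
#' @param bundle a [ConfidenceBundle-class].
#' @param region optional integer vector of 0-based concatenated residue
#'   indices; default is all residues.
#' @return arithmetic mean, on the 0-100 scale.
#' @export
meanPlddt <- function(bundle, region = NULL) {
  p <- plddt(bundle)
  if (is.null(region)) return(mean(p))
  region <- as.integer(region)
  if (!length(region)) stop("empty region")
  if (any(region < 0L | region >= length(p)))
    stop("region indices outside 0..N-1")
  mean(p[region + 1L])
}

#' Mean interchain PAE
#'
#' Mean of the PAE entries over all residue pairs on different chains; both
#' off-diagonal blocks are averaged, so the result does not depend on the
#' orientation convention of the matrix.
#'
#' @param bundle a [ConfidenceBundle-class] with at least two chain spans.
#' @return mean PAE in Angstrom.
#' @export
meanInterchainPae <- function(bundle) {
  sp <- chainSpans(bundle)
  if (length(sp) < 2L)
    stop("mean interchain PAE needs at least 2 chains in the bundle")
  n <- nResidues(bundle)
  chain <- integer(n)
  for (k in seq_along(sp))
    chain[(sp[[k]][1] + 1L):sp[[k]][2]] <- k
  inter <- outer(chain, chain, "!=")
  mean(pae(bundle)[inter])
}

#' Parameters of the ipSAE interface score
#'
#' @param paeCutoff only residue pairs with PAE strictly below this value
#'   (Angstrom) contribute; default 3.
#' @param distCutoff only pairs whose CA-CA distance is strictly below this
#'   value (Angstrom) contribute; default 5.  Use `Inf` to disable the
#'   structural gate (the score then depends on the PAE matrix alone).
#' @param d0Floor lower bound for the TM-score distance scale d0 (Angstrom).
#' @return list of validated parameters.
#' @export
ipsaeParams <- function(paeCutoff = 3, distCutoff = 5, d0Floor = 1) {
  stopifnot(paeCutoff > 0, distCutoff > 0, d0Floor > 0)
  list(paeCutoff = paeCutoff, distCutoff = distCutoff, d0Floor = d0Floor)
}

#' ipSAE: interface score from aligned errors
#'
#' A TM-score-style transform of the interchain PAE restricted to confident
#' residue pairs, designed to resist dilution by disordered regions.  A pair
#' (i, j) across chains qualifies when `pae[i, j] < paeCutoff` and, when a
#' model is supplied and `distCutoff` is finite, the side-chain (CB, with CA
#' fallback for glycine) distance is below `distCutoff` -- side-chain
#' positions carry the knobs-into-holes contacts, whereas backbone CA atoms
#' of even an ideal dimer interface sit further apart than typical distance
#' cutoffs.  For each residue i with `n_i >= 1` qualifying partners,
#'
#'   `d0_i = max(d0Floor, 1.24 * (max(n_i, 19) - 15)^(1/3) - 1.8)`
#'   `s_i  = mean_j 1 / (1 + (pae[i, j] / d0_i)^2)`
#'
#' and the score is the maximum of `s_i` over all residues of both chains
#' (the by-residue variant).  When no pair qualifies the score is 0.
#'
#' @param bundle a [ConfidenceBundle-class] with two or more chains.
#' @param model optional [DimerModel-class] aligned on the same concatenated
#'   index, used for the CA distance gate.
#' @param params an [ipsaeParams()] list.
#' @return score in `[0, 1]`, with attributes `bestResidue` (0-based index
#'   of the maximising residue) and `nPairs` (number of qualifying pairs).
#' @export
ipsae <- function(bundle, model = NULL, params = ipsaeParams()) {
  sp <- chainSpans(bundle)
  if (length(sp) < 2L) stop("ipsae needs at least 2 chains in the bundle")
  n <- nResidues(bundle)
  P <- pae(bundle)
  chain <- integer(n)
  for (k in seq_along(sp))
    chain[(sp[[k]][1] + 1L):sp[[k]][2]] <- k
  qual <- outer(chain, chain, "!=") & (P < params$paeCutoff)
  if (!is.null(model) && is.finite(params$distCutoff)) {
    if (nResidues(model) != n)
      stop(sprintf("shape mismatch: bundle has %d residues, model has %d",
                   n, nResidues(model)))
    res <- model@residues[order(model@residues$gindex), , drop = FALSE]
    cb <- as.matrix(res[, c("cb_x", "cb_y", "cb_z")])
    caM <- as.matrix(res[, c("ca_x", "ca_y", "ca_z")])
    miss <- !is.finite(cb[, 1])
    cb[miss, ] <- caM[miss, ]
    qual <- qual & (crossDist(cb, cb) < params$distCutoff)
  }
  nPairs <- sum(qual)
  if (nPairs == 0L)
    return(structure(0, bestResidue = NA_integer_, nPairs = 0L))
  sBest <- 0
  iBest <- NA_integer_
  for (i in seq_len(n)) {
    js <- which(qual[i, ])
    ni <- length(js)
    if (!ni) next
    d0 <- max(params$d0Floor, 1.24 * (max(ni, 19) - 15)^(1 / 3) - 1.8)
    si <- mean(1 / (1 + (P[i, js] / d0)^2))
    if (si > sBest) { sBest <- si; iBest <- i - 1L }
  }
  structure(sBest, bestResidue = iBest, nPairs = nPairs)
}

#' Extract the stored ipTM scalar
#'
#' ipTM is produced by the predictor and is never recomputed here; a bundle
#' without one yields `NA` so that downstream benchmark rows can be dropped
#' with a logged count.
#'
#' @param bundle a [ConfidenceBundle-class].
#' @return the ipTM value in `[0, 1]`, or `NA_real_` when absent.
#' @export
extractIptm <- function(bundle) {
  if (length(bundle@iptm)) bundle@iptm else NA_real_
}

#' All four interface confidence metrics for one model
#'
#' @param bundle a [ConfidenceBundle-class] (two or more chains).
#' @param model optional [DimerModel-class] for the ipSAE distance gate.
#' @param params an [ipsaeParams()] list.
#' @return one-row data.frame with `iptm`, `ipsae`, `mean_plddt`,
#'   `mean_pae`.
#' @export
interfaceScores <- function(bundle, model = NULL, params = ipsaeParams()) {
  data.frame(iptm = extractIptm(bundle),
             ipsae = as.numeric(ipsae(bundle, model, params)),
             mean_plddt = meanPlddt(bundle),
             mean_pae = meanInterchainPae(bundle))
}
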