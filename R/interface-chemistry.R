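ACIDIC <- c("D", "E")
BASIC <- c("K", "R")

#' Enumerate g-e' residue pairs across a parallel interface
#'
#' In the canonical bZIP pairing, the g residue of heptad k on one helix
#' contacts the e residue of heptad k+1 on the partner helix.  Pairs are
#' generated in both directions (A.g with B.e and B.g with A.e) and are
#' truncated at the termini where no k+1 heptad exists.  Heptad indices are
#' the ones carried by the register assignments (incremented at each 'a').
#'
#' @param registerA,registerB heptad assignments from
#'   [assignHeptadRegister()] (or built by hand with the same fields:
#'   `chain`, `resno`, `labels`, `heptad`, `aa`).
#' @param orientation must be `"parallel"`; the g-e' geometry of antiparallel
#'   interfaces is different and is not scored.
#' @return data.frame with one row per pair: `g_chain`, `g_resno`, `g_aa`,
#'   `e_chain`, `e_resno`, `e_aa`, `heptad_g`.
#' @export
enumerateGePairs <- function(registerA, registerB, orientation = "parallel") {
  if (!identical(orientation, "parallel"))
    stop("g-e' pairing is only defined for parallel dimers")
  one <- function(gr, er) {
    gsel <- gr$labels == "g"
    esel <- er$labels == "e"
    gh <- gr$heptad[gsel]
    eh <- er$heptad[esel]
    m <- match(gh + 1L, eh)
    keep <- !is.na(m)
    if (!any(keep)) return(NULL)
    data.frame(g_chain = gr$chain, g_resno = gr$resno[gsel][keep],
               g_aa = unname(gr$aa[gsel][keep]),
               e_chain = er$chain, e_resno = er$resno[esel][m[keep]],
               e_aa = unname(er$aa[esel][m[keep]]),
               heptad_g = unname(gh[keep]),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(registerA, registerB), one(registerB, registerA))
  if (is.null(out))
    out <- data.frame(g_chain = character(0), g_resno = integer(0),
                      g_aa = character(0), e_chain = character(0),
                      e_resno = integer(0), e_aa = character(0),
                      heptad_g = integer(0))
  rownames(out) <- NULL
  out
}

#' Charge complementarity of g-e' pairs
#'
#' Each pair scores +1 when both residues carry like charge (both acidic
#' D/E or both basic K/R: repulsive), -1 when they carry opposite charges
#' (attractive salt bridge), and 0 otherwise (His and all polar/apolar
#' residues are treated as neutral).  A positive net score flags a
#' repulsive, physically implausible interface.
#'
#' @param pairs data.frame from [enumerateGePairs()].
#' @param basic,acidic one-letter codes counted as charged (override to
#'   e.g. score His as basic).
#' @return list with `net` (sum), `implausible` (`net > 0`) and `perPair`
#'   (the input with a `charge_score` column).
#' @export
chargeComplementarity <- function(pairs, basic = BASIC, acidic = ACIDIC) {
  sgn <- function(aa) ifelse(aa %in% acidic, -1L, ifelse(aa %in% basic, 1L, 0L))
  g <- sgn(pairs$g_aa)
  e <- sgn(pairs$e_aa)
  score <- ifelse(g != 0L & g == e, 1L, ifelse(g != 0L & e != 0L, -1L, 0L))
  pairs$charge_score <- score
  list(net = sum(score), implausible = sum(score) > 0, perPair = pairs)
}

#' Read a g-e' coupling-energy table
#'
#' The table is user-supplied (TSV with columns `g_residue`, `e_residue`,
#' `ddd_g_int_kcal_mol`), holding interaction energies of g-e' residue pairs
#' relative to an Ala-Ala pair.  No energy values ship with the package.
#'
#' @param path TSV file path.
#' @return data.frame with the three columns above.
#' @export
readCouplingTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("g_residue", "e_residue", "ddd_g_int_kcal_mol")
  if (!all(need %in% names(tab)))
    stop("coupling table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Total coupling energy of an interface
#'
#' Sums the supplied per-pair energies over the g-e' pairs covered by the
#' table; pairs absent from the table are excluded and counted, because
#' published tables cover only the common residues at these positions.
#'
#' @param pairs data.frame from [enumerateGePairs()].
#' @param table coupling table from [readCouplingTable()] (keys are ordered:
#'   g residue first).
#' @return list with `total` (kcal/mol over covered pairs), `coverage`
#'   (covered / total pairs), `nCovered`, `nMissing`.
#' @export
couplingEnergy <- function(pairs, table) {
  if (is.null(table) || !nrow(table))
    stop("empty coupling table: supply energies via readCouplingTable()")
  key <- paste(pairs$g_aa, pairs$e_aa)
  m <- match(key, paste(table$g_residue, table$e_residue))
  covered <- !is.na(m)
  list(total = sum(table$ddd_g_int_kcal_mol[m[covered]]),
       coverage = if (nrow(pairs)) mean(covered) else NA_real_,
       nCovered = sum(covered), nMissing = sum(!covered))
}

#' Per-position charge profile of a registered helix
#'
#' Summarises, for each heptad position a-g, which residues occupy it and
#' the net charge, in the manner of a helical-wheel/spiral diagram rendered
#' as text.
#'
#' @param register a heptad assignment (see [assignHeptadRegister()]).
#' @return data.frame with `position` (a-g), `residues` (concatenated
#'   one-letter codes in sequence order) and `net_charge`; printed with
#'   [cat()] it reads as a small wheel table.
#' @export
chargeProfile <- function(register) {
  sgn <- function(aa) ifelse(aa %in% ACIDIC, -1L, ifelse(aa %in% BASIC, 1L, 0L))
  out <- do.call(rbind, lapply(letters[1:7], function(pos) {
    aa <- register$aa[register$labels == pos]
    data.frame(position = pos,
               residues = paste(aa, collapse = ""),
               net_charge = sum(sgn(aa)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
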