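#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two paired coordinate sets, via the SVD of the covariance matrix with a
#' determinant correction that excludes reflections.
#'
#' @param P,Q n x 3 matrices of paired coordinates (n >= 3).  P is the
#'   mobile set, Q the target.
#' @return list with `rotation` (3 x 3, det +1), `translation` (such that
#'   `P %*% rotation + translation` superposes P on Q), `rmsd`, and
#'   `transformed` (the superposed P).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3L || ncol(Q) != 3L)
    stop("P and Q must be equal-size n x 3 matrices")
  if (nrow(P) < 3L) stop("need at least 3 points to superpose")
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP); Qc <- sweep(Q, 2, cQ)
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Pt <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((Pt - Qc)^2)))
  list(rotation = R, translation = cQ - as.numeric(cP %*% R), rmsd = rmsd,
       transformed = sweep(Pt, 2, cQ, "+"))
}

# parse "A:6-40,B:6-40" into a list of (chain, start, end)
parseRangeSpec <- function(spec) {
  if (is.list(spec)) return(spec)
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^\\s*([^:]+):(-?\\d+)-(-?\\d+)\\s*$", p))[[1]]
    if (length(m) != 4L) stop("malformed range spec: ", p)
    list(chain = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  })
}

rangeCa <- function(model, ranges) {
  do.call(rbind, lapply(ranges, function(r) {
    res <- residueRows(model, r$chain)
    res <- res[res$resno >= r$start & res$resno <= r$end, , drop = FALSE]
    as.matrix(res[, c("ca_x", "ca_y", "ca_z")])
  }))
}

#' Iterative superposition with outlier rejection
#'
#' Reproduces the usual structure-alignment refinement: superpose on the
#' currently retained CA pairs, drop pairs deviating by more than
#' `rejectCutoff`, and repeat for up to `cycles` rounds or until no pair is
#' dropped.  Residues are paired 1:1 by position within the given ranges
#' (which must select equal residue counts per paired chain).
#'
#' @param mobile,target [DimerModel-class] objects.
#' @param mobileRange,targetRange range specs: either a string like
#'   `"A:6-40,B:6-40"` or a list of `list(chain, start, end)`.
#' @param cycles maximum refinement cycles (default 5).
#' @param rejectCutoff per-pair deviation cutoff in Angstrom (default 2.0).
#' @return list with `rmsd` (over retained pairs), `nRetained`, `nTotal`,
#'   `cycles` used, `rotation`, `translation`.
#' @export
iterativeAlign <- function(mobile, target, mobileRange, targetRange,
                           cycles = 5L, rejectCutoff = 2.0) {
  P <- rangeCa(mobile, parseRangeSpec(mobileRange))
  Q <- rangeCa(target, parseRangeSpec(targetRange))
  if (nrow(P) != nrow(Q))
    stop(sprintf("ranges select %d mobile vs %d target residues",
                 nrow(P), nrow(Q)))
  keep <- rep(TRUE, nrow(P))
  fit <- NULL
  used <- 0L
  repeat {
    if (sum(keep) < 3L)
      stop("alignment collapse: fewer than 3 residue pairs retained")
    fit <- kabsch(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
    if (used >= cycles) break
    dev <- sqrt(rowSums((sweep(P %*% fit$rotation, 2, fit$translation, "+") - Q)^2))
    drop <- keep & dev > rejectCutoff
    if (!any(drop)) break
    keep <- keep & !drop
    used <- used + 1L
  }
  list(rmsd = fit$rmsd, nRetained = sum(keep), nTotal = nrow(P),
       cycles = used, rotation = fit$rotation, translation = fit$translation)
}
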