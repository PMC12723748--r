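#' Detect alpha-helical segments from CA geometry
#'
#' A sliding window marks positions where the CA(i)-CA(i+3) distance lies in
#' 4.5-6.0 Angstrom and CA(i)-CA(i+4) in 5.5-7.0 Angstrom (the canonical
#' alpha-helical spacings).  Residues covered by any passing window are
#' merged into maximal runs; runs shorter than `minLength` residues are
#' discarded.  Runs are broken at gaps in the author residue numbering.
#'
#' @param model a [DimerModel-class].
#' @param chain chain identifier.
#' @param minLength minimal helix length in residues (default 7, one heptad).
#' @return list of helix segments; each a list with `chain`, `start`, `end`
#'   (author residue numbers, inclusive), `resno` (vector) and `ca`
#'   (coordinate matrix).  Empty list when nothing helical is found.
#' @export
detectHelices <- function(model, chain, minLength = 7L) {
  res <- residueRows(model, chain)
  n <- nrow(res)
  if (n < 5L) return(list())
  ca <- as.matrix(res[, c("ca_x", "ca_y", "ca_z")])
  d <- function(i, j) sqrt(rowSums((ca[i, , drop = FALSE] - ca[j, , drop = FALSE])^2))
  i <- seq_len(n - 4L)
  d3 <- d(i, i + 3L)
  d4 <- d(i, i + 4L)
  win <- d3 >= 4.5 & d3 <= 6.0 & d4 >= 5.5 & d4 <= 7.0
  covered <- logical(n)
  for (k in which(win)) covered[k:(k + 4L)] <- TRUE
  # break runs at numbering gaps (chain breaks)
  brk <- c(FALSE, diff(res$resno) != 1L)
  runs <- list()
  cur <- integer(0)
  for (k in seq_len(n)) {
    if (covered[k] && (length(cur) == 0L || !brk[k])) {
      cur <- c(cur, k)
    } else {
      if (length(cur) >= minLength) runs[[length(runs) + 1L]] <- cur
      cur <- if (covered[k]) k else integer(0)
    }
  }
  if (length(cur) >= minLength) runs[[length(runs) + 1L]] <- cur
  lapply(runs, function(idx) {
    seg <- list(chain = chain, start = res$resno[idx[1]],
                end = res$resno[idx[length(idx)]],
                resno = res$resno[idx],
                ca = ca[idx, , drop = FALSE])
    seg
  })
}

#' Fit the local axis of a helix segment
#'
#' The axis point for residue i is the running mean of CA(i-1..i+1); for an
#' ideal alpha-helix this cancels most of the 100 degree winding and leaves a
#' point within ~0.5 Angstrom of the true axis.  The segment direction is the
#' unit vector from the first to the last axis point (N-to-C sense).
#'
#' @param segment a helix segment from [detectHelices()] (needs `ca`).
#' @return the segment with `axis` (an (n-2) x 3 polyline) and `direction`
#'   (unit 3-vector) added.
#' @export
fitHelixAxis <- function(segment) {
  ca <- segment$ca
  n <- nrow(ca)
  if (n < 7L) stop("helix segment too short to fit an axis (need >= 7 residues)")
  idx <- 2:(n - 1L)
  axis <- (ca[idx - 1L, , drop = FALSE] + ca[idx, , drop = FALSE] +
           ca[idx + 1L, , drop = FALSE]) / 3
  dirv <- axis[nrow(axis), ] - axis[1, ]
  if (vnorm(dirv) < 1e-6)
    stop("degenerate helix axis (collinear or collapsed input)")
  segment$axis <- axis
  segment$direction <- unitv(dirv)
  segment
}

#' Relative orientation of two helix segments
#'
#' @param a,b helix segments with fitted axes (see [fitHelixAxis()]).
#' @return list with `orientation` (`"parallel"` if the inter-axis angle is
#'   below 90 degrees, `"antiparallel"` otherwise -- the 90 degree tie goes
#'   to antiparallel) and `angle` in degrees.
#' @export
pairOrientation <- function(a, b) {
  ang <- acos(max(-1, min(1, sum(a$direction * b$direction)))) * 180 / pi
  list(orientation = if (ang < 90) "parallel" else "antiparallel",
       angle = ang)
}

#' Interchain residue contacts between two helix segments
#'
#' Counts residue pairs whose CB-CB distance (CA for glycine or missing CB)
#' is below `cutoff`.
#'
#' @param model the [DimerModel-class] both segments come from.
#' @param a,b helix segments on different chains.
#' @param cutoff contact distance in Angstrom (default 8.0).
#' @return list with `count` and `pairs` (data.frame `resno_a`, `resno_b`,
#'   `dist`).
#' @export
interchainContacts <- function(model, a, b, cutoff = 8.0) {
  if (identical(a$chain, b$chain))
    stop("contact counting requires segments on different chains")
  cbA <- cbMatrix(model, chain = a$chain, resno = a$resno)
  cbB <- cbMatrix(model, chain = b$chain, resno = b$resno)
  dm <- crossDist(cbA, cbB)
  hit <- which(dm < cutoff, arr.ind = TRUE)
  pairs <- data.frame(resno_a = a$resno[hit[, 1]],
                      resno_b = b$resno[hit[, 2]],
                      dist = dm[hit])
  list(count = nrow(pairs), pairs = pairs[order(pairs$resno_a, pairs$resno_b), ,
                                          drop = FALSE])
}

# nearest point on a polyline (rows of `axis`) for each row of `pts`
nearestAxisPoint <- function(pts, axis) {
  dm <- crossDist(pts, axis)
  axis[max.col(-dm, ties.method = "first"), , drop = FALSE]
}

#' Assign the heptad register of a coiled-coil helix pair
#'
#' Core (a/d) residues are those whose side-chain direction (CA to CB)
#' points toward the partner helix axis (positive projection on the
#' inter-axis vector) and whose CB lies within the contact shell of the
#' partner.  The seven-position register is then extended cyclically from
#' the modal core phase: the phase (0-6) is chosen to put the largest number
#' of detected core residues on the a/d positions, which fixes the a-vs-d
#' distinction through the 3-4 spacing (a to d is +3 residues, d to the next
#' a is +4).  Ties prefer the phase that puts Leu/Ile on d.
#'
#' @param model the [DimerModel-class].
#' @param a,b helix segments on different chains (axes are fitted if absent).
#' @param cutoff contact-shell distance in Angstrom (default 8.0).
#' @return list of two heptad assignments (one per segment); each has
#'   `chain`, `resno`, `labels` (letters a-g, named by residue number),
#'   `heptad` (integer heptad index, incremented at each 'a'), `core`
#'   (residue numbers detected geometrically as core), `confidence`
#'   (fraction of detected core residues consistent with the register) and
#'   `phase`.
#' @export
assignHeptadRegister <- function(model, a, b, cutoff = 8.0) {
  if (is.null(a$axis)) a <- fitHelixAxis(a)
  if (is.null(b$axis)) b <- fitHelixAxis(b)
  one <- function(seg, partner) {
    ca <- caMatrix(model, seg$chain, seg$resno)
    cb <- cbMatrix(model, seg$chain, seg$resno)
    pcb <- cbMatrix(model, partner$chain, partner$resno)
    ownAx <- rbind(seg$axis[1, , drop = FALSE], seg$axis,
                   seg$axis[nrow(seg$axis), , drop = FALSE])  # pad to n rows
    toPartner <- nearestAxisPoint(ca, partner$axis) - ownAx
    side <- cb - ca
    # cosine of the angle between the side-chain direction and the
    # inter-axis vector: ~0.9 for a/d, weakly positive for flanking e/g
    cosang <- rowSums(side * toPartner) /
      pmax(sqrt(rowSums(side^2)) * sqrt(rowSums(toPartner^2)), 1e-9)
    shell <- apply(crossDist(cb, pcb), 1, min) < cutoff
    core <- which(cosang > 0 & shell)
    if (!length(core))
      stop("register undetermined: no core residues face the partner helix")
    s <- core - 1L  # 0-based positions within the segment
    aa1 <- AA3_TO_1[residueRows(model, seg$chain)$resid[
      match(seg$resno, residueRows(model, seg$chain)$resno)]]
    # phase vote weighted by how directly each core residue faces the
    # partner, so the strongly buried a/d positions dominate
    scorePhase <- function(p) sum(cosang[core][((s - p) %% 7L) %in% c(0L, 3L)])
    sc <- vapply(0:6, scorePhase, numeric(1))
    best <- which(sc == max(sc)) - 1L
    if (length(best) > 1L) {
      # prefer phases that put Leu/Ile on the d position
      dcount <- vapply(best, function(p) {
        dpos <- which(((seq_along(seg$resno) - 1L - p) %% 7L) == 3L)
        sum(aa1[dpos] %in% c("L", "I"), na.rm = TRUE)
      }, numeric(1))
      best <- best[which.max(dcount)]
    } else best <- best[1]
    offs <- (seq_along(seg$resno) - 1L - best) %% 7L
    labels <- letters[offs + 1L]
    heptad <- cumsum(offs == 0L)
    names(labels) <- names(heptad) <- as.character(seg$resno)
    list(chain = seg$chain, resno = seg$resno, labels = labels,
         heptad = heptad, core = seg$resno[core],
         confidence = mean(((s - best) %% 7L) %in% c(0L, 3L)), phase = best,
         aa = stats::setNames(aa1, as.character(seg$resno)))
  }
  list(one(a, b), one(b, a))
}

#' Classify a two-chain model as a valid or broken leucine zipper
#'
#' Pipeline: detect helices on both chains, pick the interchain helix pair
#' with the most CB-CB contacts, determine orientation, assign the heptad
#' register, and apply the failure checks.  A model is recorded broken when
#' it shows any of: no contacting helix pair (`no_helix_pair`), antiparallel
#' packing (`antiparallel`), fewer than `contactsMin` interchain contacts
#' (`minimal_contact`), a registered interface shorter than one heptad
#' (`too_short`), or more than half of the d-position Leu/Ile side chains
#' pointing away from the partner axis (`wrong_leu_orientation`).
#'
#' The interface heptad count is the longest contiguous run of heptads that
#' contain at least one contacting core residue, minimised over the two
#' chains.
#'
#' @param model a [DimerModel-class] with exactly two chains.
#' @param contactsMin minimum contact count for a credible interface
#'   (default 4).
#' @param contactCutoff CB-CB contact distance in Angstrom (default 8.0).
#' @return An [LzipVerdict-class].
#' @examples
#' mod <- crickBackbone(synthSequence(5), synthSequence(5))
#' classifyLzip(mod)
#' @export
classifyLzip <- function(model, contactsMin = 4L, contactCutoff = 8.0) {
  if (length(chainIds(model)) != 2L)
    stop("classifyLzip expects exactly 2 chains, got ", length(chainIds(model)))
  ch <- chainIds(model)
  helA <- detectHelices(model, ch[1])
  helB <- detectHelices(model, ch[2])

  broken <- function(reasons, orientation = "none", angle = NA_real_,
                     contacts = 0L, heptads = 0L, regA = list(),
                     regB = list(), details = list()) {
    new("LzipVerdict", isValid = FALSE, reasons = unique(reasons),
        orientation = orientation, interhelixAngle = angle,
        contacts = as.integer(contacts),
        interfaceHeptads = as.integer(heptads),
        registerA = regA, registerB = regB, details = details)
  }
  if (!length(helA) || !length(helB))
    return(broken("no_helix_pair"))

  helA <- lapply(helA, fitHelixAxis)
  helB <- lapply(helB, fitHelixAxis)
  best <- NULL
  for (sa in helA) for (sb in helB) {
    ct <- interchainContacts(model, sa, sb, cutoff = contactCutoff)
    if (is.null(best) || ct$count > best$ct$count)
      best <- list(a = sa, b = sb, ct = ct)
  }
  if (best$ct$count < 1L)
    return(broken("no_helix_pair"))

  ori <- pairOrientation(best$a, best$b)
  reasons <- character(0)
  if (ori$orientation == "antiparallel") reasons <- c(reasons, "antiparallel")
  if (best$ct$count < contactsMin) reasons <- c(reasons, "minimal_contact")

  regs <- tryCatch(assignHeptadRegister(model, best$a, best$b,
                                        cutoff = contactCutoff),
                   error = function(e) NULL)
  heptads <- 0L
  if (is.null(regs)) {
    reasons <- c(reasons, "minimal_contact")
    regA <- regB <- list()
  } else {
    regA <- regs[[1]]; regB <- regs[[2]]
    contactRun <- function(reg, contactRes) {
      ad <- reg$resno[reg$labels %in% c("a", "d")]
      hit <- reg$heptad[as.character(intersect(intersect(reg$core, ad), contactRes))]
      if (!length(hit)) return(0L)
      hs <- sort(unique(hit))
      runs <- split(hs, cumsum(c(1L, diff(hs) != 1L)))
      max(vapply(runs, length, integer(1)))
    }
    heptads <- min(contactRun(regA, unique(best$ct$pairs$resno_a)),
                   contactRun(regB, unique(best$ct$pairs$resno_b)))
    if (heptads < 1L) reasons <- c(reasons, "too_short")

    # d-position Leu/Ile must point toward the partner axis
    dOrientationBad <- function(seg, reg, partner) {
      dres <- as.character(reg$resno[reg$labels == "d"])
      aa <- reg$aa[dres]
      dres <- dres[aa %in% c("L", "I")]
      if (!length(dres)) return(FALSE)
      inward <- dres %in% as.character(reg$core)
      mean(!inward) > 0.5
    }
    if (dOrientationBad(best$a, regA, best$b) ||
        dOrientationBad(best$b, regB, best$a))
      reasons <- c(reasons, "wrong_leu_orientation")
  }

  if (length(reasons))
    return(broken(reasons, ori$orientation, ori$angle, best$ct$count,
                  heptads, regA, regB,
                  details = list(segmentA = best$a, segmentB = best$b,
                                 contacts = best$ct$pairs)))
  new("LzipVerdict", isValid = TRUE, reasons = character(0),
      orientation = ori$orientation, interhelixAngle = ori$angle,
      contacts = as.integer(best$ct$count),
      interfaceHeptads = as.integer(heptads),
      registerA = regA, registerB = regB,
      details = list(segmentA = best$a, segmentB = best$b,
                     contacts = best$ct$pairs))
}
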