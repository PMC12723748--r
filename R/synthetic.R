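#' Crick parameters for ideal two-helix coiled coils
#'
#' Defaults are canonical values for a dimeric coiled coil: superhelix
#' radius 4.9 Angstrom, superhelix pitch 148 Angstrom, minor helix radius
#' 2.26 Angstrom, 3.6 residues per turn, 1.51 Angstrom rise per residue.
#'
#' @param superhelixRadius,superhelixPitch,helixRadius Angstrom.
#' @param residuesPerTurn minor-helix periodicity (lab frame).
#' @param risePerResidue axial rise per residue, Angstrom.
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @param registerOffset integer 0-6 rotating the heptad assignment.
#' @param chainSeparationExtra extra radial separation of chain B, Angstrom
#'   (use ~30 to build non-interacting "separated" fixtures).
#' @return validated parameter list.
#' @export
crickParams <- function(superhelixRadius = 4.9, superhelixPitch = 148,
                        helixRadius = 2.26, residuesPerTurn = 3.6,
                        risePerResidue = 1.51,
                        orientation = c("parallel", "antiparallel"),
                        registerOffset = 0L, chainSeparationExtra = 0) {
  orientation <- match.arg(orientation)
  stopifnot(superhelixRadius > 0, superhelixPitch > 0, helixRadius > 0,
            residuesPerTurn > 0, risePerResidue > 0,
            registerOffset %in% 0:6, chainSeparationExtra >= 0)
  list(superhelixRadius = superhelixRadius, superhelixPitch = superhelixPitch,
       helixRadius = helixRadius, residuesPerTurn = residuesPerTurn,
       risePerResidue = risePerResidue, orientation = orientation,
       registerOffset = as.integer(registerOffset),
       chainSeparationExtra = chainSeparationExtra)
}

#' Build a heptad-patterned synthetic peptide sequence
#'
#' Each heptad is laid out in the order g-a-b-c-d-e-f, with the d position
#' taken heptad-wise from `dPattern` (Leu/Ile), the e and g positions filled
#' with `eg` (the charged specificity positions), a with `a` and b/c/f with
#' `bcf`.
#'
#' @param nHeptads number of heptad repeats.
#' @param dPattern string over `{L, I}` of length `nHeptads` (default all
#'   Leu).
#' @param eg one-letter code for the e and g positions (default `"E"`).
#' @param a,bcf one-letter codes for the remaining positions (defaults
#'   `"V"` and `"A"`).
#' @return amino-acid string of length `7 * nHeptads`.
#' @examples
#' synthSequence(5)                       # all-Glu e/g, all-Leu d
#' synthSequence(5, dPattern = "ILLLL")   # one Leu->Ile mutant
#' @export
synthSequence <- function(nHeptads, dPattern = strrep("L", nHeptads),
                          eg = "E", a = "V", bcf = "A") {
  dp <- strsplit(dPattern, "")[[1]]
  if (length(dp) != nHeptads)
    stop("dPattern length must equal nHeptads")
  codes <- c(dp, eg, a, bcf)
  if (!all(codes %in% names(AA1_TO_3)))
    stop("invalid amino-acid code: ",
         paste(setdiff(codes, names(AA1_TO_3)), collapse = ", "))
  paste(vapply(seq_len(nHeptads), function(k)
    paste0(eg, a, bcf, bcf, dp[k], eg, bcf), character(1)), collapse = "")
}

#' Parse a Table-2-style d-pattern token
#'
#' Tokens such as `"ILLLL_LIILL"` give the d patterns of the two chains; a
#' single pattern (`"LLILL"`) applies to both chains.
#'
#' @param token string matching `^[LI]+(_[LI]+)?$`.
#' @return character vector of two equal-length patterns.
#' @export
parsePairPattern <- function(token) {
  if (!grepl("^[LI]+(_[LI]+)?$", token))
    stop("malformed d-pattern token: ", token)
  parts <- strsplit(token, "_", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, parts)
  if (nchar(parts[1]) != nchar(parts[2]))
    stop("chain patterns differ in length: ", token)
  parts
}

# one chain of an ideal coiled coil; returns CA coordinates, the minor-helix
# axis trace, and idealized N/C/O/CB positions.  `aAnchor` is the 0-based
# index of the first 'a' residue; `reverse=TRUE` makes the chain run N->C
# in the -z sense (antiparallel partner).
crickChain <- function(n, theta0, params, aAnchor, reverse = FALSE) {
  R0 <- params$superhelixRadius
  R1 <- params$helixRadius
  rise <- params$risePerResidue
  w0 <- -2 * pi * rise / params$superhelixPitch
  w1 <- 2 * pi / params$residuesPerTurn - w0
  phaseA <- (180 + 25.7) * pi / 180     # 'a' points inward, slightly offset
  i <- 0:(n - 1)
  s <- if (reverse) (n - 1 - i) else i  # axial residue coordinate
  alph <- phaseA + w1 * (i - aAnchor)
  th <- theta0 + w0 * s
  z <- s * rise
  axis <- cbind(R0 * cos(th), R0 * sin(th), z)
  u <- cbind(cos(th), sin(th), 0)       # outward radial
  dthdz <- w0 / rise
  Tv <- cbind(-R0 * sin(th) * dthdz, R0 * cos(th) * dthdz, 1)
  Tv <- Tv / sqrt(rowSums(Tv^2))
  if (reverse) Tv <- -Tv
  v <- cbind(Tv[, 2] * u[, 3] - Tv[, 3] * u[, 2],
             Tv[, 3] * u[, 1] - Tv[, 1] * u[, 3],
             Tv[, 1] * u[, 2] - Tv[, 2] * u[, 1])
  ca <- axis + R1 * cos(alph) * u + R1 * sin(alph) * v
  cb <- ca + 1.53 * (ca - axis) / sqrt(rowSums((ca - axis)^2))
  # idealized N/C along the chain, O off the carbonyl
  nxt <- rbind(ca[-1, , drop = FALSE], 2 * ca[n, ] - ca[n - 1, ])
  prv <- rbind(2 * ca[1, ] - ca[2, ], ca[-n, , drop = FALSE])
  Nat <- ca + 0.45 * (prv - ca)
  Cat <- ca + 0.45 * (nxt - ca)
  Oat <- Cat + 1.23 * (Cat - axis) / sqrt(rowSums((Cat - axis)^2))
  list(ca = ca, cb = cb, n = Nat, c = Cat, o = Oat, axis = axis)
}

#' Generate an ideal coiled-coil dimer with known ground truth
#'
#' Places both chains on a common left-handed superhelical axis (chain B on
#' the opposite side), with the minor helix phased so that the a/d core
#' positions face the partner by construction.  Antiparallel builds run
#' chain B N-to-C in the opposite axial sense.  The generator's ground
#' truth -- orientation, per-chain heptad register, core residues, and the
#' minor-helix axis trace -- is stored in the model metadata for use as an
#' oracle.
#'
#' @param seqA,seqB amino-acid strings (equal length).
#' @param params a [crickParams()] list.
#' @param registerStart heptad letter of residue 1 (default `"g"`, matching
#'   [synthSequence()]); combined with `params$registerOffset`.
#' @return A [DimerModel-class]; `metadata$truth` holds the annotations.
#' @examples
#' mod <- crickBackbone(synthSequence(5), synthSequence(5))
#' classifyLzip(mod)
#' @export
crickBackbone <- function(seqA, seqB, params = crickParams(),
                          registerStart = "g") {
  if (!nchar(seqA) || nchar(seqA) != nchar(seqB))
    stop("sequences must be non-empty and of equal length")
  n <- nchar(seqA)
  off0 <- (match(registerStart, letters[1:7]) - 1L + params$registerOffset) %% 7L
  aAnchor <- (7L - off0) %% 7L          # 0-based index of the first 'a'
  lettersOf <- function() letters[((seq_len(n) - 1L - aAnchor) %% 7L) + 1L]

  A <- crickChain(n, 0, params, aAnchor)
  thetaB <- pi
  paramsB <- params
  paramsB$superhelixRadius <- params$superhelixRadius + params$chainSeparationExtra
  B <- crickChain(n, thetaB, paramsB, aAnchor,
                  reverse = params$orientation == "antiparallel")

  chainAtoms <- function(ch, seq, geom) {
    aa3 <- unname(AA1_TO_3[strsplit(seq, "")[[1]]])
    if (anyNA(aa3)) stop("invalid amino-acid code in sequence")
    per <- lapply(seq_len(n), function(i) {
      at <- rbind(geom$n[i, ], geom$ca[i, ], geom$c[i, ], geom$o[i, ])
      ety <- c("N", "CA", "C", "O")
      if (aa3[i] != "GLY") { at <- rbind(at, geom$cb[i, ]); ety <- c(ety, "CB") }
      data.frame(chain = ch, resno = i, ins = "", resid = aa3[i], elety = ety,
                 x = at[, 1], y = at[, 2], z = at[, 3],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per)
  }
  atoms <- rbind(chainAtoms("A", seqA, A), chainAtoms("B", seqB, B))
  regLetters <- lettersOf()
  truth <- list(orientation = params$orientation,
                registerA = stats::setNames(regLetters, as.character(1:n)),
                registerB = stats::setNames(regLetters, as.character(1:n)),
                coreA = which(regLetters %in% c("a", "d")),
                coreB = which(regLetters %in% c("a", "d")),
                axisA = A$axis, axisB = B$axis,
                aAnchor = aAnchor, params = params,
                helixSpans = list(A = c(1L, n), B = c(1L, n)))
  newDimerModel(atoms, sourcePath = "",
                metadata = list(truth = truth, generator = "crickBackbone"))
}

#' Write a DimerModel as a PDB file
#'
#' @param model a [DimerModel-class].
#' @param path output path.
#' @export
writeModelPdb <- function(model, path) {
  a <- model@atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resid,
                   elety = a$elety, o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Write a DimerModel as a minimal mmCIF file
#'
#' Emits a bare `atom_site` loop sufficient for structure readers; intended
#' for fixtures and round-trip tests.
#'
#' @param model a [DimerModel-class].
#' @param path output path.
#' @export
writeModelCif <- function(model, path) {
  a <- model@atoms
  elem <- substr(a$elety, 1, 1)
  lines <- c("data_model", "#", "loop_",
             "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.type_symbol", "_atom_site.label_atom_id",
             "_atom_site.label_alt_id", "_atom_site.label_comp_id",
             "_atom_site.label_asym_id", "_atom_site.label_entity_id",
             "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
             "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
             "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
             "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
             "_atom_site.pdbx_PDB_model_num",
             sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
                     seq_len(nrow(a)), elem, a$elety, a$resid, a$chain,
                     a$resno, a$x, a$y, a$z, a$resno, a$resid, a$chain,
                     a$elety),
             "#")
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic confidence bundle for a generated model
#'
#' Emulates the confidence pattern of a well- or poorly-supported interface:
#' high quality draws pLDDT uniformly in 90-98 inside helix spans and 20-40
#' elsewhere, PAE in 0.5-2.5 within and between helix blocks and 15-30
#' elsewhere, and ipTM in 0.7-0.95; low quality keeps the helices locally
#' confident but draws every interchain PAE entry in 10-30 and ipTM in
#' 0.1-0.4.  Deterministic given `seed`.
#'
#' @param model a [DimerModel-class]; helix spans are taken from generator
#'   metadata when present, otherwise detected with [detectHelices()].
#' @param interfaceQuality `"high"` or `"low"`.
#' @param seed integer seed.
#' @return A [ConfidenceBundle-class] with the model's chain spans.
#' @export
synthConfidence <- function(model, interfaceQuality = c("high", "low"),
                            seed = 1L) {
  interfaceQuality <- match.arg(interfaceQuality)
  n <- nResidues(model)
  res <- model@residues
  spans <- model@metadata$truth$helixSpans
  inHelix <- logical(n)
  if (!is.null(spans)) {
    for (ch in names(spans)) {
      sel <- res$chain == ch & res$resno >= spans[[ch]][1] &
        res$resno <= spans[[ch]][2]
      inHelix[res$gindex[sel] + 1L] <- TRUE
    }
  } else {
    for (ch in chainIds(model)) for (seg in detectHelices(model, ch)) {
      sel <- res$chain == ch & res$resno %in% seg$resno
      inHelix[res$gindex[sel] + 1L] <- TRUE
    }
  }
  chainOf <- integer(n)
  sp <- chainSpans(model)
  for (k in seq_along(sp)) chainOf[(sp[[k]][1] + 1L):sp[[k]][2]] <- k

  withSeed(seed, {
    pl <- ifelse(inHelix, stats::runif(n, 90, 98), stats::runif(n, 20, 40))
    helBlock <- outer(inHelix, inHelix, "&")
    P <- matrix(stats::runif(n * n, 15, 30), n, n)
    P[helBlock] <- stats::runif(sum(helBlock), 0.5, 2.5)
    diag(P) <- 0
    if (interfaceQuality == "low") {
      inter <- outer(chainOf, chainOf, "!=")
      P[inter] <- stats::runif(sum(inter), 10, 30)
      ip <- stats::runif(1, 0.1, 0.4)
    } else {
      ip <- stats::runif(1, 0.7, 0.95)
    }
    confidenceBundle(pl, P, iptm = ip, chainSpans = sp)
  })
}

#' Labelled synthetic Z-score populations
#'
#' False pairs draw from Normal(0, 1) and true pairs from Normal(delta, 1),
#' so the expected AUC of a perfect ranking is `pnorm(delta / sqrt(2))`.
#'
#' @param nTrue,nFalse class sizes (>= 1).
#' @param delta mean shift of the true class.
#' @param seed integer seed.
#' @return data.frame with `score` and `label` (`"true"`/`"false"`).
#' @export
synthZscores <- function(nTrue, nFalse, delta, seed = 1L) {
  stopifnot(nTrue >= 1L, nFalse >= 1L)
  withSeed(seed, {
    data.frame(score = c(stats::rnorm(nTrue, delta, 1), stats::rnorm(nFalse, 0, 1)),
               label = rep(c("true", "false"), c(nTrue, nFalse)),
               stringsAsFactors = FALSE)
  })
}
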