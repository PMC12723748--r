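test_that("helix detection finds helices and rejects extended chains", {
  # ideal 21-residue alpha-helix: one segment covering everything
  mod <- caOnlyModel(straightHelixCa(21))
  segs <- detectHelices(mod, "A")
  expect_length(segs, 1L)
  expect_identical(segs[[1]]$start, 1L)
  expect_identical(segs[[1]]$end, 21L)

  # extended strand (3.8 A per residue in a straight line): nothing helical
  strand <- cbind(3.8 * (0:20), 0, 0)
  expect_length(detectHelices(caOnlyModel(strand), "A"), 0L)

  # helix-loop-helix: exactly two segments
  h1 <- straightHelixCa(14)
  loopStart <- h1[14, ] + c(3.8, 0, 0)
  loop <- cbind(loopStart[1] + 3.8 * (0:5), loopStart[2], loopStart[3])
  h2 <- straightHelixCa(14, origin = loop[6, ] + c(6, 0, 2))
  mod2 <- caOnlyModel(rbind(h1, loop, h2))
  segs2 <- detectHelices(mod2, "A")
  expect_length(segs2, 2L)
  expect_gte(min(vapply(segs2, function(s) length(s$resno), integer(1))), 10L)

  # chains shorter than 5 residues give an empty list, not an error
  expect_length(detectHelices(caOnlyModel(straightHelixCa(4)), "A"), 0L)
})

test_that("helix axis fitting recovers direction and is rotation-equivariant", {
  seg <- list(chain = "A", resno = 1:21, ca = straightHelixCa(21))
  fit <- fitHelixAxis(seg)
  expect_equal(nrow(fit$axis), 21L - 2L)
  expect_lt(acos(min(1, sum(fit$direction * c(0, 0, 1)))) * 180 / pi, 2)

  set.seed(42)
  R <- randomRotation()
  fitR <- fitHelixAxis(list(chain = "A", resno = 1:21, ca = seg$ca %*% t(R)))
  expect_lt(acos(min(1, sum(fitR$direction * as.numeric(R %*% c(0, 0, 1))))) *
              180 / pi, 2)

  # coiled-coil helix: fitted axis points stay within 1 A of the generator's
  # minor-helix axis trace
  mod <- validDimer()
  segs <- detectHelices(mod, "A")
  fit2 <- fitHelixAxis(segs[[1]])
  trace <- mod@metadata$truth$axisA
  dev <- apply(fit2$axis, 1, function(p) min(sqrt(colSums((t(trace) - p)^2))))
  expect_lt(max(dev), 1.0)

  expect_error(fitHelixAxis(list(chain = "A", resno = 1:7,
                                 ca = matrix(1, 7, 3))), "degenerate")
})

test_that("pair orientation classifies parallel, antiparallel, and the 90-degree tie", {
  mod <- validDimer()
  a <- fitHelixAxis(detectHelices(mod, "A")[[1]])
  b <- fitHelixAxis(detectHelices(mod, "B")[[1]])
  o <- pairOrientation(a, b)
  expect_identical(o$orientation, "parallel")
  expect_lt(o$angle, 30)

  flipped <- b
  flipped$direction <- -b$direction
  expect_identical(pairOrientation(a, flipped)$orientation, "antiparallel")

  # exact 90 degrees resolves to antiparallel (conservative tie-break)
  o90 <- pairOrientation(list(direction = c(0, 0, 1)),
                         list(direction = c(1, 0, 0)))
  expect_identical(o90$orientation, "antiparallel")
  expect_equal(o90$angle, 90)
})

test_that("interchain contacts count CB pairs inside the cutoff", {
  mod <- validDimer()
  a <- detectHelices(mod, "A")[[1]]
  b <- detectHelices(mod, "B")[[1]]
  ct <- interchainContacts(mod, a, b)
  expect_gte(ct$count, 2 * 5)  # at least two contacts per heptad

  # translating chain B 30 A away removes every contact
  atoms <- mod@atoms
  sel <- atoms$chain == "B"
  atoms$x[sel] <- atoms$x[sel] + 30
  far <- newDimerModel(atoms)
  expect_identical(interchainContacts(far, a, b)$count, 0L)

  # constructed single-contact fixture reports the exact residue pair
  mkChain <- function(ch, xs) {
    do.call(rbind, lapply(seq_along(xs), function(i)
      data.frame(chain = ch, resno = i, ins = "", resid = "ALA",
                 elety = c("CA", "CB"), x = xs[[i]][1],
                 y = xs[[i]][2] + c(0, 0.5), z = xs[[i]][3],
                 stringsAsFactors = FALSE)))
  }
  xsA <- lapply(1:7, function(i) c(i * 10, 0, 0))
  xsB <- lapply(1:7, function(i) c(i * 10, 100, 0))
  xsB[[4]] <- c(30, 7, 0)  # B4 within 8 A of A3 only
  toy <- newDimerModel(rbind(mkChain("A", xsA), mkChain("B", xsB)))
  segA <- list(chain = "A", resno = 1:7)
  segB <- list(chain = "B", resno = 1:7)
  ct1 <- interchainContacts(toy, segA, segB)
  expect_identical(ct1$count, 1L)
  expect_identical(ct1$pairs$resno_a, 3L)
  expect_identical(ct1$pairs$resno_b, 4L)
})

test_that("heptad register is recovered from geometry", {
  mod <- validDimer()
  v <- classifyLzip(mod)
  truth <- mod@metadata$truth$registerA
  core <- names(truth)[truth %in% c("a", "d")]
  estA <- v@registerA$labels
  estB <- v@registerB$labels
  expect_gte(mean(estA[core] == truth[core]), 0.95)
  expect_gte(mean(estB[core] == truth[core]), 0.95)

  # registers are cyclically consistent: label(i+7) == label(i)
  lab <- unname(estA)
  expect_identical(lab[8:length(lab)], lab[1:(length(lab) - 7)])

  # a register-shifted build shifts the assignment by exactly one position
  shifted <- crickBackbone(synthSequence(5), synthSequence(5),
                           crickParams(registerOffset = 1L))
  vs <- classifyLzip(shifted)
  expect_identical(unname(vs@registerA$labels[1:28]),
                   unname(estA[2:29]))

  # Leu occupies the d position in the recovered register
  dres <- names(estA)[estA == "d"]
  expect_true(all(v@registerA$aa[dres] == "L"))
})

test_that("register recovery holds over randomized register offsets", {
  set.seed(7)
  agree <- replicate(50, {
    off <- sample(0:6, 1)
    m <- crickBackbone(synthSequence(4), synthSequence(4),
                       crickParams(registerOffset = off))
    truth <- m@metadata$truth$registerA
    core <- names(truth)[truth %in% c("a", "d")]
    v <- classifyLzip(m)
    mean(c(v@registerA$labels[core] == truth[core],
           v@registerB$labels[core] == truth[core]))
  })
  expect_gte(mean(agree), 0.95)
})

test_that("classification matches generator ground truth on the factorial grid", {
  conditions <- list(
    valid = function(p) crickBackbone(synthSequence(5), synthSequence(5), p),
    separated = function(p) {
      p$chainSeparationExtra <- 30
      crickBackbone(synthSequence(5), synthSequence(5), p)
    },
    short = function(p) crickBackbone("EVAAL", "EVAAL", p),
    ile_d = function(p) crickBackbone(synthSequence(5, dPattern = "IIIII"),
                                      synthSequence(5, dPattern = "IIIII"), p)
  )
  for (ori in c("parallel", "antiparallel")) {
    for (cond in names(conditions)) {
      m <- conditions[[cond]](crickParams(orientation = ori))
      v <- classifyLzip(m)
      expectValid <- ori == "parallel" && cond %in% c("valid", "ile_d")
      expect_identical(isValidLzip(v), expectValid,
                       label = sprintf("%s/%s verdict", ori, cond))
      if (ori == "antiparallel" && cond %in% c("valid", "ile_d"))
        expect_true("antiparallel" %in% verdictReasons(v))
      if (cond == "separated")
        expect_true(any(c("minimal_contact", "no_helix_pair") %in%
                          verdictReasons(v)))
    }
  }
})

test_that("valid five-heptad dimers report five interface heptads", {
  v <- classifyLzip(validDimer())
  expect_true(isValidLzip(v))
  expect_identical(interfaceHeptads(v), 5L)
  expect_identical(helixOrientation(v), "parallel")
})

test_that("classification is invariant under rigid motion and chain swap", {
  mod <- validDimer()
  v0 <- classifyLzip(mod)
  set.seed(11)
  for (k in 1:3) {
    vr <- classifyLzip(transformModel(mod, randomRotation(), rnorm(3, 0, 20)))
    expect_identical(isValidLzip(vr), isValidLzip(v0))
    expect_identical(sort(verdictReasons(vr)), sort(verdictReasons(v0)))
    expect_identical(interfaceHeptads(vr), interfaceHeptads(v0))
  }
  vs <- classifyLzip(swapChains(mod))
  expect_identical(isValidLzip(vs), isValidLzip(v0))
  expect_identical(interfaceHeptads(vs), interfaceHeptads(v0))

  anti <- crickBackbone(synthSequence(5), synthSequence(5),
                        crickParams(orientation = "antiparallel"))
  va <- classifyLzip(anti)
  vas <- classifyLzip(swapChains(anti))
  expect_identical(sort(verdictReasons(vas)), sort(verdictReasons(va)))

  expect_error(classifyLzip(caOnlyModel(straightHelixCa(21))), "2 chains")
})
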