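# five full a-g heptads per chain, Glu at e and g, Leu at d
egSeq <- function(n = 5, eg = "E") paste(rep(paste0("VAA", "L", eg, "A", eg), n),
                                         collapse = "")

test_that("g-e' enumeration follows registered heptad indices", {
  # 5 full heptads starting at 'a': the g of heptad k pairs the partner's e
  # of heptad k+1, and the last g has no partner: 4 pairs per direction
  rA <- makeRegister("A", egSeq(), startLetter = "a")
  rB <- makeRegister("B", egSeq(), startLetter = "a")
  pairs <- enumerateGePairs(rA, rB)
  expect_identical(nrow(pairs), 8L)
  expect_identical(sum(pairs$g_chain == "A"), 4L)

  # a single heptad has no k+1 heptad: no pairs
  r1A <- makeRegister("A", substr(egSeq(1), 1, 7), startLetter = "a")
  r1B <- makeRegister("B", substr(egSeq(1), 1, 7), startLetter = "a")
  expect_identical(nrow(enumerateGePairs(r1A, r1B)), 0L)

  # misaligned registers pair by heptad index, not raw sequence position
  rBshift <- makeRegister("B", egSeq(), startLetter = "a", resnoStart = 100L)
  pairs2 <- enumerateGePairs(rA, rBshift)
  expect_identical(nrow(pairs2), 8L)
  gA <- pairs2[pairs2$g_chain == "A", ]
  expect_identical(gA$e_resno, gA$g_resno - 2L + 99L + 7L)

  expect_error(enumerateGePairs(rA, rB, orientation = "antiparallel"),
               "parallel")
})

test_that("charge complementarity scores like/opposite charges", {
  mk <- function(g, e) data.frame(g_chain = "A", g_resno = 1L, g_aa = g,
                                  e_chain = "B", e_resno = 12L, e_aa = e,
                                  heptad_g = 1L, stringsAsFactors = FALSE)
  expect_identical(chargeComplementarity(mk("E", "K"))$net, -1L)
  expect_identical(chargeComplementarity(mk("E", "E"))$net, 1L)
  expect_identical(chargeComplementarity(mk("E", "S"))$net, 0L)
  expect_identical(chargeComplementarity(mk("K", "R"))$net, 1L)
  expect_identical(chargeComplementarity(mk("H", "E"))$net, 0L)  # His neutral

  # all-Glu e/g homodimer-like interface: every pair repulsive
  rA <- makeRegister("A", egSeq(), startLetter = "a")
  rB <- makeRegister("B", egSeq(), startLetter = "a")
  pairs <- enumerateGePairs(rA, rB)
  cc <- chargeComplementarity(pairs)
  expect_identical(cc$net, 8L)
  expect_true(cc$implausible)

  # antisymmetry: inverting the charges of one chain's e/g flips every
  # attraction/repulsion pair
  kSeq <- egSeq(eg = "K")
  rBk <- makeRegister("B", kSeq, startLetter = "a")
  ccX <- chargeComplementarity(enumerateGePairs(rA, rBk))
  expect_identical(ccX$net, -cc$net)
})

test_that("coupling energies sum over covered pairs only", {
  rA <- makeRegister("A", egSeq(), startLetter = "a")
  rB <- makeRegister("B", egSeq(), startLetter = "a")
  pairs <- enumerateGePairs(rA, rB)

  tabFile <- tempfile(fileext = ".tsv")
  writeLines(c("g_residue\te_residue\tddd_g_int_kcal_mol", "E\tE\t1.0"), tabFile)
  tab <- readCouplingTable(tabFile)
  ce <- couplingEnergy(pairs, tab)
  expect_equal(ce$total, 8.0)
  expect_equal(ce$coverage, 1.0)

  # a pair absent from the table is excluded and counted
  tab2 <- data.frame(g_residue = "E", e_residue = "K",
                     ddd_g_int_kcal_mol = -1.5)
  ce2 <- couplingEnergy(pairs, tab2)
  expect_identical(ce2$nCovered, 0L)
  expect_lt(ce2$coverage, 1.0)

  # any table with attraction below repulsion ranks the heterodimeric
  # interface below the homodimeric one
  tab3 <- data.frame(g_residue = c("E", "E"), e_residue = c("E", "K"),
                     ddd_g_int_kcal_mol = c(1.0, -1.5))
  rBk <- makeRegister("B", egSeq(eg = "K"), startLetter = "a")
  hetero <- couplingEnergy(enumerateGePairs(rA, rBk), tab3)
  # only the A.g(E) -> B.e(K) direction is covered for the heterodimer
  expect_lt(hetero$total / hetero$nCovered, ce$total / ce$nCovered)

  expect_error(couplingEnergy(pairs, data.frame()), "empty coupling table")
  expect_error(readCouplingTable(tabFile2 <- {
    f <- tempfile(); writeLines("a\tb", f); f
  }), "columns")
})

test_that("charge profiles summarise heptad positions as a text wheel", {
  reg <- makeRegister("A", egSeq(), startLetter = "a")
  prof <- chargeProfile(reg)
  expect_identical(prof$position, letters[1:7])
  expect_identical(prof$residues[prof$position == "e"], "EEEEE")
  expect_identical(prof$net_charge[prof$position == "e"], -5L)
  expect_identical(prof$net_charge[prof$position == "g"], -5L)
  expect_identical(prof$residues[prof$position == "d"], "LLLLL")

  neutral <- makeRegister("A", strrep("A", 35), startLetter = "a")
  expect_true(all(chargeProfile(neutral)$net_charge == 0L))
})

test_that("geometric registers from the classifier feed the chemistry screen", {
  mod <- crickBackbone(synthSequence(5), synthSequence(5))
  v <- classifyLzip(mod)
  pairs <- enumerateGePairs(v@registerA, v@registerB)
  expect_gt(nrow(pairs), 0L)
  expect_true(all(pairs$g_aa == "E") && all(pairs$e_aa == "E"))
  cc <- chargeComplementarity(pairs)
  expect_true(cc$implausible)  # the all-Glu design is self-repulsive
})
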