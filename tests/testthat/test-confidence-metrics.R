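twoChainBundle <- function(pae, plddt = NULL, iptm = NULL) {
  n <- nrow(pae)
  if (is.null(plddt)) plddt <- rep(90, n)
  confidenceBundle(plddt, pae,
                   iptm = iptm,
                   chainSpans = list(A = c(0L, n %/% 2L), B = c(n %/% 2L, n)))
}

test_that("mean pLDDT averages the requested region", {
  b <- twoChainBundle(matrix(1, 2, 2), plddt = c(90, 100))
  expect_equal(meanPlddt(b), 95)
  expect_equal(meanPlddt(b, region = 1L), 100)
  expect_error(meanPlddt(b, region = integer(0)), "empty region")
  expect_error(meanPlddt(b, region = 5L), "outside")

  # block structure: helix residues at 95, coil at 30
  b2 <- confidenceBundle(c(95, 95, 30, 30), matrix(1, 4, 4))
  expect_equal(meanPlddt(b2, region = c(0L, 1L)), 95)
})

test_that("mean interchain PAE averages both off-diagonal blocks", {
  P <- matrix(0, 4, 4)
  P[1:2, 3:4] <- 4; P[3:4, 1:2] <- 4
  expect_equal(meanInterchainPae(twoChainBundle(P)), 4)

  P2 <- matrix(0, 4, 4)
  P2[1:2, 3:4] <- c(2, 2, 6, 6); P2[3:4, 1:2] <- c(2, 2, 6, 6)
  expect_equal(meanInterchainPae(twoChainBundle(P2)), 4)

  # asymmetric matrix gives the same answer as its transpose
  P3 <- matrix(0, 4, 4)
  P3[1:2, 3:4] <- 1; P3[3:4, 1:2] <- 7
  expect_equal(meanInterchainPae(twoChainBundle(P3)),
               meanInterchainPae(twoChainBundle(t(P3))))

  # constant interchain matrix returns the constant
  P4 <- matrix(3.3, 6, 6); diag(P4) <- 0
  expect_equal(meanInterchainPae(twoChainBundle(P4)), 3.3)

  expect_error(meanInterchainPae(confidenceBundle(rep(90, 4), matrix(1, 4, 4))),
               "2 chains")
})

test_that("ipsae matches the closed-form oracle on toy matrices", {
  # all interchain PAE zero: every term is 1 whatever d0, so the score is 1
  P <- matrix(0, 4, 4)
  expect_equal(as.numeric(ipsae(twoChainBundle(P))), 1.0)

  # nothing under the PAE cutoff: declared convention is 0
  P1 <- matrix(10, 4, 4); diag(P1) <- 0
  expect_equal(as.numeric(ipsae(twoChainBundle(P1))), 0)

  # one qualifying pair with pae = 2:
  # d0 = max(1, 1.24 * (max(1, 19) - 15)^(1/3) - 1.8) = max(1, 0.1684...) = 1
  # s  = 1 / (1 + (2 / 1)^2) = 0.2
  P2 <- matrix(10, 2, 2); diag(P2) <- 0
  P2[1, 2] <- 2
  b2 <- confidenceBundle(c(90, 90), P2,
                         chainSpans = list(A = c(0L, 1L), B = c(1L, 2L)))
  expect_equal(as.numeric(ipsae(b2)), 1 / (1 + 4))
  expect_identical(attr(ipsae(b2), "nPairs"), 1L)

  # brute-force oracle (explicit loops) on a random two-chain matrix
  set.seed(5)
  n <- 10L
  P3 <- matrix(runif(n * n, 0, 6), n, n); diag(P3) <- 0
  b3 <- confidenceBundle(rep(90, n), P3,
                         chainSpans = list(A = c(0L, 5L), B = c(5L, n)))
  cutoff <- 3
  chain <- rep(1:2, each = 5)
  best <- 0
  for (i in 1:n) {
    js <- which(chain != chain[i] & P3[i, ] < cutoff)
    if (!length(js)) next
    d0 <- max(1, 1.24 * (max(length(js), 19) - 15)^(1 / 3) - 1.8)
    best <- max(best, mean(1 / (1 + (P3[i, js] / d0)^2)))
  }
  expect_equal(as.numeric(ipsae(b3)), best, tolerance = 1e-12)
})

test_that("ipsae respects its range and monotonicity invariants", {
  set.seed(9)
  for (k in 1:20) {
    n <- 8L
    P <- matrix(runif(n * n, 0, 8), n, n); diag(P) <- 0
    b <- confidenceBundle(rep(90, n), P,
                          chainSpans = list(A = c(0L, 4L), B = c(4L, n)))
    s0 <- as.numeric(ipsae(b))
    expect_gte(s0, 0); expect_lte(s0, 1)
    # raising a qualifying entry (still below the cutoff) cannot raise the score
    qual <- which(P < 3 & row(P) <= 4 & col(P) > 4, arr.ind = TRUE)
    if (nrow(qual)) {
      ij <- qual[1, ]
      P2 <- P
      P2[ij[1], ij[2]] <- min(2.99, P[ij[1], ij[2]] + 0.5)
      b2 <- confidenceBundle(rep(90, n), P2, chainSpans = chainSpans(b))
      expect_lte(as.numeric(ipsae(b2)), s0 + 1e-12)
    }
  }
})

test_that("ipsae with an infinite distance cutoff ignores the structure", {
  mod <- validDimer()
  b <- synthConfidence(mod, "high", seed = 2)
  free <- ipsaeParams(distCutoff = Inf)
  expect_equal(as.numeric(ipsae(b, mod, free)), as.numeric(ipsae(b, NULL, free)))
  # the gated score counts no more pairs than the structure-free one
  expect_lte(attr(ipsae(b, mod), "nPairs"), attr(ipsae(b, NULL, free), "nPairs"))
})

test_that("ipTM is extracted verbatim or reported absent", {
  b <- twoChainBundle(matrix(1, 4, 4), iptm = 0.83)
  expect_equal(extractIptm(b), 0.83)
  expect_identical(extractIptm(twoChainBundle(matrix(1, 4, 4))), NA_real_)
  expect_equal(extractIptm(twoChainBundle(matrix(1, 4, 4), iptm = 1.0)), 1.0)
})

test_that("interfaceScores assembles all four metrics", {
  mod <- validDimer()
  b <- synthConfidence(mod, "high", seed = 4)
  sc <- interfaceScores(b, mod)
  expect_named(sc, c("iptm", "ipsae", "mean_plddt", "mean_pae"))
  expect_true(sc$ipsae > 0.5)       # confident interface
  expect_true(sc$mean_pae < 3)
  bl <- synthConfidence(mod, "low", seed = 4)
  scl <- interfaceScores(bl, mod)
  expect_identical(scl$ipsae, 0)    # no interchain pair under the cutoff
  expect_true(scl$mean_pae > 10)
})
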