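# fixture builders shared across the suite; everything is generated in code

# CA trace of an ideal straight alpha-helix along `direction`
straightHelixCa <- function(n, radius = 2.26, rise = 1.51, omega = 2 * pi / 3.6,
                            origin = c(0, 0, 0)) {
  i <- 0:(n - 1)
  cbind(radius * cos(omega * i), radius * sin(omega * i), rise * i) +
    matrix(origin, n, 3, byrow = TRUE)
}

# minimal one-chain model from a CA matrix (CB omitted)
caOnlyModel <- function(ca, chain = "A", resid = "ALA", resnoStart = 1L) {
  n <- nrow(ca)
  atoms <- data.frame(chain = chain, resno = seq.int(resnoStart, length.out = n),
                      ins = "", resid = resid, elety = "CA",
                      x = ca[, 1], y = ca[, 2], z = ca[, 3],
                      stringsAsFactors = FALSE)
  newDimerModel(atoms)
}

# random proper rotation matrix
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid transform to every atom of a model
transformModel <- function(model, R = diag(3), t = c(0, 0, 0)) {
  a <- model@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]; a$y <- xyz[, 2] + t[2]; a$z <- xyz[, 3] + t[3]
  newDimerModel(a, sourcePath = model@sourcePath, metadata = model@metadata)
}

# swap the two chains (order and identity)
swapChains <- function(model) {
  a <- model@atoms
  a$chain <- ifelse(a$chain == "A", "B", "A")
  a <- a[order(match(a$chain, c("A", "B"))), ]
  newDimerModel(a)
}

# hand-built heptad register (the shape assignHeptadRegister returns)
makeRegister <- function(chain, seq, startLetter = "a", resnoStart = 1L) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  off0 <- match(startLetter, letters[1:7]) - 1L
  offs <- (seq_len(n) - 1L + off0) %% 7L
  labels <- letters[offs + 1L]
  heptad <- cumsum(offs == 0L)
  resno <- seq.int(resnoStart, length.out = n)
  names(labels) <- names(heptad) <- as.character(resno)
  list(chain = chain, resno = resno, labels = labels, heptad = heptad,
       core = resno[labels %in% c("a", "d")], confidence = 1, phase = off0,
       aa = stats::setNames(aa, as.character(resno)))
}

# O(n^2) concordance oracle for the AUC (ties count one half)
bruteAuc <- function(value, label) {
  vt <- value[label == "true"]; vf <- value[label == "false"]
  cmp <- outer(vt, vf, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# valid 5-heptad generator dimer, memoised for speed
validDimer <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- crickBackbone(synthSequence(5), synthSequence(5))
    cache
  }
})
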