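# small internal helpers shared across modules

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

# pairwise Euclidean distances between the rows of two matrices
crossDist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# run `expr` under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# stable hash of a parameter list, for run provenance
paramHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(unlist(x)), unlist(x), sep = "="), f)
  unname(tools::md5sum(f))
}

#' CA coordinates of a model
#'
#' @param model a [DimerModel-class].
#' @param chain optional chain filter.
#' @param resno optional residue-number filter.
#' @return n x 3 matrix of CA coordinates, rows named `chain:resno`.
#' @export
caMatrix <- function(model, chain = NULL, resno = NULL) {
  res <- model@residues
  if (!is.null(chain)) res <- res[res$chain == chain, , drop = FALSE]
  if (!is.null(resno)) res <- res[res$resno %in% resno, , drop = FALSE]
  m <- as.matrix(res[, c("ca_x", "ca_y", "ca_z")])
  rownames(m) <- paste(res$chain, res$resno, sep = ":")
  m
}

#' CB coordinates of a model, with CA fallback
#'
#' Glycine (and any residue without a CB atom) falls back to its CA
#' position, so the result always has one row per residue.
#'
#' @inheritParams caMatrix
#' @return n x 3 matrix, rows named `chain:resno`.
#' @export
cbMatrix <- function(model, chain = NULL, resno = NULL) {
  res <- model@residues
  if (!is.null(chain)) res <- res[res$chain == chain, , drop = FALSE]
  if (!is.null(resno)) res <- res[res$resno %in% resno, , drop = FALSE]
  m <- as.matrix(res[, c("cb_x", "cb_y", "cb_z")])
  ca <- as.matrix(res[, c("ca_x", "ca_y", "ca_z")])
  miss <- !is.finite(m[, 1])
  m[miss, ] <- ca[miss, ]
  rownames(m) <- paste(res$chain, res$resno, sep = ":")
  m
}

residueRows <- function(model, chain) {
  model@residues[model@residues$chain == chain, , drop = FALSE]
}
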