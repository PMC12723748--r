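#' Convert an array Z-score to a Newman rank
#'
#' Strict-inequality thresholds: Z > 20 gives rank 6, > 10 rank 5, > 5
#' rank 4, > 2.5 rank 3, > 1.5 rank 2, > 1 rank 1, anything else rank 0
#' (rank 0 pairs are excluded from analysis downstream).
#'
#' @param z numeric vector of Z-scores (finite).
#' @return integer vector of ranks 0-6.
#' @export
newmanRank <- function(z) {
  if (any(!is.finite(z))) stop("non-finite Z-score")
  cuts <- c(1, 1.5, 2.5, 5, 10, 20)
  vapply(z, function(x) sum(x > cuts), integer(1))
}

#' Label dimer pairs as true/false binders from Newman ranks
#'
#' Rank 4 or higher is labelled a likely (true) dimer, ranks 1-3 unlikely
#' (false), and rank 0 is excluded (insufficient or inconsistent array
#' data).  An alternative strict split (true only above 4, false only below
#' 3, rank 3 and 4 excluded) is available for sensitivity checks.
#'
#' @param rank integer vector of ranks 0-6.
#' @param split `"ge4"` (default: true >= 4, false 1-3) or `"strict"`
#'   (true > 4, false < 3).
#' @return list with `label` (factor `true`/`false`/`excluded`), `nTrue`,
#'   `nFalse`, `nExcluded`.
#' @export
labelPairs <- function(rank, split = c("ge4", "strict")) {
  split <- match.arg(split)
  if (any(rank < 0 | rank > 6)) stop("ranks must lie in 0..6")
  lab <- rep("excluded", length(rank))
  if (split == "ge4") {
    lab[rank >= 4] <- "true"
    lab[rank >= 1 & rank <= 3] <- "false"
  } else {
    lab[rank > 4] <- "true"
    lab[rank >= 1 & rank < 3] <- "false"
  }
  lab <- factor(lab, levels = c("true", "false", "excluded"))
  list(label = lab, nTrue = sum(lab == "true"), nFalse = sum(lab == "false"),
       nExcluded = sum(lab == "excluded"))
}

#' ROC curve and AUC by Mann-Whitney concordance
#'
#' AUC is the probability that a randomly chosen true pair outscores a
#' randomly chosen false pair, with ties counting one half (computed exactly
#' via midranks).  The ROC polyline comes from a threshold sweep over the
#' unique score values; its trapezoidal area equals the concordance AUC.
#' For metrics where small is good (mean PAE), use
#' `polarity = "lower-is-positive"`.
#'
#' @param value numeric metric values.
#' @param label factor or character with levels `true`/`false` (rows labelled
#'   `excluded` are dropped).
#' @param polarity `"higher-is-positive"` (default) or
#'   `"lower-is-positive"`.
#' @return list of class `ROCResult`: `auc`, `points` (data.frame `fpr`,
#'   `tpr`), `nTrue`, `nFalse`, `polarity`.
#' @export
rocAuc <- function(value, label,
                   polarity = c("higher-is-positive", "lower-is-positive")) {
  polarity <- match.arg(polarity)
  keep <- label %in% c("true", "false") & is.finite(value)
  value <- value[keep]
  lab <- as.character(label[keep])
  nT <- sum(lab == "true"); nF <- sum(lab == "false")
  if (nT < 1L || nF < 1L)
    stop("degenerate labels: need at least one true and one false value")
  v <- if (polarity == "lower-is-positive") -value else value
  r <- rank(v)  # midranks handle ties
  auc <- (sum(r[lab == "true"]) - nT * (nT + 1) / 2) / (nT * nF)
  # threshold sweep, thresholds descending: predict positive when v > t
  ord <- order(v, decreasing = TRUE)
  vs <- v[ord]; ls <- lab[ord]
  isEnd <- c(vs[-length(vs)] != vs[-1], TRUE)  # last index of each tie group
  tpr <- cumsum(ls == "true")[isEnd] / nT
  fpr <- cumsum(ls == "false")[isEnd] / nF
  points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(auc = auc, points = points, nTrue = nT, nFalse = nF,
                 polarity = polarity),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROCResult: AUC = %.4f (%d true vs %d false, %s)\n",
              x$auc, x$nTrue, x$nFalse, x$polarity))
  invisible(x)
}

#' Confusion rates at a fixed decision threshold
#'
#' A value is predicted positive when it exceeds the threshold (or falls
#' below it under `lower-is-positive` polarity); comparisons are strict.
#'
#' @inheritParams rocAuc
#' @param threshold decision threshold on the metric scale.
#' @return list with `tpr`, `fpr`, `tnr`, `fnr`.
#' @export
confusionAtThreshold <- function(value, label, threshold,
                                 polarity = c("higher-is-positive",
                                              "lower-is-positive")) {
  polarity <- match.arg(polarity)
  keep <- label %in% c("true", "false") & is.finite(value)
  value <- value[keep]
  lab <- as.character(label[keep])
  nT <- sum(lab == "true"); nF <- sum(lab == "false")
  if (nT < 1L || nF < 1L)
    stop("degenerate labels: need at least one true and one false value")
  pos <- if (polarity == "lower-is-positive") value < threshold
         else value > threshold
  list(tpr = sum(pos & lab == "true") / nT,
       fpr = sum(pos & lab == "false") / nF,
       tnr = sum(!pos & lab == "false") / nF,
       fnr = sum(!pos & lab == "true") / nT)
}

#' Per-class relative-frequency histogram of a metric
#'
#' Shared bin edges across classes; within each class the frequencies sum
#' to one.
#'
#' @inheritParams rocAuc
#' @param bins number of equal-width bins (>= 1).
#' @return list with `breaks` and `freq`, a matrix with one row per class.
#' @export
scoreHistogram <- function(value, label, bins = 10L) {
  stopifnot(bins >= 1L)
  keep <- label %in% c("true", "false") & is.finite(value)
  value <- value[keep]
  lab <- as.character(label[keep])
  rng <- range(value)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  classes <- unique(lab)
  freq <- t(vapply(classes, function(cl) {
    h <- graphics::hist(value[lab == cl], breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    h$counts / sum(h$counts)
  }, numeric(bins)))
  rownames(freq) <- classes
  list(breaks = breaks, freq = freq)
}
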