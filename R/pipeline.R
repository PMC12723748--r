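#' Assessment configuration
#'
#' One place for every tunable threshold of the per-dimer assessment; the
#' MD5 hash of the configuration is embedded in each record so results are
#' traceable to the parameters that produced them.
#'
#' @param contactsMin minimum interchain contacts for a credible interface.
#' @param contactCutoff CB-CB contact distance, Angstrom.
#' @param paeCutoff,distCutoff,d0Floor ipSAE parameters (see
#'   [ipsaeParams()]).
#' @param couplingTable optional data.frame from [readCouplingTable()].
#' @return list of class `lzipConfig`.
#' @export
lzipConfig <- function(contactsMin = 4L, contactCutoff = 8.0,
                       paeCutoff = 3, distCutoff = 5, d0Floor = 1,
                       couplingTable = NULL) {
  cfg <- list(contactsMin = as.integer(contactsMin),
              contactCutoff = contactCutoff,
              ipsae = ipsaeParams(paeCutoff, distCutoff, d0Floor),
              couplingTable = couplingTable)
  cfg$hash <- paramHash(cfg[c("contactsMin", "contactCutoff", "ipsae")])
  class(cfg) <- "lzipConfig"
  cfg
}

#' Assess one dimer model end to end
#'
#' Always classifies the model; computes the four confidence metrics when a
#' confidence bundle (or its file paths) is supplied; screens g-e' chemistry
#' only for valid parallel L-zips.  Metrics that cannot be computed are
#' reported as `NA`, never silently as zero.
#'
#' @param structure a [DimerModel-class] or a structure file path.
#' @param confidence a [ConfidenceBundle-class], a JSON file path, or
#'   `NULL`.
#' @param paePath optional companion PAE file (when `confidence` is a path).
#' @param pairId identifier carried into the record.
#' @param config an [lzipConfig()] list.
#' @return list of class `AssessmentRecord`: `pairId`, `verdict`
#'   ([LzipVerdict-class]), `scores` (one-row data.frame or `NULL`),
#'   `chemistry` (list or `NULL`), `provenance`.
#' @export
runAssess <- function(structure, confidence = NULL, paePath = NULL,
                      pairId = NULL, config = lzipConfig()) {
  model <- if (is(structure, "DimerModel")) structure
           else readStructure(structure)
  if (is.null(pairId))
    pairId <- if (nzchar(model@sourcePath))
      sub("\\.[^.]*$", "", basename(model@sourcePath)) else "model"
  verdict <- classifyLzip(model, contactsMin = config$contactsMin,
                          contactCutoff = config$contactCutoff)
  scores <- NULL
  if (!is.null(confidence)) {
    bundle <- if (is(confidence, "ConfidenceBundle")) confidence
              else readConfidence(confidence, paePath = paePath, model = model)
    if (length(chainSpans(bundle)) < 2L)
      bundle <- attachChainSpans(bundle, model)
    scores <- interfaceScores(bundle, model, config$ipsae)
  }
  chemistry <- NULL
  if (isValidLzip(verdict) && helixOrientation(verdict) == "parallel") {
    pairs <- enumerateGePairs(verdict@registerA, verdict@registerB, "parallel")
    chemistry <- chargeComplementarity(pairs)
    if (!is.null(config$couplingTable))
      chemistry$coupling <- couplingEnergy(pairs, config$couplingTable)
  }
  structure(list(pairId = pairId, verdict = verdict, scores = scores,
                 chemistry = chemistry,
                 provenance = list(
                   source = model@sourcePath,
                   paramHash = config$hash)),
            class = "AssessmentRecord")
}

#' @export
print.AssessmentRecord <- function(x, ...) {
  cat("AssessmentRecord:", x$pairId, "\n")
  show(x$verdict)
  if (!is.null(x$scores))
    cat(sprintf("  ipTM %.3f | ipSAE %.3f | mean pLDDT %.1f | mean PAE %.2f\n",
                x$scores$iptm, x$scores$ipsae, x$scores$mean_plddt,
                x$scores$mean_pae))
  if (!is.null(x$chemistry))
    cat(sprintf("  g-e' net charge score %+d (%s)\n", x$chemistry$net,
                if (x$chemistry$implausible) "repulsive interface"
                else "compatible interface"))
  invisible(x)
}

#' Flatten assessment records into a report table
#'
#' @param records list of `AssessmentRecord`s from [runAssess()].
#' @return data.frame, one row per record, suitable for [writeReport()].
#' @export
assessmentTable <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(pair_id = r$pairId,
               formed_lzip = isValidLzip(r$verdict),
               reasons = paste(verdictReasons(r$verdict), collapse = ";"),
               orientation = helixOrientation(r$verdict),
               interface_heptads = interfaceHeptads(r$verdict),
               contacts = r$verdict@contacts,
               iptm = if (is.null(r$scores)) NA_real_ else r$scores$iptm,
               ipsae = if (is.null(r$scores)) NA_real_ else r$scores$ipsae,
               mean_plddt = if (is.null(r$scores)) NA_real_ else r$scores$mean_plddt,
               mean_pae = if (is.null(r$scores)) NA_real_ else r$scores$mean_pae,
               charge_net = if (is.null(r$chemistry)) NA_integer_
                            else r$chemistry$net,
               param_hash = r$provenance$paramHash,
               stringsAsFactors = FALSE)
  }))
}

#' Benchmark a metric against experimental dimerization ranks
#'
#' Joins per-pair metric values with Newman ranks, labels pairs, and
#' computes ROC/AUC over the pairs whose prediction formed an L-zip (the
#' failure cross-tabulation of formed vs rank class is reported for all
#' joined pairs).  Synonymous A-B and B-A pairs are distinct rows.
#'
#' @param metrics data.frame with columns `pair_a`, `pair_b`, the metric
#'   column, and optionally `formed_lzip` (default `TRUE` when absent).
#' @param ranks data.frame with columns `pair_a`, `pair_b` and either
#'   `rank` or `z_score`.
#' @param metric name of the metric column (e.g. `"iptm"`, `"ipsae"`,
#'   `"mean_plddt"`, `"mean_pae"`).
#' @param polarity passed to [rocAuc()]; defaults to lower-is-positive for
#'   `mean_pae`, higher-is-positive otherwise.
#' @param split rank-to-label split, see [labelPairs()].
#' @return list with `roc` (`ROCResult` or `NULL` when no L-zip-forming
#'   pairs remain), `crossTab` (formed x rank-class counts), `nJoined`,
#'   `nExcludedRank0`, `nMissingMetric`.
#' @export
runBenchmark <- function(metrics, ranks, metric = "iptm", polarity = NULL,
                         split = "ge4") {
  stopifnot(all(c("pair_a", "pair_b") %in% names(metrics)),
            all(c("pair_a", "pair_b") %in% names(ranks)))
  if (!metric %in% names(metrics))
    stop("metric column not found: ", metric)
  if (is.null(ranks$rank)) {
    if (is.null(ranks$z_score)) stop("ranks table needs 'rank' or 'z_score'")
    ranks$rank <- newmanRank(ranks$z_score)
  }
  key <- function(d) paste(d$pair_a, d$pair_b, sep = "\r")
  m <- match(key(metrics), key(ranks))
  if (!any(!is.na(m))) {
    stop("join produced 0 rows; sample metric ids: ",
         paste(utils::head(paste(metrics$pair_a, metrics$pair_b, sep = "-"), 3),
               collapse = ", "))
  }
  joined <- metrics[!is.na(m), , drop = FALSE]
  joined$rank <- ranks$rank[m[!is.na(m)]]
  if (is.null(joined$formed_lzip)) joined$formed_lzip <- TRUE
  lab <- labelPairs(joined$rank, split = split)
  joined$label <- lab$label

  crossTab <- table(formed = joined$formed_lzip,
                    rankClass = ifelse(joined$rank == 0, "excluded",
                                       ifelse(joined$rank <= 3, "rank<=3",
                                              "rank>=4")))
  use <- joined$formed_lzip & joined$label != "excluded"
  nMissing <- sum(use & !is.finite(joined[[metric]]))
  roc <- NULL
  if (any(use)) {
    if (is.null(polarity))
      polarity <- if (metric == "mean_pae") "lower-is-positive"
                  else "higher-is-positive"
    roc <- tryCatch(rocAuc(joined[[metric]][use], joined$label[use], polarity),
                    error = function(e) NULL)
  }
  list(roc = roc, crossTab = crossTab, nJoined = nrow(joined),
       nExcludedRank0 = lab$nExcluded, nMissingMetric = nMissing)
}
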