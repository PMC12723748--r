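#' Build a DimerModel from an atom table
#'
#' Lower-level constructor used by [readStructure()] and the synthetic
#' generator.  Keeps only backbone/CB atoms of standard residues, resolves
#' alternate locations by occupancy, and derives the residue-level table with
#' the 0-based concatenated index.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`, and optionally `ins` (insertion code) and `o` (occupancy).
#' @param sourcePath provenance string stored on the object.
#' @param metadata optional list of annotations.
#' @return A [DimerModel-class] object.
#' @export
newDimerModel <- function(atoms, sourcePath = "", metadata = list()) {
  if (!nrow(atoms)) stop("empty model: no protein atoms")
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  atoms$o[is.na(atoms$o)] <- 1
  keep <- atoms$elety %in% c("N", "CA", "C", "O", "CB")
  atoms <- atoms[keep, , drop = FALSE]
  if (!nrow(atoms)) stop("empty model: no backbone atoms")

  # altloc resolution: highest occupancy per (chain, resno, ins, elety)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety, sep = "\r")
  ord <- order(-atoms$o)
  atoms <- atoms[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]

  chains <- unique(atoms$chain)
  reslist <- lapply(chains, function(ch) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    rkey <- paste(a$resno, a$ins, sep = "\r")
    first <- !duplicated(rkey)
    r <- a[first, c("chain", "resno", "ins", "resid")]
    ca <- a[a$elety == "CA", , drop = FALSE]
    cb <- a[a$elety == "CB", , drop = FALSE]
    m <- match(paste(r$resno, r$ins, sep = "\r"), paste(ca$resno, ca$ins, sep = "\r"))
    r$ca_x <- ca$x[m]; r$ca_y <- ca$y[m]; r$ca_z <- ca$z[m]
    m <- match(paste(r$resno, r$ins, sep = "\r"), paste(cb$resno, cb$ins, sep = "\r"))
    r$cb_x <- cb$x[m]; r$cb_y <- cb$y[m]; r$cb_z <- cb$z[m]
    r[is.finite(r$ca_x), , drop = FALSE]   # residues need at least a CA
  })
  res <- do.call(rbind, reslist)
  if (is.null(res) || !nrow(res)) stop("empty model: no residues with CA atoms")
  res$gindex <- seq_len(nrow(res)) - 1L
  rownames(res) <- NULL
  rownames(atoms) <- NULL
  new("DimerModel", atoms = atoms[, c("chain", "resno", "ins", "resid",
                                      "elety", "x", "y", "z")],
      residues = res, chainIds = chains, sourcePath = sourcePath,
      metadata = metadata)
}

#' Read a predicted structure (PDB or mmCIF) into a DimerModel
#'
#' Parses the first model of the file, keeps protein chains only (waters,
#' heteroatoms and nucleic acids are skipped), and resolves alternate
#' locations by occupancy.  Residues with non-standard names are dropped with
#' a warning.
#'
#' @param path path to a `.pdb`, `.cif` or `.mmcif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A [DimerModel-class].
#' @examples
#' mod <- crickBackbone(synthSequence(5), synthSequence(5))
#' f <- tempfile(fileext = ".pdb")
#' writeModelPdb(mod, f)
#' readStructure(f)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  nonstd <- setdiff(unique(a$resid), STANDARD_AA3)
  if (length(nonstd)) {
    warning("dropping non-standard residues: ", paste(nonstd, collapse = ", "))
    a <- a[a$resid %in% STANDARD_AA3, , drop = FALSE]
  }
  if (!nrow(a)) stop("no protein chains in ", path)
  atoms <- data.frame(chain = a$chain, resno = a$resno, ins = a$insert,
                      resid = a$resid, elety = a$elety,
                      x = a$x, y = a$y, z = a$z, o = a$o,
                      stringsAsFactors = FALSE)
  atoms$ins[is.na(atoms$ins)] <- ""
  newDimerModel(atoms, sourcePath = path)
}

#' Construct a ConfidenceBundle
#'
#' @param plddt per-residue confidence; values on a 0-1 scale are detected
#'   (max <= 1) and rescaled to 0-100.
#' @param pae square PAE matrix (Angstrom).
#' @param iptm optional ipTM scalar; `NULL` means absent.
#' @param chainSpans named list of half-open 0-based `c(start, end)` ranges;
#'   defaults to a single chain `"A"` covering all residues.
#' @return A [ConfidenceBundle-class].
#' @export
confidenceBundle <- function(plddt, pae, iptm = NULL, chainSpans = NULL) {
  plddt <- as.numeric(plddt)
  pae <- as.matrix(pae)
  if (length(plddt) && max(plddt, na.rm = TRUE) <= 1)
    plddt <- plddt * 100
  if (length(plddt) != nrow(pae) || nrow(pae) != ncol(pae))
    stop(sprintf("shape mismatch: %d pLDDT values vs %dx%d PAE",
                 length(plddt), nrow(pae), ncol(pae)))
  if (is.null(chainSpans))
    chainSpans <- list(A = c(0L, length(plddt)))
  new("ConfidenceBundle", plddt = plddt, pae = pae,
      iptm = if (is.null(iptm)) numeric(0) else as.numeric(iptm),
      chainSpans = lapply(chainSpans, as.integer))
}

#' Read predictor confidence files into a ConfidenceBundle
#'
#' Understands the common layouts: ColabFold ranked-model JSON (`plddt`,
#' `pae`, `ptm`, `iptm`), AlphaFold-server style JSON
#' (`predicted_aligned_error`), and Boltz-style output where the JSON holds
#' pLDDT/ipTM and the PAE matrix lives in a companion dense-matrix `.npz`
#' archive (key `"pae"`, or the sole array).  pLDDT on a 0-1 scale is
#' rescaled to 0-100.
#'
#' @param pathJson JSON file with at least per-residue pLDDT.
#' @param paePath optional companion PAE file (`.npz` archive or JSON).
#' @param dialect `"auto"`, `"colabfold"`, `"boltz"` or `"af3"` (accepted for
#'   interface compatibility; field names are probed in all dialects).
#' @param model optional [DimerModel-class] used to set the chain spans.
#' @param chainLengths optional named integer vector of per-chain residue
#'   counts, an alternative way to set chain spans.
#' @return A [ConfidenceBundle-class]; `iptm` is absent (length-0) when the
#'   file carries none.
#' @export
readConfidence <- function(pathJson, paePath = NULL,
                           dialect = c("auto", "colabfold", "boltz", "af3"),
                           model = NULL, chainLengths = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(pathJson)) stop("file not found: ", pathJson)
  j <- jsonlite::fromJSON(pathJson)

  pick <- function(keys) {
    for (k in keys) if (!is.null(j[[k]])) return(j[[k]])
    NULL
  }
  pl <- pick(c("plddt", "plddts", "confidence_plddt"))
  if (is.null(pl)) stop("no per-residue pLDDT found in ", pathJson)
  pl <- as.numeric(unlist(pl))

  paeM <- NULL
  if (!is.null(paePath)) {
    paeM <- if (grepl("\\.npz$", paePath, ignore.case = TRUE))
      readPaeNpz(paePath)
    else as.matrix(jsonlite::fromJSON(paePath)[["pae"]])
  } else {
    p <- pick(c("pae", "predicted_aligned_error", "pae_matrix"))
    if (!is.null(p)) paeM <- as.matrix(p)
  }
  if (is.null(paeM)) stop("no PAE matrix found for ", pathJson)

  ip <- pick(c("iptm", "ipTM"))
  if (!is.null(ip)) ip <- as.numeric(ip)

  spans <- NULL
  if (!is.null(model)) {
    if (nResidues(model) != length(pl))
      stop(sprintf("shape mismatch: model has %d residues, pLDDT has %d",
                   nResidues(model), length(pl)))
    spans <- chainSpans(model)
  } else if (!is.null(chainLengths)) {
    ends <- cumsum(as.integer(chainLengths))
    spans <- mapply(function(s, e) c(s, e), c(0L, ends[-length(ends)]), ends,
                    SIMPLIFY = FALSE)
    names(spans) <- names(chainLengths)
  }
  confidenceBundle(pl, paeM, iptm = ip, chainSpans = spans)
}

#' Read a PAE matrix from a NumPy `.npz` archive
#'
#' Dense-matrix archives are zip files of `.npy` members.  The matrix is
#' taken from the member named `pae.npy` when present, otherwise the archive
#' must contain exactly one array.
#'
#' @param path path to the `.npz` file.
#' @return numeric matrix.
#' @export
readPaeNpz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  members <- utils::unzip(path, list = TRUE)$Name
  pick <- if ("pae.npy" %in% members) "pae.npy" else {
    if (length(members) != 1L)
      stop("archive has several arrays and none named 'pae': ",
           paste(members, collapse = ", "))
    members
  }
  dir <- tempfile("npz")
  on.exit(unlink(dir, recursive = TRUE))
  utils::unzip(path, files = pick, exdir = dir)
  readNpy(file.path(dir, pick))
}

# minimal NumPy .npy reader: v1/v2 headers, little-endian float/int, 1-2D
readNpy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an npy file: ", path)
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2)
    readBin(con, "integer", 1, size = 4, endian = "little")
  else readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape), ",")[[1]])
  n <- prod(dims)
  vals <- switch(descr,
    "<f8" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "<f4" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "<i8" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "<i4" = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    "<i2" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    stop("unsupported npy dtype: ", descr))
  if (length(dims) == 1L) return(vals)
  if (length(dims) != 2L) stop("expected a 1- or 2-D array, got shape (", shape, ")")
  m <- matrix(vals, nrow = dims[1], ncol = dims[2], byrow = !fortran)
  m
}

#' Attach chain spans from a model to a confidence bundle
#'
#' @param bundle a [ConfidenceBundle-class].
#' @param model a [DimerModel-class] with the same residue count.
#' @return the bundle with `chainSpans` taken from the model.
#' @export
attachChainSpans <- function(bundle, model) {
  if (nResidues(model) != nResidues(bundle))
    stop(sprintf("shape mismatch: model %d residues vs bundle %d",
                 nResidues(model), nResidues(bundle)))
  new("ConfidenceBundle", plddt = bundle@plddt, pae = bundle@pae,
      iptm = bundle@iptm, chainSpans = chainSpans(model))
}

#' Write an assessment/benchmark report
#'
#' Deterministic column order (as given), floats at fixed precision
#' (6 significant digits), re-readable with [readReport()].
#'
#' @param records data.frame of records sharing one schema.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
writeReport <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  num <- vapply(records, is.numeric, logical(1))
  out <- records
  out[num] <- lapply(records[num], function(v) signif(v, 6))
  if (format == "tsv") {
    ok <- tryCatch({
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
      TRUE
    }, error = function(e) stop("cannot write report to ", path, ": ",
                                conditionMessage(e), call. = FALSE))
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a report written by [writeReport()]
#'
#' @param path report path; format inferred from the extension.
#' @return data.frame.
#' @export
readReport <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::fromJSON(path))
  else
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a tabular metrics/ranks file (CSV, TSV or XLSX)
#'
#' Thin convenience reader for benchmark inputs such as per-pair metric
#' tables or Z-score/rank tables.  XLSX requires the `readxl` package.
#'
#' @param path file path; format inferred from the extension.
#' @param sheet sheet name or index for XLSX input.
#' @return data.frame.
#' @export
readMetricsTable <- function(path, sheet = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading xlsx requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
}
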