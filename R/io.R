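#' Read perturbation data from a MIDAS-flavored CSV
#'
#' Expected columns: `ID`; treatment columns `TR:<node>:Stim` and
#' `TR:<node>:Inhib` holding 0/1; value columns `DV:<readout>`; optional
#' error columns `DE:<readout>`. Empty cells are missing. When `DE:`
#' columns are absent, errors are filled from `defaultError` (scalar or
#' per-readout named vector).
#'
#' @param file path to the CSV.
#' @param measuredMap optional named character vector mapping readout names
#'   to network nodes (default: each readout measures the same-named node).
#' @param masked data.frame with columns `target`, `readout` (see
#'   [perturbationDesign()]).
#' @param defaultError per-readout standard error used when no `DE:`
#'   columns are present.
#' @param nReplicates replicate count recorded in the dataset.
#' @return list with elements `design` and `data`.
#' @export
readPerturbationData <- function(file, measuredMap = NULL,
                                 masked = data.frame(target = character(),
                                                     readout = character()),
                                 defaultError = NULL, nReplicates = 3L) {
  tab <- utils::read.csv(file, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  if (!"ID" %in% colnames(tab))
    stop("malformed header: missing column 'ID'")
  cn <- colnames(tab)
  trCols <- grep("^TR:", cn, value = TRUE)
  dvCols <- grep("^DV:", cn, value = TRUE)
  deCols <- grep("^DE:", cn, value = TRUE)
  if (!length(dvCols))
    stop("malformed header: no 'DV:' value columns")
  if (!length(trCols))
    stop("malformed header: no 'TR:' treatment columns")
  badTr <- trCols[!grepl("^TR:[^:]+:(Stim|Inhib)$", trCols)]
  if (length(badTr))
    stop("malformed treatment column: ", badTr[1])
  readouts <- sub("^DV:", "", dvCols)
  numMat <- function(cols, what) {
    m <- matrix(NA_real_, nrow(tab), length(cols))
    for (j in seq_along(cols)) {
      raw <- trimws(tab[[cols[j]]])
      empty <- is.na(raw) | raw == "" | raw == "NA"
      v <- suppressWarnings(as.numeric(raw))
      bad <- which(!empty & is.na(v))
      if (length(bad))
        stop("non-numeric ", what, " in row ", bad[1] + 1L, ", column '",
             cols[j], "': '", raw[bad[1]], "'")
      m[, j] <- v
    }
    m
  }
  values <- numMat(dvCols, "value")
  colnames(values) <- readouts
  rownames(values) <- tab$ID
  if (length(deCols)) {
    errors <- numMat(deCols, "error")
    colnames(errors) <- sub("^DE:", "", deCols)
    errors <- errors[, readouts, drop = FALSE]
  } else {
    if (is.null(defaultError))
      stop("no 'DE:' error columns and no defaultError supplied")
    if (length(defaultError) == 1L)
      defaultError <- stats::setNames(rep(defaultError, length(readouts)),
                                      readouts)
    errors <- matrix(rep(defaultError[readouts], each = nrow(tab)),
                     nrow(tab), length(readouts))
  }
  dimnames(errors) <- dimnames(values)
  stimNodes <- sub("^TR:", "", sub(":Stim$", "",
                                   grep(":Stim$", trCols, value = TRUE)))
  inhNodes <- sub("^TR:", "", sub(":Inhib$", "",
                                  grep(":Inhib$", trCols, value = TRUE)))
  trVal <- function(node, kind) {
    col <- paste0("TR:", node, ":", kind)
    as.numeric(tab[[col]]) != 0
  }
  stimulated <- lapply(seq_len(nrow(tab)), function(i)
    stimNodes[vapply(stimNodes, function(s) trVal(s, "Stim")[i],
                     logical(1))])
  inhibited <- lapply(seq_len(nrow(tab)), function(i)
    inhNodes[vapply(inhNodes, function(s) trVal(s, "Inhib")[i],
                    logical(1))])
  if (is.null(measuredMap))
    measuredMap <- stats::setNames(readouts, readouts)
  design <- perturbationDesign(tab$ID, stimulated, inhibited, measuredMap,
                               masked)
  data <- perturbationDataset(values, errors, design = design,
                              nReplicates = nReplicates)
  list(design = design, data = data)
}

fmt9 <- function(x) {
  ifelse(is.na(x), "", formatC(signif(x, 9), digits = 9, format = "g"))
}

#' Write perturbation data to a MIDAS-flavored CSV
#'
#' Inverse of [readPerturbationData()]; floats are serialized at 9
#' significant digits, missing cells as empty fields.
#'
#' @param design a [PerturbationDesign-class].
#' @param data a [PerturbationDataset-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writePerturbationData <- function(design, data, file) {
  stimNodes <- sort(unique(unlist(design@stimulated)))
  inhNodes <- sort(unique(unlist(design@inhibited)))
  readouts <- names(design@measured)
  out <- data.frame(ID = design@conditionIds, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (s in stimNodes)
    out[[paste0("TR:", s, ":Stim")]] <-
      as.integer(vapply(design@stimulated, function(x) s %in% x, logical(1)))
  for (k in inhNodes)
    out[[paste0("TR:", k, ":Inhib")]] <-
      as.integer(vapply(design@inhibited, function(x) k %in% x, logical(1)))
  for (w in readouts) out[[paste0("DV:", w)]] <- fmt9(data@values[, w])
  for (w in readouts) out[[paste0("DE:", w)]] <- fmt9(data@errors[, w])
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

MODEL_JSON_VERSION <- "1.0"

#' Serialize a fitted model to JSON / restore it
#'
#' The JSON stores the network, design, raw coefficients, coefficient paths
#' with exponents and values, fit statistics, seed and format version;
#' [readModelJson()] restores a simulable [MRAFit-class]. Reading checks
#' structural consistency: every network edge must be covered by the stored
#' path parameterization.
#'
#' @param fit an [MRAFit-class].
#' @param path file path.
#' @param extra optional named list merged into the JSON (e.g. profile
#'   CIs, run configuration).
#' @return `path` invisibly ([writeModelJson()]); an [MRAFit-class]
#'   ([readModelJson()]).
#' @export
writeModelJson <- function(fit, path, extra = list()) {
  m <- fit@model
  obj <- list(
    format = "mranet-model",
    version = MODEL_JSON_VERSION,
    seed = fit@seed,
    network = list(nodes = m@network@nodes,
                   edges = networkEdges(m@network),
                   stimuli = m@network@stimuli),
    design = list(conditionIds = m@design@conditionIds,
                  stimulated = m@design@stimulated,
                  inhibited = m@design@inhibited,
                  measured = as.list(m@design@measured),
                  masked = m@design@masked),
    coefficients = as.list(rawParameterValues(m)),
    fixed = m@fixed,
    paths = list(names = pathNames(m),
                 parameters = m@paths@parameters,
                 exponents = unname(apply(m@paths@exponents, 1L, identity,
                                          simplify = FALSE)),
                 values = unname(m@paths@values)),
    statistics = list(wssrFit = fit@wssrFit,
                      nDatapoints = fit@nDatapoints,
                      nParameters = fit@nParameters,
                      nFreeParameters = fit@nFreeParameters,
                      reducedChiSquare = fit@reducedChiSquare,
                      nRestarts = fit@nRestarts,
                      convergedRestarts = fit@convergedRestarts))
  obj <- c(obj, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("corrupted model JSON: ", conditionMessage(e)))
  if (!identical(obj$format, "mranet-model"))
    stop("not an mranet model JSON: ", path)
  if (!identical(obj$version, MODEL_JSON_VERSION))
    warning("model JSON version ", obj$version,
            " differs from current ", MODEL_JSON_VERSION)
  network <- signalingNetwork(obj$network$edges,
                              stimuli = unlist(obj$network$stimuli),
                              nodes = obj$network$nodes)
  listify <- function(x, n) {
    if (is.null(x)) rep(list(character()), n)
    else lapply(seq_len(n), function(i)
      as.character(unlist(x[[i]])))
  }
  nC <- length(obj$design$conditionIds)
  masked <- as.data.frame(obj$design$masked)
  if (!nrow(masked))
    masked <- data.frame(target = character(), readout = character())
  design <- perturbationDesign(
    obj$design$conditionIds,
    listify(obj$design$stimulated, nC),
    listify(obj$design$inhibited, nC),
    unlist(obj$design$measured), masked)
  coefs <- unlist(obj$coefficients)
  params <- obj$paths$parameters
  en <- edgeNames(network)
  missEdge <- setdiff(en, params)
  if (length(missEdge))
    stop("model JSON inconsistent: edge(s) ",
         paste(missEdge, collapse = ", "),
         " absent from the coefficient-path parameterization")
  pe <- obj$paths$exponents
  exps <- if (is.matrix(pe)) pe
  else do.call(rbind, lapply(pe, as.integer))
  if (is.null(exps)) exps <- matrix(0L, 0L, length(params))
  storage.mode(exps) <- "integer"
  dimnames(exps) <- list(obj$paths$names, params)
  paths <- new("CoefficientPaths", parameters = params, exponents = exps,
               values = as.numeric(obj$paths$values))
  inh <- coefs[startsWith(names(coefs), "l_")]
  model <- mraModel(network, design, coefs[en], inh, paths = paths,
                    fixed = as.character(unlist(obj$fixed)))
  st <- obj$statistics
  new("MRAFit", model = model, wssrFit = as.numeric(st$wssrFit),
      nDatapoints = as.integer(st$nDatapoints),
      nParameters = as.integer(st$nParameters),
      nFreeParameters = as.integer(st$nFreeParameters),
      reducedChiSquare = as.numeric(st$reducedChiSquare),
      nRestarts = as.integer(st$nRestarts),
      convergedRestarts = as.integer(st$convergedRestarts),
      seed = as.integer(obj$seed))
}
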