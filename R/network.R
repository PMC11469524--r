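#' Construct a SignalingNetwork
#'
#' @param edges two-column data.frame (or matrix) with columns
#'   `source`, `target`, one row per directed edge.
#' @param stimuli character vector of stimulus nodes (no incoming edges).
#' @param nodes optional explicit node ordering; defaults to order of first
#'   appearance in the edge list (sources before targets, row by row),
#'   followed by any stimulus nodes not yet seen.
#' @return a validated [SignalingNetwork-class].
#' @examples
#' net <- signalingNetwork(
#'   data.frame(source = c("BCR", "SYK"), target = c("SYK", "PI3K")),
#'   stimuli = "BCR")
#' networkNodes(net)
#' @export
signalingNetwork <- function(edges, stimuli = character(), nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% colnames(edges)))
    stop("edge table needs columns 'source' and 'target'")
  from <- as.character(edges$source)
  to <- as.character(edges$target)
  if (is.null(nodes)) {
    seen <- character()
    for (i in seq_along(from)) seen <- union(seen, c(from[i], to[i]))
    nodes <- union(seen, stimuli)
  }
  new("SignalingNetwork", nodes = nodes, from = from, to = to,
      stimuli = as.character(stimuli))
}

#' Load a network from an edge-list CSV
#'
#' Reads a comma-separated file with header `source,target`. Stimulus nodes
#' may be declared in-file by a comment line of the form
#' `# stimuli: BCR,CD40` (any number of such lines are merged), or passed
#' via the `stimuli` argument.
#'
#' @param file path to the edge-list CSV.
#' @param stimuli additional stimulus nodes beyond the in-file declaration.
#' @return a validated [SignalingNetwork-class].
#' @export
loadNetwork <- function(file, stimuli = character()) {
  lines <- readLines(file)
  decl <- grep("^#\\s*stimuli\\s*:", lines, value = TRUE)
  if (length(decl)) {
    named <- unlist(strsplit(sub("^#\\s*stimuli\\s*:\\s*", "", decl), ","))
    stimuli <- union(stimuli, trimws(named))
  }
  body <- lines[!startsWith(trimws(lines), "#")]
  edges <- utils::read.csv(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE)
  signalingNetwork(edges, stimuli = stimuli)
}

#' Write a network to an edge-list CSV
#'
#' Inverse of [loadNetwork()]: stimulus nodes are stored as a
#' `# stimuli:` comment line above the header.
#'
#' @param network a [SignalingNetwork-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeNetwork <- function(network, file) {
  con <- file(file, "w")
  on.exit(close(con))
  if (length(network@stimuli))
    writeLines(paste0("# stimuli: ",
                      paste(network@stimuli, collapse = ",")), con)
  writeLines("source,target", con)
  if (length(network@from))
    writeLines(paste(network@from, network@to, sep = ","), con)
  invisible(file)
}

#' Add or remove a single edge
#'
#' Convenience editors used by the greedy structure-adaptation loop. Both
#' return a new, validated network; the node set is never changed.
#'
#' @param network a [SignalingNetwork-class].
#' @param source,target node names of the edge.
#' @return a [SignalingNetwork-class].
#' @export
addEdge <- function(network, source, target) {
  new("SignalingNetwork", nodes = network@nodes,
      from = c(network@from, source), to = c(network@to, target),
      stimuli = network@stimuli)
}

#' @rdname addEdge
#' @export
removeEdge <- function(network, source, target) {
  hit <- network@from == source & network@to == target
  if (!any(hit))
    stop("edge ", source, "->", target, " not present")
  new("SignalingNetwork", nodes = network@nodes,
      from = network@from[!hit], to = network@to[!hit],
      stimuli = network@stimuli)
}

edgeNames <- function(network) {
  paste0("r_", network@to, "_", network@from)
}

asIgraph <- function(network) {
  igraph::graph_from_data_frame(
    data.frame(from = network@from, to = network@to,
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = network@nodes, stringsAsFactors = FALSE))
}

#' Construct a PerturbationDesign
#'
#' @param conditionIds character vector of condition identifiers.
#' @param stimulated list of character vectors (stimulated nodes per
#'   condition); a single vector is recycled.
#' @param inhibited list of character vectors (inhibited nodes per
#'   condition).
#' @param measured named character vector mapping readout names to network
#'   nodes; an unnamed vector is taken as readouts measuring the same-named
#'   node.
#' @param masked data.frame with columns `target`, `readout`; the readout is
#'   dropped in every condition in which `target` is inhibited.
#' @return a validated [PerturbationDesign-class].
#' @export
perturbationDesign <- function(conditionIds, stimulated, inhibited, measured,
                               masked = data.frame(target = character(),
                                                   readout = character())) {
  n <- length(conditionIds)
  if (!is.list(stimulated)) stimulated <- rep(list(stimulated), n)
  if (!is.list(inhibited)) inhibited <- rep(list(inhibited), n)
  measured <- vapply(measured, as.character, character(1))
  if (is.null(names(measured))) names(measured) <- measured
  new("PerturbationDesign", conditionIds = as.character(conditionIds),
      stimulated = lapply(stimulated, as.character),
      inhibited = lapply(inhibited, as.character),
      measured = measured,
      masked = as.data.frame(masked, stringsAsFactors = FALSE))
}

#' Construct a PerturbationDataset
#'
#' Row/column names are matched against the design; masked cells are set to
#' `NA`.
#'
#' @param values numeric condition-by-readout matrix of log2 fold changes.
#' @param errors numeric matrix of per-cell standard errors (same shape).
#' @param design optional [PerturbationDesign-class]; when given, rows and
#'   columns are reordered to match and the design's masking is applied.
#' @param nReplicates replicate count behind each mean.
#' @return a validated [PerturbationDataset-class].
#' @export
perturbationDataset <- function(values, errors, design = NULL,
                                nReplicates = 3L) {
  values <- as.matrix(values)
  errors <- as.matrix(errors)
  if (!is.null(design)) {
    if (!is.null(rownames(values)))
      values <- values[design@conditionIds, , drop = FALSE]
    if (!is.null(rownames(errors)))
      errors <- errors[design@conditionIds, , drop = FALSE]
    if (!is.null(colnames(values)))
      values <- values[, names(design@measured), drop = FALSE]
    if (!is.null(colnames(errors)))
      errors <- errors[, names(design@measured), drop = FALSE]
    rownames(values) <- rownames(errors) <- design@conditionIds
    colnames(values) <- colnames(errors) <- names(design@measured)
    values <- applyMasking(values, design)
  }
  new("PerturbationDataset", values = values, errors = errors,
      nReplicates = as.integer(nReplicates))
}

applyMasking <- function(values, design) {
  if (!nrow(design@masked)) return(values)
  for (i in seq_along(design@conditionIds)) {
    inh <- design@inhibited[[i]]
    hit <- design@masked$target %in% inh
    if (any(hit))
      values[i, design@masked$readout[hit]] <- NA_real_
  }
  values
}

#' Validate a network / design / dataset triple
#'
#' Cross-checks conformability and reports the experimental coverage:
#' which nodes are perturbed but unmeasured, measured but unperturbed, and
#' how many cells are masked. Side-effect free; raises on conformability
#' mismatch.
#'
#' @param network a [SignalingNetwork-class].
#' @param design a [PerturbationDesign-class].
#' @param data a [PerturbationDataset-class] (optional).
#' @return (invisibly) a list with elements `summary` (string such as
#'   `"17 conditions x 14 readouts"`), `perturbedUnmeasured`,
#'   `measuredUnperturbed`, `maskedCells` (count of NA cells attributable
#'   to masking).
#' @export
validateDesign <- function(network, design, data = NULL) {
  validObject(network)
  validObject(design)
  nodes <- network@nodes
  badM <- setdiff(design@measured, nodes)
  if (length(badM))
    stop("measured node(s) not in network: ", paste(badM, collapse = ", "))
  badI <- setdiff(unlist(design@inhibited), nodes)
  if (length(badI))
    stop("inhibited node(s) not in network: ", paste(badI, collapse = ", "))
  badS <- setdiff(unlist(design@stimulated), network@stimuli)
  if (length(badS))
    stop("stimulated node(s) not declared as stimuli: ",
         paste(badS, collapse = ", "))
  if (nrow(design@masked)) {
    badT <- setdiff(design@masked$target, unlist(design@inhibited))
    if (length(badT))
      stop("masked target never inhibited: ", paste(badT, collapse = ", "))
  }
  if (!is.null(data)) {
    validObject(data)
    if (nrow(data@values) != length(design@conditionIds))
      stop("condition count mismatch: design has ",
           length(design@conditionIds), ", data has ", nrow(data@values))
    if (!is.null(colnames(data@values))) {
      extra <- setdiff(colnames(data@values), names(design@measured))
      if (length(extra))
        stop("readout in data absent from design: ",
             paste(extra, collapse = ", "))
    } else if (ncol(data@values) != length(design@measured)) {
      stop("readout count mismatch between design and data")
    }
  }
  perturbed <- union(unlist(design@stimulated), unlist(design@inhibited))
  measuredNodes <- unname(design@measured)
  masked <- applyMasking(
    matrix(0, length(design@conditionIds), length(design@measured),
           dimnames = list(design@conditionIds, names(design@measured))),
    design)
  out <- list(
    summary = paste(length(design@conditionIds), "conditions x",
                    length(design@measured), "readouts"),
    perturbedUnmeasured = setdiff(perturbed, measuredNodes),
    measuredUnperturbed = setdiff(measuredNodes, perturbed),
    maskedCells = sum(is.na(masked)))
  invisible(out)
}
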