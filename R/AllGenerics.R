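#' @include AllClasses.R
NULL

#' Accessors for mranet classes
#'
#' Small accessor family: `networkNodes`, `networkEdges`, `stimulusNodes`,
#' `conditionIds`, `measuredReadouts`, `maskedReadouts`, `responseValues`,
#' `responseErrors`, `pathNames`, `pathValues`, `localResponseMatrix`,
#' `inhibitorStrengths`.
#'
#' @param object an mranet S4 object.
#' @return The requested slot content in a plain base-R form (character
#'   vector, data.frame or matrix).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("stimulusNodes", function(object) standardGeneric("stimulusNodes"))
#' @rdname accessors
#' @export
setGeneric("conditionIds", function(object) standardGeneric("conditionIds"))
#' @rdname accessors
#' @export
setGeneric("measuredReadouts",
           function(object) standardGeneric("measuredReadouts"))
#' @rdname accessors
#' @export
setGeneric("maskedReadouts",
           function(object) standardGeneric("maskedReadouts"))
#' @rdname accessors
#' @export
setGeneric("responseValues", function(object) standardGeneric("responseValues"))
#' @rdname accessors
#' @export
setGeneric("responseErrors", function(object) standardGeneric("responseErrors"))
#' @rdname accessors
#' @export
setGeneric("pathNames", function(object) standardGeneric("pathNames"))
#' @rdname accessors
#' @export
setGeneric("pathValues", function(object) standardGeneric("pathValues"))
#' @rdname accessors
#' @export
setGeneric("localResponseMatrix",
           function(object) standardGeneric("localResponseMatrix"))
#' @rdname accessors
#' @export
setGeneric("inhibitorStrengths",
           function(object) standardGeneric("inhibitorStrengths"))

setMethod("networkNodes", "SignalingNetwork", function(object) object@nodes)
setMethod("networkEdges", "SignalingNetwork", function(object)
  data.frame(source = object@from, target = object@to,
             stringsAsFactors = FALSE))
setMethod("stimulusNodes", "SignalingNetwork", function(object) object@stimuli)
setMethod("networkNodes", "MRAModel", function(object) object@network@nodes)
setMethod("networkEdges", "MRAModel",
          function(object) networkEdges(object@network))

setMethod("conditionIds", "PerturbationDesign",
          function(object) object@conditionIds)
setMethod("measuredReadouts", "PerturbationDesign",
          function(object) object@measured)
setMethod("maskedReadouts", "PerturbationDesign", function(object) object@masked)

setMethod("responseValues", "PerturbationDataset", function(object) object@values)
setMethod("responseErrors", "PerturbationDataset", function(object) object@errors)

setMethod("pathNames", "CoefficientPaths",
          function(object) rownames(object@exponents))
setMethod("pathValues", "CoefficientPaths", function(object) {
  v <- object@values
  names(v) <- rownames(object@exponents)
  v
})
setMethod("pathNames", "MRAModel", function(object) pathNames(object@paths))
setMethod("pathValues", "MRAModel", function(object) pathValues(object@paths))
setMethod("pathNames", "MRAFit", function(object) pathNames(object@model))
setMethod("pathValues", "MRAFit", function(object) pathValues(object@model))

setMethod("localResponseMatrix", "MRAModel", function(object) object@r)
setMethod("inhibitorStrengths", "MRAModel", function(object) object@inhibitors)
setMethod("localResponseMatrix", "MRAFit",
          function(object) object@model@r)
setMethod("inhibitorStrengths", "MRAFit",
          function(object) object@model@inhibitors)

setMethod("show", "SignalingNetwork", function(object) {
  cat("SignalingNetwork with", length(object@nodes), "nodes and",
      length(object@from), "edges\n")
  if (length(object@stimuli))
    cat("  stimuli:", paste(object@stimuli, collapse = ", "), "\n")
  cat("  nodes:", paste(object@nodes, collapse = ", "), "\n")
})

setMethod("show", "PerturbationDesign", function(object) {
  cat("PerturbationDesign:", length(object@conditionIds), "conditions x",
      length(object@measured), "readouts\n")
  nstim <- sum(lengths(object@stimulated) > 0)
  cat("  stimulated conditions:", nstim,
      "| masked pairs:", nrow(object@masked), "\n")
})

setMethod("show", "PerturbationDataset", function(object) {
  cat("PerturbationDataset:", nrow(object@values), "conditions x",
      ncol(object@values), "readouts (n =", object@nReplicates,
      "replicates);", sum(is.na(object@values)), "missing cells\n")
})

setMethod("show", "CoefficientPaths", function(object) {
  cat("CoefficientPaths:", nrow(object@exponents),
      "identifiable combinations of", length(object@parameters),
      "raw parameters\n")
  nm <- rownames(object@exponents)
  if (length(nm)) {
    shown <- utils::head(nm, 8L)
    cat(paste0("  ", shown, collapse = "\n"), "\n")
    if (length(nm) > 8L) cat("  ...\n")
  }
})

setMethod("show", "MRAModel", function(object) {
  cat("MRAModel on", length(object@network@nodes), "nodes /",
      length(object@network@from), "edges;",
      nrow(object@paths@exponents), "coefficient paths;",
      length(object@inhibitors), "inhibitor strengths",
      if (length(object@fixed)) paste0("(", length(object@fixed), " fixed)")
      else "", "\n")
})

setMethod("show", "MRAFit", function(object) {
  cat("MRAFit: WSSR =", format(object@wssrFit, digits = 6),
      "on", object@nDatapoints, "data points,",
      object@nParameters, "identifiable parameters\n")
  cat("  reduced chi-square =", format(object@reducedChiSquare, digits = 4),
      "| restarts converged:", object@convergedRestarts, "/",
      object@nRestarts, "\n")
})

setMethod("show", "ConsensusNetwork", function(object) {
  cat("ConsensusNetwork:", nrow(object@edges), "edges present in >=",
      object@k, "of", length(object@members), "models\n")
})
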