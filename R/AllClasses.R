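#' @import methods
NULL

#' SignalingNetwork: a directed signed-interaction graph
#'
#' Container for the topology of a signaling network. Nodes represent the
#' measured phospho-signal of a protein (or an external stimulus such as
#' receptor crosslinking); directed edges represent direct influences whose
#' strengths (local response coefficients) are estimated from data.
#' Stimulus nodes are explicit graph nodes without incoming edges; the
#' stimulation strength is absorbed into their outgoing coefficients.
#'
#' @slot nodes character vector of unique node names, in order of first
#'   appearance in the edge list.
#' @slot from,to parallel character vectors: edge i runs `from[i] -> to[i]`.
#' @slot stimuli character vector, subset of `nodes`, naming external
#'   stimulus entry points (e.g. the BCR node engaged by anti-IgM).
#'
#' @export
setClass("SignalingNetwork",
  slots = c(nodes = "character", from = "character", to = "character",
            stimuli = "character"))

setValidity("SignalingNetwork", function(object) {
  msgs <- character()
  if (anyDuplicated(object@nodes))
    msgs <- c(msgs, "duplicate node names")
  if (length(object@from) != length(object@to))
    msgs <- c(msgs, "edge source/target vectors differ in length")
  bad <- setdiff(c(object@from, object@to, object@stimuli), object@nodes)
  if (length(bad))
    msgs <- c(msgs, paste0("undeclared nodes referenced: ",
                           paste(bad, collapse = ", ")))
  self <- object@from == object@to
  if (any(self))
    msgs <- c(msgs, paste0("self-loop on ", paste(unique(object@from[self]),
                                                  collapse = ", ")))
  key <- paste(object@from, object@to, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    msgs <- c(msgs, paste0("duplicate edge ",
                           gsub("\r", "->", d, fixed = TRUE)))
  }
  into <- object@to %in% object@stimuli
  if (any(into))
    msgs <- c(msgs, paste0("edge into stimulus node ",
                           paste(unique(object@to[into]), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' PerturbationDesign: conditions, readouts and masked measurements
#'
#' Describes which nodes were stimulated and which were inhibited in each
#' experimental condition, which antibody readouts map to which network
#' nodes, and which (inhibitor target, readout) measurements are masked.
#' Masking is used when an inhibitor perturbs the phospho-signal of its own
#' target (e.g. allosteric AKT and covalent Btk inhibitors): in every
#' condition containing that inhibitor, the corresponding readout is
#' excluded from fitting.
#'
#' @slot conditionIds character vector of unique condition identifiers.
#' @slot stimulated list (one element per condition) of stimulated nodes.
#' @slot inhibited list (one element per condition) of inhibited nodes.
#' @slot measured named character vector: names are readout names, values
#'   are the network nodes they report on.
#' @slot masked data.frame with columns `target` (inhibited node) and
#'   `readout` whose combinations are dropped.
#'
#' @export
setClass("PerturbationDesign",
  slots = c(conditionIds = "character", stimulated = "list",
            inhibited = "list", measured = "character", masked = "data.frame"))

setValidity("PerturbationDesign", function(object) {
  msgs <- character()
  n <- length(object@conditionIds)
  if (n == 0L) msgs <- c(msgs, "empty condition list")
  if (anyDuplicated(object@conditionIds))
    msgs <- c(msgs, "duplicate condition ids")
  if (length(object@stimulated) != n || length(object@inhibited) != n)
    msgs <- c(msgs, "per-condition lists not conformal with condition ids")
  if (is.null(names(object@measured)) || anyDuplicated(names(object@measured)))
    msgs <- c(msgs, "readout names missing or duplicated")
  if (!all(c("target", "readout") %in% colnames(object@masked)))
    msgs <- c(msgs, "masked must have columns target, readout")
  else if (nrow(object@masked) &&
           !all(object@masked$readout %in% names(object@measured)))
    msgs <- c(msgs, "masked readout not among measured readouts")
  if (length(msgs)) msgs else TRUE
})

#' PerturbationDataset: log2 fold-change measurements with errors
#'
#' Holds the condition-by-readout matrix of log2 fold changes versus the
#' unperturbed solvent control, and the matching per-cell standard errors
#' (mean over replicates). `NA` cells are missing (masked readouts) and are
#' excluded from all residual sums.
#'
#' @slot values numeric matrix, conditions in rows, readouts in columns.
#' @slot errors numeric matrix of identical shape, strictly positive where
#'   the value is observed.
#' @slot nReplicates integer, replicate count behind each mean.
#'
#' @export
setClass("PerturbationDataset",
  slots = c(values = "matrix", errors = "matrix", nReplicates = "integer"))

setValidity("PerturbationDataset", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), dim(object@errors)))
    msgs <- c(msgs, "values and errors differ in shape")
  obs <- !is.na(object@values)
  if (any(obs & (is.na(object@errors) | object@errors <= 0)))
    msgs <- c(msgs, "non-positive or missing error on an observed cell")
  if (length(msgs)) msgs else TRUE
})

#' CoefficientPaths: identifiable parameter combinations
#'
#' The structurally identifiable combinations of local response coefficients
#' and inhibitor strengths for a network/design pair, found by exact
#' Gaussian elimination over the integer exponent vectors of the response
#' monomials. Each path is a product of raw coefficients; a path that
#' consists of a single raw coefficient means that coefficient is
#' identifiable on its own.
#'
#' @slot parameters character vector naming all raw parameters
#'   (`r_<target>_<source>` for edges, `l_<node>` for inhibitor strengths).
#' @slot exponents integer matrix, one row per path (rownames are the
#'   canonical path names), one column per raw parameter.
#' @slot values numeric vector of fitted path values (NA before fitting).
#'
#' @export
setClass("CoefficientPaths",
  slots = c(parameters = "character", exponents = "matrix",
            values = "numeric"))

setValidity("CoefficientPaths", function(object) {
  msgs <- character()
  if (ncol(object@exponents) != length(object@parameters))
    msgs <- c(msgs, "exponent columns not conformal with parameter names")
  if (length(object@values) != nrow(object@exponents))
    msgs <- c(msgs, "values not conformal with paths")
  if (nrow(object@exponents) > 1L &&
      qr(object@exponents)$rank < nrow(object@exponents))
    msgs <- c(msgs, "exponent vectors are linearly dependent")
  if (length(msgs)) msgs else TRUE
})

#' MRAModel: a parameterized steady-state response model
#'
#' Couples a network topology and perturbation design with concrete local
#' response coefficients (`r`, diagonal fixed at -1), inhibitor strengths
#' (`l < 0`), and the identifiable coefficient-path parameterization.
#'
#' @slot network a [SignalingNetwork-class].
#' @slot design a [PerturbationDesign-class].
#' @slot r numeric node-by-node matrix; `r[i, j]` is the local response
#'   coefficient of edge `j -> i`, zero off the edge set, diagonal -1.
#' @slot inhibitors named numeric vector of strictly negative inhibitor
#'   strengths, one per inhibited node in the design.
#' @slot paths a [CoefficientPaths-class] object.
#' @slot fixed character vector of raw parameter names held constant during
#'   fitting (e.g. inhibitor strengths clamped for cross-model comparison).
#'
#' @export
setClass("MRAModel",
  slots = c(network = "SignalingNetwork", design = "PerturbationDesign",
            r = "matrix", inhibitors = "numeric", paths = "CoefficientPaths",
            fixed = "character"))

setValidity("MRAModel", function(object) {
  msgs <- character()
  nn <- object@network@nodes
  if (!identical(dim(object@r), c(length(nn), length(nn))))
    msgs <- c(msgs, "r matrix not conformal with nodes")
  else {
    if (any(abs(diag(object@r) + 1) > 1e-12))
      msgs <- c(msgs, "diagonal of r must be -1")
    allowed <- matrix(FALSE, length(nn), length(nn),
                      dimnames = list(nn, nn))
    allowed[cbind(object@network@to, object@network@from)] <- TRUE
    diag(allowed) <- TRUE
    if (any(object@r[!allowed] != 0))
      msgs <- c(msgs, "nonzero coefficient outside the edge set")
  }
  if (length(object@inhibitors) && any(object@inhibitors >= 0))
    msgs <- c(msgs, "inhibitor strengths must be strictly negative")
  if (length(msgs)) msgs else TRUE
})

#' MRAFit: result of a weighted least-squares model fit
#'
#' @slot model the fitted [MRAModel-class].
#' @slot wssrFit weighted sum of squared residuals at the optimum.
#' @slot nDatapoints number of non-missing data cells entering the fit.
#' @slot nParameters number of identifiable model parameters (numerical
#'   Jacobian rank over the free raw parameters).
#' @slot nFreeParameters degrees of freedom: `nDatapoints - nParameters`.
#' @slot reducedChiSquare `wssrFit / nFreeParameters`.
#' @slot nRestarts number of Latin-hypercube restarts attempted.
#' @slot convergedRestarts restarts finishing within relative 1e-6 of the
#'   best objective.
#' @slot seed integer seed that reproduces the fit.
#'
#' @export
setClass("MRAFit",
  slots = c(model = "MRAModel", wssrFit = "numeric", nDatapoints = "integer",
            nParameters = "integer", nFreeParameters = "integer",
            reducedChiSquare = "numeric", nRestarts = "integer",
            convergedRestarts = "integer", seed = "integer"))

#' ConsensusNetwork: edges voted across fitted models
#'
#' @slot edges data.frame with columns `source`, `target`, `votes`, one
#'   binned-state column per member model, and `consensus` (majority bin or
#'   "unresolved" on ties).
#' @slot k minimum number of member models an edge must appear in.
#' @slot members names of the member models.
#'
#' @export
setClass("ConsensusNetwork",
  slots = c(edges = "data.frame", k = "integer", members = "character"))
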