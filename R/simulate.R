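#' Global response from local response coefficients
#'
#' Solves the steady-state Modular Response Analysis relation
#' `R = -r^{-1} p`: the observable global response of every node to a
#' perturbation vector, given the local response matrix.
#'
#' @param r square local response matrix (diagonal -1, zeros off the edge
#'   set).
#' @param p perturbation vector, conformal with `r`.
#' @return numeric vector of node responses.
#' @examples
#' r <- rbind(c(-1, 0), c(2, -1))   # A -> B with coefficient 2
#' localToGlobal(r, c(1, 0))        # c(1, 2)
#' @export
localToGlobal <- function(r, p) {
  x <- tryCatch(solve(r, -p), error = function(e)
    stop("local response matrix is singular (det = ",
         format(det(r), digits = 3), "); responses undefined", call. = FALSE))
  as.numeric(x)
}

# Effective linear system for one condition.
#
# An inhibitor on node k changes what k transmits to its targets from x_k
# to e^{l_k} x_k + l_k: a basal negative offset l_k plus a dampening e^{l_k}
# of the propagated signal. In matrix form the off-diagonal column k of r is
# scaled by e^{l_k} and every target j gains a constant input r[j,k] * l_k.
# Stimulated nodes receive a unit perturbation entry.
effectiveSystem <- function(r, stimulated, inhibited, inhibitorStrengths,
                            nodes) {
  A <- r
  n <- length(nodes)
  p <- numeric(n)
  p[match(stimulated, nodes)] <- 1
  for (k in inhibited) {
    ki <- match(k, nodes)
    lk <- inhibitorStrengths[[k]]
    col <- r[, ki]
    col[ki] <- 0                      # the node's own equation is untouched
    p <- p + col * lk
    A[, ki] <- col * exp(lk)
    A[ki, ki] <- r[ki, ki]
  }
  list(A = A, b = -p)
}

solveCondition <- function(sys) {
  x <- tryCatch(solve(sys$A, sys$b), error = function(e)
    stop("effective response matrix is singular under this perturbation",
         call. = FALSE))
  as.numeric(x)
}

#' Simulate the steady-state response of one condition
#'
#' Stimulated nodes receive a unit perturbation entry; an inhibited node k
#' transmits `e^{l_k} x_k + l_k` instead of `x_k` to its targets (its own
#' response is not directly altered). Responses are log2 fold changes
#' versus the unperturbed control.
#'
#' @param model an [MRAModel-class] with parameter values set.
#' @param stimulated,inhibited character vectors of perturbed nodes, or
#'   `condition` gives the index/id of a design condition.
#' @param condition optional condition index or id in `model@design`.
#' @return named numeric vector of node responses.
#' @export
simulateCondition <- function(model, condition = NULL, stimulated = character(),
                              inhibited = character()) {
  if (!is.null(condition)) {
    i <- if (is.character(condition))
      match(condition, model@design@conditionIds) else condition
    stimulated <- model@design@stimulated[[i]]
    inhibited <- model@design@inhibited[[i]]
  }
  nodes <- model@network@nodes
  sys <- effectiveSystem(model@r, stimulated, inhibited,
                         model@inhibitors, nodes)
  x <- solveCondition(sys)
  names(x) <- nodes
  x
}

#' Simulate a full perturbation dataset
#'
#' Applies [simulateCondition()] to every condition of the design, projects
#' node responses onto the measured readouts and applies masking.
#'
#' @param model an [MRAModel-class].
#' @param design a [PerturbationDesign-class]; defaults to the model's own.
#' @return numeric condition-by-readout matrix of predicted log2 fold
#'   changes; masked cells are `NA`.
#' @export
simulateDataset <- function(model, design = model@design) {
  nodes <- model@network@nodes
  readouts <- names(design@measured)
  nodeIdx <- match(design@measured, nodes)
  out <- matrix(NA_real_, length(design@conditionIds), length(readouts),
                dimnames = list(design@conditionIds, readouts))
  for (i in seq_along(design@conditionIds)) {
    x <- simulateCondition(model,
                           stimulated = design@stimulated[[i]],
                           inhibited = design@inhibited[[i]])
    out[i, ] <- x[nodeIdx]
  }
  applyMasking(out, design)
}

#' Assemble an MRAModel from raw parameter values
#'
#' @param network a [SignalingNetwork-class].
#' @param design a [PerturbationDesign-class].
#' @param coefficients named numeric vector of edge coefficients
#'   (`r_<target>_<source>`); unnamed vectors are taken in edge order.
#' @param inhibitors named numeric vector of inhibitor strengths
#'   (`l_<node>` or plain node names), strictly negative.
#' @param paths optional precomputed [CoefficientPaths-class]; computed on
#'   demand otherwise.
#' @param fixed character vector of raw parameter names held fixed.
#' @return an [MRAModel-class].
#' @export
mraModel <- function(network, design, coefficients, inhibitors = numeric(),
                     paths = NULL, fixed = character()) {
  nodes <- network@nodes
  en <- edgeNames(network)
  if (is.null(names(coefficients))) {
    stopifnot(length(coefficients) == length(en))
    names(coefficients) <- en
  }
  r <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  diag(r) <- -1
  r[cbind(network@to, network@from)] <- coefficients[en]
  if (length(inhibitors)) {
    nm <- names(inhibitors)
    nm <- sub("^l_", "", nm)
    names(inhibitors) <- nm
  }
  if (is.null(paths))
    paths <- coefficientPaths(network, design, warn = FALSE)
  model <- new("MRAModel", network = network, design = design, r = r,
               inhibitors = inhibitors, paths = paths, fixed = fixed)
  model@paths@values <- evaluatePaths(model)
  model
}

# Raw values extended with the dampening factors exp(l_k).
extendedValues <- function(raw) {
  isL <- startsWith(names(raw), "l_")
  if (!any(isL)) return(raw)
  e <- exp(raw[isL])
  names(e) <- paste0("exp(", names(raw)[isL], ")")
  c(raw, e)
}

# Evaluate all path monomials at the model's raw parameter values.
evaluatePaths <- function(model) {
  exps <- model@paths@exponents
  if (!nrow(exps)) return(numeric())
  vals <- extendedValues(rawParameterValues(model))[model@paths@parameters]
  apply(exps, 1L, function(e) prod(vals^e))
}

#' Raw parameter values of a model
#'
#' Named vector of all raw parameters: edge coefficients
#' (`r_<target>_<source>`) followed by inhibitor strengths (`l_<node>`).
#'
#' @param model an [MRAModel-class].
#' @return named numeric vector.
#' @export
rawParameterValues <- function(model) {
  en <- edgeNames(model@network)
  vals <- model@r[cbind(model@network@to, model@network@from)]
  names(vals) <- en
  if (length(model@inhibitors)) {
    lv <- model@inhibitors
    names(lv) <- paste0("l_", names(model@inhibitors))
    vals <- c(vals, lv)
  }
  vals
}
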