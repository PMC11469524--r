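#' Weighted sum of squared residuals
#'
#' Sum over all non-missing cells of `((data - sim) / error)^2`. Missing
#' cells (in either matrix) are excluded.
#'
#' @param data a [PerturbationDataset-class] (or numeric matrix of values,
#'   in which case `errors` must be supplied).
#' @param sim numeric matrix of model predictions, conformal with the data.
#' @param errors numeric matrix of per-cell errors when `data` is a plain
#'   matrix.
#' @param errorFloor lower bound applied to the errors before weighting.
#' @return the WSSR, a non-negative number.
#' @examples
#' wssr(matrix(1), matrix(0.5), errors = matrix(0.25))  # 4
#' @export
wssr <- function(data, sim, errors = NULL, errorFloor = 0) {
  if (is(data, "PerturbationDataset")) {
    errors <- data@errors
    data <- data@values
  }
  if (is.null(errors)) stop("errors required")
  errors <- pmax(errors, errorFloor)
  keep <- !is.na(data) & !is.na(sim)
  if (any(keep & (is.na(errors) | errors <= 0)))
    stop("non-positive error on an observed cell")
  sum(((data[keep] - sim[keep]) / errors[keep])^2)
}

#' Reduced chi-square statistic
#'
#' `wssrFit / (nDatapoints - nParams)`: the goodness-of-fit statistic whose
#' expectation is 1 when the model is correct and the weights equal the
#' noise standard deviation.
#'
#' @param wssrFit weighted sum of squared residuals at the optimum.
#' @param nDatapoints number of (non-missing) data points fitted.
#' @param nParams number of identifiable model parameters.
#' @return the reduced chi-square.
#' @export
reducedChiSquare <- function(wssrFit, nDatapoints, nParams) {
  dof <- nDatapoints - nParams
  if (dof <= 0)
    stop("model not overdetermined: ", nDatapoints, " data points for ",
         nParams, " parameters")
  wssrFit / dof
}

# Shared internals: observed-cell bookkeeping for a (design, data) pair.
makeObjective <- function(engine, data, errorFloor) {
  cells <- engineCellIndex(engine)
  vals <- data@values[cells]
  errs <- pmax(data@errors[cells], errorFloor)
  obs <- which(!is.na(vals))
  if (any(is.na(errs[obs]) | errs[obs] <= 0))
    stop("non-positive error on an observed cell after flooring")
  list(cells = cells[obs, , drop = FALSE], vals = vals[obs],
       errs = errs[obs], obs = obs, n = length(obs))
}

objResiduals <- function(engine, obj, theta) {
  ev <- engineEval(engine, theta)
  if (is.null(ev)) return(rep(1e6, obj$n))
  sim <- unlist(ev$sim, use.names = FALSE)[obj$obs]
  res <- (obj$vals - sim) / obj$errs
  res[!is.finite(res)] <- 1e6
  res
}

objJacobian <- function(engine, obj, theta, freeIdx) {
  ev <- engineEval(engine, theta, jacobian = TRUE)
  if (is.null(ev)) return(matrix(0, obj$n, length(freeIdx)))
  J <- -ev$jac[obj$obs, freeIdx, drop = FALSE] / obj$errs
  J[!is.finite(J)] <- 0
  J
}

lhsStarts <- function(nStarts, paramNames, magRange, inhRange) {
  nFree <- length(paramNames)
  isL <- startsWith(paramNames, "l_")
  U <- lhs::randomLHS(nStarts, nFree)
  starts <- matrix(0, nStarts, nFree, dimnames = list(NULL, paramNames))
  lmag <- log10(magRange)
  starts[, !isL] <- 10^(lmag[1] + U[, !isL, drop = FALSE] * diff(lmag)) *
    sign(stats::runif(nStarts * sum(!isL)) - 0.5)
  starts[, isL] <- inhRange[1] + U[, isL, drop = FALSE] * diff(inhRange)
  starts
}

#' Fit an MRA model to perturbation data
#'
#' Minimizes the weighted sum of squared residuals over the raw parameters
#' (edge coefficients unconstrained, inhibitor strengths constrained
#' negative) with damped least squares (Levenberg-Marquardt, analytic
#' Jacobian), restarted from Latin-hypercube-sampled initial points. The
#' identifiable parameter count (numerical Jacobian rank, cross-checked
#' against the symbolic coefficient-path analysis) supplies the degrees of
#' freedom of the reduced chi-square.
#'
#' @param network a [SignalingNetwork-class].
#' @param design a [PerturbationDesign-class].
#' @param data a [PerturbationDataset-class].
#' @param nStarts number of Latin-hypercube restarts.
#' @param seed integer seed controlling restarts (recorded in the result).
#' @param errorFloor per-cell standard errors are floored at this value
#'   (log2 units) to prevent infinite weights.
#' @param magnitudeRange log-uniform magnitude range for edge-coefficient
#'   starting values (sign random).
#' @param inhibitorRange uniform range for inhibitor-strength starting
#'   values.
#' @param maxit,ftol Levenberg-Marquardt iteration cap and relative
#'   function tolerance for the polishing stage.
#' @param exploreIter iteration cap of the exploration stage (every
#'   restart); the best `polishBest` endpoints are then polished with up to
#'   `maxit` further iterations.
#' @param polishBest number of best exploration endpoints to polish.
#' @param signRefine after polishing, sweep over the edge coefficients of
#'   the best fit, flipping one sign at a time and re-optimizing briefly;
#'   accepted flips are polished fully. Sign errors on weakly constrained
#'   edges are the dominant local-minimum mode of this objective, and the
#'   sweep escapes them deterministically.
#' @param fixed named numeric vector of raw parameters clamped to the given
#'   values (excluded from the identifiable parameter count).
#' @param init optional named numeric vector of raw parameter values used
#'   as an additional (first) warm start.
#' @param paths optional precomputed [CoefficientPaths-class].
#' @return an [MRAFit-class].
#' @export
fitModel <- function(network, design, data, nStarts = 100L, seed = 1L,
                     errorFloor = 0.05, magnitudeRange = c(0.01, 100),
                     inhibitorRange = c(-5, -0.01), maxit = 1000L,
                     ftol = 1e-8, exploreIter = 200L, polishBest = 5L,
                     signRefine = TRUE, fixed = NULL, init = NULL,
                     paths = NULL) {
  validateDesign(network, design, data)
  if (all(lengths(design@stimulated) + lengths(design@inhibited) == 0))
    stop("design has no perturbed conditions")
  engine <- makeEngine(network, design)
  if (!is.null(fixed) && length(fixed)) {
    names(fixed) <- normalizeInhibitorNames(names(fixed), engine$paramNames)
    bad <- setdiff(names(fixed), engine$paramNames)
    if (length(bad))
      stop("fixed parameter(s) not in model: ", paste(bad, collapse = ", "))
  } else fixed <- numeric()
  freeNames <- setdiff(engine$paramNames, names(fixed))
  freeIdx <- match(freeNames, engine$paramNames)
  if (!length(freeNames)) stop("no free parameters")
  obj <- makeObjective(engine, data, errorFloor)
  if (is.null(paths)) paths <- coefficientPaths(network, design, warn = FALSE)

  fullTheta <- function(thetaFree) {
    th <- numeric(engine$nParam)
    names(th) <- engine$paramNames
    th[names(fixed)] <- fixed
    th[freeNames] <- thetaFree
    th
  }
  fn <- function(tf) objResiduals(engine, obj, fullTheta(tf))
  jac <- function(tf) objJacobian(engine, obj, fullTheta(tf), freeIdx)
  isL <- startsWith(freeNames, "l_")
  lower <- ifelse(isL, -20, -Inf)
  upper <- ifelse(isL, -1e-4, Inf)

  set.seed(seed)
  starts <- lhsStarts(nStarts, freeNames, magnitudeRange, inhibitorRange)
  if (!is.null(init)) {
    names(init) <- normalizeInhibitorNames(names(init), engine$paramNames)
    row <- starts[1, ]
    row[intersect(names(init), freeNames)] <-
      init[intersect(names(init), freeNames)]
    starts <- rbind(row, starts)
  }
  runLM <- function(par, iter) tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = pmin(pmax(par, lower), upper),
                         fn = fn, jac = jac, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = iter, ftol = ftol, nprint = 0))),
    error = function(e) NULL)
  # stage 1: short exploration from every start
  explore <- lapply(seq_len(nrow(starts)), function(i)
    runLM(starts[i, ], min(exploreIter, maxit)))
  devs <- vapply(explore, function(r)
    if (is.null(r)) Inf else r$deviance, numeric(1))
  # stage 2: polish the most promising endpoints
  top <- utils::head(order(devs), polishBest)
  best <- NULL
  for (i in top) {
    if (is.null(explore[[i]])) next
    res <- runLM(explore[[i]]$par, maxit)
    if (is.null(res)) res <- explore[[i]]
    devs[i] <- res$deviance
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop("all ", nrow(starts), " restarts failed to converge; ",
         "check the design and data scaling")
  # stage 3: deterministic sign-flip sweeps over free edge coefficients
  if (signRefine) {
    edgeFree <- which(!startsWith(freeNames, "l_"))
    sweeps <- 0L
    improved <- TRUE
    while (improved && sweeps < 3L) {
      improved <- FALSE
      sweeps <- sweeps + 1L
      for (j in edgeFree) {
        cand <- best$par
        if (cand[j] == 0) next
        cand[j] <- -cand[j]
        res <- runLM(cand, 60L)
        if (!is.null(res) && res$deviance < best$deviance - 1e-8) {
          pol <- runLM(res$par, maxit)
          if (!is.null(pol) && pol$deviance < best$deviance) {
            best <- pol
            improved <- TRUE
          }
        }
      }
    }
  }
  converged <- sum(devs <= best$deviance * (1 + 1e-6) + 1e-12)
  if (converged < 2 && nrow(starts) >= 2)
    warning("optimum plateau reached by a single restart only; ",
            "consider more restarts")
  theta <- fullTheta(best$par)
  nParams <- numericalRank(network, design, free = freeNames,
                           seeds = seed + c(7717L, 15431L))
  model <- mraModel(network, design,
                    coefficients = theta[seq_len(engine$nEdge)],
                    inhibitors = theta[engine$nEdge +
                                         seq_along(engine$inhNodes)],
                    paths = paths, fixed = as.character(names(fixed)))
  new("MRAFit", model = model, wssrFit = best$deviance,
      nDatapoints = as.integer(obj$n), nParameters = as.integer(nParams),
      nFreeParameters = as.integer(obj$n - nParams),
      reducedChiSquare = reducedChiSquare(best$deviance, obj$n, nParams),
      nRestarts = as.integer(nrow(starts)),
      convergedRestarts = as.integer(converged), seed = as.integer(seed))
}

normalizeInhibitorNames <- function(nm, paramNames) {
  if (is.null(nm)) return(nm)
  plain <- !nm %in% paramNames & paste0("l_", nm) %in% paramNames
  nm[plain] <- paste0("l_", nm[plain])
  nm
}

#' Refit a model with inhibitor strengths clamped
#'
#' For cross-model coefficient comparison the inhibitor strengths are fixed
#' to common values (both models received the same doses) and the network
#' coefficient paths are allowed to compensate. The clamped parameters are
#' excluded from the identifiable parameter count.
#'
#' @param fit an [MRAFit-class].
#' @param fixedValues named numeric vector of inhibitor strengths
#'   (`l_<node>` or plain node names).
#' @param data the [PerturbationDataset-class] to refit against.
#' @param nStarts restarts in addition to the warm start from `fit`.
#' @param ... further arguments to [fitModel()].
#' @return an [MRAFit-class] with reduced free-parameter count.
#' @export
refitWithFixedInhibitors <- function(fit, fixedValues, data, nStarts = 10L,
                                     ...) {
  model <- fit@model
  engine <- makeEngine(model@network, model@design)
  nm <- normalizeInhibitorNames(names(fixedValues), engine$paramNames)
  bad <- setdiff(nm, engine$paramNames)
  if (length(bad))
    stop("cannot fix parameter(s) absent from the model: ",
         paste(bad, collapse = ", "))
  names(fixedValues) <- nm
  fitModel(model@network, model@design, data, nStarts = nStarts,
           fixed = fixedValues, init = rawParameterValues(model),
           paths = model@paths, ...)
}
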