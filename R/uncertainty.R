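#' Profile-likelihood confidence interval for a coefficient path
#'
#' Steps the value of one coefficient path away from its optimum in both
#' directions, re-optimizing all other free parameters at each step, until
#' the WSSR exceeds the fit optimum plus the chi-square(1) quantile at
#' `1 - alpha` (3.841 for alpha = 0.05). The crossing is located by
#' bracketing with a doubling step followed by bisection. If the path value
#' exceeds `bound` in magnitude without crossing, the direction is flagged
#' non-identifiable (`ni`), mirroring the "ni" markers of profile-likelihood
#' tables: the change can be compensated by the other coefficients.
#'
#' The path monomial is constrained by eliminating one of its raw factors:
#' that factor is computed from the target path value and the remaining
#' factors, and the optimizer works on the remaining free parameters with
#' the chain rule applied to the Jacobian.
#'
#' @param fit an [MRAFit-class].
#' @param data the fitted [PerturbationDataset-class].
#' @param pathName name(s) of coefficient paths (default: all).
#' @param alpha pointwise level (default 0.05 for 95% CIs, 1 df).
#' @param bound parameter magnitude beyond which a direction is declared
#'   non-identifiable.
#' @param errorFloor error floor matching the fit.
#' @param maxit Levenberg-Marquardt iteration cap per profile point.
#' @param stepTol bisection stops when the WSSR is within
#'   `stepTol * max(1, threshold)` of the threshold.
#' @return data.frame with columns `path`, `estimate`, `lower`, `upper`,
#'   `niLower`, `niUpper`.
#' @export
profileLikelihood <- function(fit, data, pathName = NULL, alpha = 0.05,
                              bound = 1e4, errorFloor = 0.05, maxit = 200L,
                              stepTol = 1e-3) {
  model <- fit@model
  allPaths <- pathNames(model)
  if (is.null(pathName)) pathName <- allPaths
  miss <- setdiff(pathName, allPaths)
  if (length(miss))
    stop("unknown path(s): ", paste(miss, collapse = ", "))
  engine <- makeEngine(model@network, model@design)
  obj <- makeObjective(engine, data, errorFloor)
  thetaHat <- rawParameterValues(model)
  fixed <- model@fixed
  threshold <- fit@wssrFit + stats::qchisq(1 - alpha, df = 1)
  out <- lapply(pathName, function(pn)
    profileOnePath(engine, obj, model, thetaHat, fixed, pn, threshold,
                   bound, maxit, stepTol))
  do.call(rbind, out)
}

profileOnePath <- function(engine, obj, model, thetaHat, fixed, pn,
                           threshold, bound, maxit, stepTol) {
  exps <- model@paths@exponents
  extParams <- model@paths@parameters     # includes exp(l_) symbols
  e <- stats::setNames(as.numeric(exps[pn, ]), extParams)
  params <- engine$paramNames             # underlying parameters
  support <- extParams[e != 0]
  # only an underlying factor can be eliminated; prefer an edge coefficient
  # that appears in few other paths so the parameterization stays flexible
  elimCand <- setdiff(intersect(support, params), fixed)
  # an inhibitor strength cannot be eliminated in closed form when its
  # dampening factor is also part of the path
  elimCand <- elimCand[!(startsWith(elimCand, "l_") &
                           paste0("exp(", elimCand, ")") %in% support)]
  if (!length(elimCand))
    stop("path ", pn, " has no free factor; cannot profile")
  usage <- colSums(exps[setdiff(rownames(exps), pn), , drop = FALSE] != 0)
  elimCand <- elimCand[order(startsWith(elimCand, "l_"),
                             usage[elimCand], elimCand)]
  elim <- elimCand[1]
  eElim <- e[[elim]]
  others <- setdiff(support, elim)
  free2 <- setdiff(params, c(fixed, elim))
  isL <- startsWith(free2, "l_")
  lower <- ifelse(isL, -20, -Inf)
  upper <- ifelse(isL, -1e-4, Inf)
  elimIdx <- match(elim, params)
  free2Idx <- match(free2, params)
  # d log(path)/d theta_j contribution of the non-eliminated factors:
  # alpha/theta for plain factors, gamma extra for exp(l) factors
  dLogOthers <- function(th) {
    d <- numeric(length(free2))
    for (j in seq_along(free2)) {
      nm <- free2[j]
      a <- if (nm %in% others) e[[nm]] else 0
      g <- if (startsWith(nm, "l_") &&
               paste0("exp(", nm, ")") %in% others)
        e[[paste0("exp(", nm, ")")]] else 0
      d[j] <- a / th[[nm]] + g
    }
    d
  }
  assemble <- function(tf2, target) {
    th <- thetaHat
    th[fixed] <- thetaHat[fixed]
    th[free2] <- tf2
    ext <- extendedValues(th)
    prodOthers <- prod(ext[others]^e[others])
    if (prodOthers == 0 || !is.finite(prodOthers)) return(NULL)
    ratio <- target / prodOthers
    v <- if (eElim == 1) ratio
    else if (ratio >= 0) ratio^(1 / eElim)
    else if (eElim %% 2 == 1) -((-ratio)^(1 / eElim))
    else return(NULL)
    if (startsWith(elim, "l_") && v >= -1e-4) return(NULL)
    th[elim] <- v
    th
  }
  profilePoint <- function(target, start) {
    fn <- function(tf2) {
      th <- assemble(tf2, target)
      if (is.null(th)) return(rep(1e6, obj$n))
      objResiduals(engine, obj, th)
    }
    jac <- function(tf2) {
      th <- assemble(tf2, target)
      if (is.null(th)) return(matrix(0, obj$n, length(free2)))
      J <- objJacobianFull(engine, obj, th)
      J2 <- J[, free2Idx, drop = FALSE]
      dElim <- -th[[elim]] * dLogOthers(th) / eElim
      J2 + J[, elimIdx] %o% dElim
    }
    res <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(start, lower), upper), fn = fn,
                         jac = jac, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxit, ftol = 1e-8)),
      error = function(err) NULL)
    if (is.null(res)) {
      warning("profile refit failed at ", pn, " = ",
              format(target, digits = 4), "; point skipped")
      return(list(wssr = Inf, par = start))
    }
    list(wssr = res$deviance, par = res$par)
  }
  est <- prod(extendedValues(thetaHat)[support]^e[support])
  startHat <- thetaHat[free2]
  scanDirection <- function(dir) {
    stepSize <- max(0.1 * abs(est), 0.01)
    t <- est
    lastBelow <- est
    warm <- startHat
    firstAbove <- NULL
    repeat {
      t2 <- t + dir * stepSize
      if (abs(t2) > bound) return(list(bound = NA_real_, ni = TRUE))
      pt <- profilePoint(t2, warm)
      if (pt$wssr < threshold) {
        lastBelow <- t2
        t <- t2
        warm <- pt$par
        stepSize <- stepSize * 2
      } else {
        firstAbove <- t2
        break
      }
    }
    lo <- lastBelow
    hi <- firstAbove
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      pt <- profilePoint(mid, warm)
      if (pt$wssr < threshold) {
        lo <- mid
        warm <- pt$par
      } else hi <- mid
      if (abs(pt$wssr - threshold) < stepTol * max(1, threshold) ||
          abs(hi - lo) < 1e-12 * max(1, abs(est))) break
    }
    list(bound = (lo + hi) / 2, ni = FALSE)
  }
  up <- scanDirection(+1)
  dn <- scanDirection(-1)
  data.frame(path = pn, estimate = est,
             lower = dn$bound, upper = up$bound,
             niLower = dn$ni, niUpper = up$ni,
             stringsAsFactors = FALSE)
}

# Jacobian of the weighted residuals w.r.t. *all* raw parameters.
objJacobianFull <- function(engine, obj, theta) {
  ev <- engineEval(engine, theta, jacobian = TRUE)
  if (is.null(ev)) return(matrix(0, obj$n, engine$nParam))
  J <- -ev$jac[obj$obs, , drop = FALSE] / obj$errs
  J[!is.finite(J)] <- 0
  J
}

#' Fix inhibitor strengths to a common value across models
#'
#' Prepares two or more fitted models for coefficient comparison: since all
#' systems received the same inhibitor doses, differences in response are
#' attributed to the wiring by clamping each inhibitor strength to a common
#' value — either those of a reference model or the mean across models —
#' and refitting the remaining coefficients of every model.
#'
#' @param fits named list of [MRAFit-class] objects sharing the inhibitor
#'   set.
#' @param datas list of the matching [PerturbationDataset-class] objects.
#' @param reference name or index of the reference model whose inhibitor
#'   values are imposed; `NULL` (default) uses the mean across models.
#' @param ... further arguments to [refitWithFixedInhibitors()].
#' @return list of refitted [MRAFit-class] objects, same names as `fits`.
#' @export
fixInhibitorsAcrossModels <- function(fits, datas, reference = NULL, ...) {
  stopifnot(length(fits) >= 2, length(fits) == length(datas))
  strengths <- lapply(fits, inhibitorStrengths)
  shared <- Reduce(intersect, lapply(strengths, names))
  if (!length(shared)) stop("models share no inhibitor strengths")
  common <- if (is.null(reference))
    colMeans(do.call(rbind, lapply(strengths, `[`, shared)))
  else strengths[[reference]][shared]
  lapply(seq_along(fits), function(i)
    refitWithFixedInhibitors(fits[[i]], common, datas[[i]], ...))
}

#' Compare coefficient paths across models by CI overlap
#'
#' For every coefficient path shared by all models, computes the
#' profile-likelihood confidence intervals in each model and flags the path
#' as significantly different when the intervals of any pair of models are
#' disjoint. A non-identifiable direction counts as an unbounded interval
#' (never disjoint on that side). Paths present in only some models are
#' listed separately as individual links, not flagged.
#'
#' For a meaningful comparison the inhibitor strengths should have been
#' fixed to common values beforehand ([refitWithFixedInhibitors()]).
#'
#' @param fits list of two or more [MRAFit-class] objects (named, ideally).
#' @param datas list of the matching [PerturbationDataset-class] objects.
#' @param alpha pointwise CI level.
#' @param ... further arguments to [profileLikelihood()].
#' @return list with `shared` (data.frame: `path`, per-model
#'   `estimate/lower/upper`, `significant`) and `individual` (data.frame:
#'   `model`, `path`).
#' @export
compareModels <- function(fits, datas, alpha = 0.05, ...) {
  stopifnot(length(fits) >= 2, length(fits) == length(datas))
  nms <- names(fits)
  if (is.null(nms)) nms <- paste0("model", seq_along(fits))
  pathSets <- lapply(fits, pathNames)
  shared <- Reduce(intersect, pathSets)
  if (!length(shared)) stop("models share no coefficient paths")
  profs <- lapply(seq_along(fits), function(i)
    profileLikelihood(fits[[i]], datas[[i]], pathName = shared,
                      alpha = alpha, ...))
  lo <- sapply(profs, function(p) ifelse(p$niLower, -Inf, p$lower))
  hi <- sapply(profs, function(p) ifelse(p$niUpper, Inf, p$upper))
  sig <- vapply(seq_along(shared), function(r) {
    for (a in seq_along(fits))
      for (b in seq_along(fits))
        if (a < b && (lo[r, a] > hi[r, b] || lo[r, b] > hi[r, a]))
          return(TRUE)
    FALSE
  }, logical(1))
  sharedDf <- data.frame(path = shared, stringsAsFactors = FALSE)
  for (i in seq_along(fits)) {
    sharedDf[[paste0("estimate_", nms[i])]] <- profs[[i]]$estimate
    sharedDf[[paste0("lower_", nms[i])]] <- profs[[i]]$lower
    sharedDf[[paste0("upper_", nms[i])]] <- profs[[i]]$upper
  }
  sharedDf$significant <- sig
  individual <- do.call(rbind, lapply(seq_along(fits), function(i) {
    own <- setdiff(pathSets[[i]], shared)
    if (!length(own)) return(NULL)
    data.frame(model = nms[i], path = own, stringsAsFactors = FALSE)
  }))
  if (is.null(individual))
    individual <- data.frame(model = character(), path = character())
  list(shared = sharedDf, individual = individual)
}

#' Fit a foreign network structure to another dataset
#'
#' Transfers a network structure learned on one cell system to the
#' perturbation data of another: identifiability analysis and fitting are
#' redone from scratch on the foreign data, so the resulting statistics are
#' directly comparable (same degrees-of-freedom convention) with a natively
#' adapted fit.
#'
#' @param structure a [SignalingNetwork-class].
#' @param otherDesign the foreign [PerturbationDesign-class].
#' @param otherData the foreign [PerturbationDataset-class].
#' @param ... further arguments to [fitModel()].
#' @return an [MRAFit-class].
#' @export
transferStructure <- function(structure, otherDesign, otherData, ...) {
  need <- union(unlist(otherDesign@stimulated),
                union(unlist(otherDesign@inhibited),
                      unname(otherDesign@measured)))
  miss <- setdiff(need, structure@nodes)
  if (length(miss))
    stop("design references node(s) absent from the structure: ",
         paste(miss, collapse = ", "))
  fitModel(structure, otherDesign, otherData, ...)
}

#' Bin a local response coefficient into five qualitative states
#'
#' States: amplification (r > 1), dampening to neutral relay (0 < r <= 1),
#' no link (r = 0), attenuating to neutral inhibition (-1 <= r < 0),
#' enforced inhibition (r < -1). Boundary values (|r| = 1) fall into the
#' neutral-side bin; |r| below `zeroTol` is treated as no link.
#'
#' @param value numeric vector of coefficients.
#' @param zeroTol values with `abs(value) < zeroTol` map to "no link".
#' @return character vector of state labels.
#' @examples
#' binCoefficient(c(1.5, 0.3, 0, -0.4, -1.2))
#' @export
binCoefficient <- function(value, zeroTol = 1e-9) {
  labels <- c("amplification", "dampening to neutral relay", "no link",
              "attenuating to neutral inhibition", "enforced inhibition")
  out <- character(length(value))
  out[value > 1] <- labels[1]
  out[value > zeroTol & value <= 1] <- labels[2]
  out[abs(value) <= zeroTol] <- labels[3]
  out[value < -zeroTol & value >= -1] <- labels[4]
  out[value < -1] <- labels[5]
  out
}

#' Compose a response along a path
#'
#' The response transmitted along a chain of links is the product of the
#' local response coefficients; two inhibitory links in series therefore
#' yield an overall positive response.
#'
#' @param values numeric vector of coefficients along the path.
#' @return their product.
#' @examples
#' composePath(c(-0.5, -2))  # 1: inhibition of an inhibitor activates
#' @export
composePath <- function(values) {
  stopifnot(length(values) >= 1)
  prod(values)
}

#' Consensus core network by edge voting
#'
#' Votes edges across fitted models and keeps those present in at least
#' `k` of them; each kept edge carries the five-state bin of its
#' coefficient in every member model and a consensus state (majority bin
#' among the models containing the edge; ties are reported "unresolved").
#'
#' @param models list of [MRAModel-class] (or [MRAFit-class]) objects;
#'   names become member labels.
#' @param k minimum number of member models (default 3, the
#'   "at least 3 of 4" rule).
#' @return a [ConsensusNetwork-class].
#' @export
consensusNetwork <- function(models, k = 3L) {
  models <- lapply(models, function(m) if (is(m, "MRAFit")) m@model else m)
  if (k > length(models))
    stop("k = ", k, " exceeds the number of models (", length(models), ")")
  nms <- names(models)
  if (is.null(nms)) nms <- paste0("model", seq_along(models))
  edgeTabs <- lapply(models, function(m) networkEdges(m@network))
  allEdges <- unique(do.call(rbind, edgeTabs))
  key <- function(df) paste(df$source, df$target, sep = "\r")
  votes <- rowSums(sapply(edgeTabs, function(t) key(allEdges) %in% key(t)))
  keep <- votes >= k
  edges <- allEdges[keep, , drop = FALSE]
  votes <- votes[keep]
  binCols <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    has <- key(edges) %in% key(edgeTabs[[i]])
    val <- rep(0, nrow(edges))
    if (any(has))
      val[has] <- m@r[cbind(edges$target[has], edges$source[has])]
    ifelse(has, binCoefficient(val), "no link")
  })
  consensus <- vapply(seq_len(nrow(edges)), function(r) {
    bins <- vapply(seq_along(models), function(i) binCols[[i]][r],
                   character(1))
    present <- bins[bins != "no link" |
                      vapply(edgeTabs, function(t)
                        key(edges)[r] %in% key(t), logical(1))]
    tab <- sort(table(present), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) "unresolved" else names(tab)[1]
  }, character(1))
  out <- edges
  rownames(out) <- NULL
  out$votes <- as.integer(votes)
  for (i in seq_along(models)) out[[paste0("bin_", nms[i])]] <- binCols[[i]]
  out$consensus <- consensus
  new("ConsensusNetwork", edges = out, k = as.integer(k), members = nms)
}
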