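#' Likelihood-ratio test p-value for nested MRA models
#'
#' The difference in weighted sums of squared residuals between a nested
#' (smaller) and an encompassing (bigger) model is chi-square distributed
#' under the null, with degrees of freedom equal to the change in the
#' *identifiable* parameter count (not the raw edge count: an edge absorbed
#' into a coefficient path changes no degrees of freedom).
#'
#' @param wssrSmall WSSR of the nested model (must fit no better).
#' @param wssrBig WSSR of the encompassing model.
#' @param deltaDf change in identifiable parameter count (>= 0).
#' @param slack numerical slack for a slightly negative difference.
#' @return p-value in `[0, 1]`; `deltaDf = 0` returns 1.
#' @export
lrtPvalue <- function(wssrSmall, wssrBig, deltaDf, slack = 1e-6) {
  delta <- wssrSmall - wssrBig
  if (delta < -slack * max(1, wssrBig))
    stop("nested model fits better than the encompassing model ",
         "(delta WSSR = ", format(delta, digits = 4),
         "); upstream fit failure")
  delta <- max(delta, 0)
  if (deltaDf == 0) return(1)
  stats::pchisq(delta, df = deltaDf, lower.tail = FALSE)
}

# Refit helper shared by both scans: quiet fit of an altered structure,
# warm-started from the current parameter values.
scanRefit <- function(network, design, data, init, nStarts, seed, ...) {
  suppressWarnings(
    fitModel(network, design, data, nStarts = nStarts, seed = seed,
             init = init, signRefine = FALSE, ...))
}

#' Scan single-edge removals
#'
#' Refits the model once per removed edge and reports the likelihood-ratio
#' p-value of the removal. Edges whose removal does not significantly
#' worsen the fit (p > `alpha`) are removal candidates, ranked by
#' descending p; ties are broken by fewer identifiable parameters, then by
#' lexicographic edge name. A removal with unchanged identifiable parameter
#' count and essentially unchanged WSSR is a pure simplification and is
#' flagged `autoAccept`.
#'
#' @param fit the current [MRAFit-class].
#' @param data the training [PerturbationDataset-class].
#' @param alpha removal threshold (default 0.05).
#' @param nStarts restarts per candidate refit (plus the warm start).
#' @param seed integer seed.
#' @param returnFits also attach the refits as attribute `"fits"`.
#' @param ... further arguments to [fitModel()].
#' @return data.frame (one row per edge) with columns
#'   `source, target, wssr, nParameters, deltaDf, deltaWssr, p, candidate,
#'   autoAccept, failed`, candidates first in rank order.
#' @export
scanRemovals <- function(fit, data, alpha = 0.05, nStarts = 5L, seed = 1L,
                         returnFits = FALSE, ...) {
  network <- fit@model@network
  design <- fit@model@design
  init <- rawParameterValues(fit@model)
  edges <- networkEdges(network)
  rows <- vector("list", nrow(edges))
  fits <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    net2 <- removeEdge(network, edges$source[i], edges$target[i])
    f2 <- tryCatch(
      scanRefit(net2, design, data, init, nStarts, seed + i, ...),
      error = function(e) e)
    if (inherits(f2, "error")) {
      warning("removal ", edges$source[i], "->", edges$target[i],
              " skipped: ", conditionMessage(f2))
      rows[[i]] <- data.frame(source = edges$source[i],
                              target = edges$target[i], wssr = NA_real_,
                              nParameters = NA_integer_,
                              deltaDf = NA_integer_, deltaWssr = NA_real_,
                              p = NA_real_, candidate = FALSE,
                              autoAccept = FALSE, failed = TRUE)
      next
    }
    fits[[i]] <- f2
    deltaDf <- fit@nParameters - f2@nParameters
    delta <- f2@wssrFit - fit@wssrFit
    if (delta < -1e-6 * max(1, fit@wssrFit)) {
      warning("removal ", edges$source[i], "->", edges$target[i],
              " fits better than the full model; treating as removable")
      p <- 1
    } else p <- lrtPvalue(f2@wssrFit, fit@wssrFit, max(deltaDf, 0L))
    rows[[i]] <- data.frame(source = edges$source[i],
                            target = edges$target[i], wssr = f2@wssrFit,
                            nParameters = f2@nParameters,
                            deltaDf = deltaDf, deltaWssr = delta, p = p,
                            candidate = p > alpha,
                            autoAccept = deltaDf == 0 && delta < 1e-6,
                            failed = FALSE)
  }
  out <- do.call(rbind, rows)
  name <- paste0(out$source, "->", out$target)
  ord <- order(!out$candidate, -out$p, out$nParameters, name)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (returnFits) attr(out, "fits") <- fits[ord]
  out
}

#' Scan single-edge additions
#'
#' Refits the model once per absent ordered node pair (excluding self-loops
#' and edges into stimulus nodes) and reports the likelihood-ratio p-value
#' of the addition. Additions that significantly improve the fit
#' (p < `alpha`) are candidates, ranked by ascending p.
#'
#' @inheritParams scanRemovals
#' @param alpha addition threshold (default 0.05).
#' @return data.frame as in [scanRemovals()] (without `autoAccept`),
#'   candidates first in rank order.
#' @export
scanAdditions <- function(fit, data, alpha = 0.05, nStarts = 5L, seed = 1L,
                          returnFits = FALSE, ...) {
  network <- fit@model@network
  design <- fit@model@design
  init <- rawParameterValues(fit@model)
  nodes <- network@nodes
  existing <- paste(network@from, network@to, sep = "\r")
  cand <- expand.grid(source = nodes, target = nodes,
                      stringsAsFactors = FALSE)
  cand <- cand[cand$source != cand$target &
                 !cand$target %in% network@stimuli &
                 !paste(cand$source, cand$target, sep = "\r") %in% existing,
               , drop = FALSE]
  rows <- vector("list", nrow(cand))
  fits <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    net2 <- addEdge(network, cand$source[i], cand$target[i])
    f2 <- tryCatch(
      scanRefit(net2, design, data, init, nStarts, seed + i, ...),
      error = function(e) e)
    if (inherits(f2, "error")) {
      warning("addition ", cand$source[i], "->", cand$target[i],
              " skipped: ", conditionMessage(f2))
      rows[[i]] <- data.frame(source = cand$source[i],
                              target = cand$target[i], wssr = NA_real_,
                              nParameters = NA_integer_,
                              deltaDf = NA_integer_, deltaWssr = NA_real_,
                              p = NA_real_, candidate = FALSE, failed = TRUE)
      next
    }
    fits[[i]] <- f2
    deltaDf <- f2@nParameters - fit@nParameters
    delta <- fit@wssrFit - f2@wssrFit
    p <- if (delta < -1e-6 * max(1, fit@wssrFit)) 1
    else lrtPvalue(fit@wssrFit, f2@wssrFit, max(deltaDf, 0L))
    rows[[i]] <- data.frame(source = cand$source[i],
                            target = cand$target[i], wssr = f2@wssrFit,
                            nParameters = f2@nParameters,
                            deltaDf = deltaDf, deltaWssr = -delta, p = p,
                            candidate = p < alpha, failed = FALSE)
  }
  out <- do.call(rbind, rows)
  name <- paste0(out$source, "->", out$target)
  ord <- order(!out$candidate, out$p, out$nParameters, name)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (returnFits) attr(out, "fits") <- fits[ord]
  out
}

#' Held-out consistency check
#'
#' Simulates the held-out conditions (in the emulated study: inhibitor
#' treatments without stimulation) and expresses the prediction quality as
#' the percentage reduction of WSSR relative to the all-zero null model
#' (unperturbed control prediction).
#'
#' @param model an [MRAModel-class] (or [MRAFit-class]).
#' @param design the held-out [PerturbationDesign-class].
#' @param data the held-out [PerturbationDataset-class].
#' @param errorFloor error floor applied to both WSSRs.
#' @return list with `wssrSimulation`, `wssrNullmodel`,
#'   `errorReductionPct` (`100 * (null - sim) / null`; negative when the
#'   model predicts worse than the null).
#' @export
consistencyCheck <- function(model, design, data, errorFloor = 0.05) {
  if (is(model, "MRAFit")) model <- model@model
  sim <- simulateDataset(model, design)
  wssrSim <- wssr(data, sim, errorFloor = errorFloor)
  null <- matrix(0, nrow(data@values), ncol(data@values))
  wssrNull <- wssr(data, null, errorFloor = errorFloor)
  if (wssrNull == 0)
    stop("null-model WSSR is zero; consistency undefined")
  list(wssrSimulation = wssrSim, wssrNullmodel = wssrNull,
       errorReductionPct = 100 * (wssrNull - wssrSim) / wssrNull)
}

#' Greedy network-structure adaptation
#'
#' Iteratively adapts the network to the training data: in each iteration
#' the removal candidates (likelihood-ratio p > `alphaRm`, most superfluous
#' first) and then the addition candidates (p < `alphaAdd`, most
#' significant first) are tried in rank order; a structural change is
#' upheld only if (i) the held-out consistency error reduction does not
#' drop by more than `deltaPct` percentage points and (ii) the reduced
#' chi-square does not increase. The first upheld change ends the
#' iteration; the loop stops when no candidate is upheld. Pure
#' simplifications (no change in identifiable parameters or WSSR) are
#' upheld without consulting the gate.
#'
#' @param network starting [SignalingNetwork-class].
#' @param design training [PerturbationDesign-class].
#' @param trainData training [PerturbationDataset-class].
#' @param heldoutDesign,heldoutData held-out conditions for the consistency
#'   gate; when `NULL` the gate is disabled (with a warning).
#' @param alphaRm,alphaAdd likelihood-ratio thresholds for removal and
#'   addition candidates.
#' @param deltaPct tolerated drop of the consistency error-reduction
#'   percentage per accepted step ("not significantly worse").
#' @param maxSteps cap on structural changes.
#' @param seed integer master seed; all scan seeds derive from it.
#' @param nStartsFull restarts for the full fits.
#' @param nStartsScan restarts per candidate refit inside scans.
#' @param maxCandidates candidates tried per scan before falling through.
#' @param ... further arguments to [fitModel()].
#' @return list with `fit` (final [MRAFit-class]) and `trace` (data.frame,
#'   one row per tried candidate, replayable: columns `step, action,
#'   source, target, p, deltaDf, wssrBefore, wssrAfter, xrBefore, xrAfter,
#'   errorReductionPct, accepted`).
#' @export
adaptNetwork <- function(network, design, trainData, heldoutDesign = NULL,
                         heldoutData = NULL, alphaRm = 0.05,
                         alphaAdd = 0.05, deltaPct = 2, maxSteps = 20L,
                         seed = 1L, nStartsFull = 30L, nStartsScan = 5L,
                         maxCandidates = 5L, ...) {
  gate <- !is.null(heldoutData) && !is.null(heldoutDesign)
  if (!gate)
    warning("no held-out data supplied; consistency gate disabled")
  fit <- fitModel(network, design, trainData, nStarts = nStartsFull,
                  seed = seed, ...)
  prevRed <- if (gate)
    consistencyCheck(fit, heldoutDesign, heldoutData)$errorReductionPct
  else NA_real_
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > maxSteps) break
    accepted <- FALSE
    for (action in c("remove", "add")) {
      scan <- if (action == "remove")
        scanRemovals(fit, trainData, alpha = alphaRm,
                     nStarts = nStartsScan, seed = seed + 1000L * step,
                     returnFits = TRUE, ...)
      else
        scanAdditions(fit, trainData, alpha = alphaAdd,
                      nStarts = nStartsScan, seed = seed + 1000L * step +
                        500L, returnFits = TRUE, ...)
      fits <- attr(scan, "fits")
      idx <- which(scan$candidate)
      idx <- utils::head(idx, maxCandidates)
      for (i in idx) {
        f2 <- fits[[i]]
        if (is.null(f2)) next
        auto <- action == "remove" && isTRUE(scan$autoAccept[i])
        red <- if (gate)
          consistencyCheck(f2, heldoutDesign, heldoutData)$errorReductionPct
        else NA_real_
        ok <- auto ||
          ((!gate || red >= prevRed - deltaPct) &&
             f2@reducedChiSquare <= fit@reducedChiSquare * (1 + 1e-9))
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, action = action, source = scan$source[i],
          target = scan$target[i], p = scan$p[i],
          deltaDf = scan$deltaDf[i], wssrBefore = fit@wssrFit,
          wssrAfter = f2@wssrFit, xrBefore = fit@reducedChiSquare,
          xrAfter = f2@reducedChiSquare, errorReductionPct = red,
          accepted = ok)
        if (ok) {
          fit <- f2
          if (gate && !auto) prevRed <- red
          accepted <- TRUE
          break
        }
      }
      if (accepted) break
    }
    if (!accepted) break
  }
  trace <- if (length(trace)) do.call(rbind, trace)
  else data.frame(step = integer(), action = character(),
                  source = character(), target = character(), p = numeric(),
                  deltaDf = integer(), wssrBefore = numeric(),
                  wssrAfter = numeric(), xrBefore = numeric(),
                  xrAfter = numeric(), errorReductionPct = numeric(),
                  accepted = logical())
  list(fit = fit, trace = trace)
}
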