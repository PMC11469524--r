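# Internal computational engine: precompiled condition structures plus a
# vectorized evaluator returning predicted responses and their analytic
# Jacobian with respect to the raw parameters (edge coefficients and
# inhibitor strengths). Differentiating the steady state A x = b gives
# dx = A^{-1} (db - dA x); for an edge k->j the right-hand side has a
# single nonzero entry -x~_k at row j (x~_k is the signal k transmits),
# so the Jacobian assembles from columns of A^{-1} without extra solves.

makeEngine <- function(network, design) {
  nodes <- network@nodes
  n <- length(nodes)
  toIdx <- match(network@to, nodes)
  fromIdx <- match(network@from, nodes)
  inhNodes <- intersect(nodes, unique(unlist(design@inhibited)))
  paramNames <- c(edgeNames(network),
                  if (length(inhNodes)) paste0("l_", inhNodes))
  nEdge <- length(toIdx)
  readouts <- names(design@measured)
  readoutNode <- match(design@measured, nodes)
  masked <- matrix(FALSE, length(design@conditionIds), length(readouts),
                   dimnames = list(design@conditionIds, readouts))
  masked <- is.na(applyMasking(masked + 0, design))
  conditions <- lapply(seq_along(design@conditionIds), function(i) {
    list(stim = match(design@stimulated[[i]], nodes),
         inh = match(design@inhibited[[i]], nodes),
         keep = which(!masked[i, ]))
  })
  list(nodes = nodes, n = n, toIdx = toIdx, fromIdx = fromIdx,
       nEdge = nEdge, inhNodes = inhNodes,
       inhIdx = match(inhNodes, nodes), paramNames = paramNames,
       nParam = length(paramNames), readoutNode = readoutNode,
       readouts = readouts, conditions = conditions,
       conditionIds = design@conditionIds)
}

engineRMatrix <- function(engine, theta) {
  r <- matrix(0, engine$n, engine$n)
  diag(r) <- -1
  r[cbind(engine$toIdx, engine$fromIdx)] <- theta[seq_len(engine$nEdge)]
  r
}

# Evaluate all conditions. Returns NULL if any effective system is
# (numerically) singular. With jacobian = TRUE also returns dsim/dtheta for
# every retained (condition, readout) cell, stacked condition-major.
engineEval <- function(engine, theta, jacobian = FALSE) {
  r <- engineRMatrix(engine, theta)
  lvals <- theta[engine$nEdge + seq_along(engine$inhNodes)]
  n <- engine$n
  nP <- engine$nParam
  simRows <- vector("list", length(engine$conditions))
  jacRows <- if (jacobian) vector("list", length(engine$conditions))
  for (ci in seq_along(engine$conditions)) {
    cond <- engine$conditions[[ci]]
    A <- r
    p <- numeric(n)
    p[cond$stim] <- 1
    for (k in cond$inh) {
      lk <- lvals[match(k, engine$inhIdx)]
      col <- r[, k]
      col[k] <- 0
      p <- p + col * lk
      A[, k] <- col * exp(lk)
      A[k, k] <- -1
    }
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv) || !all(is.finite(Ainv))) return(NULL)
    x <- as.numeric(Ainv %*% (-p))
    simRows[[ci]] <- x[engine$readoutNode][cond$keep]
    if (jacobian) {
      # transmitted signal of every node under this condition
      xt <- x
      for (k in cond$inh) {
        lk <- lvals[match(k, engine$inhIdx)]
        xt[k] <- exp(lk) * x[k] + lk
      }
      J <- matrix(0, n, nP)
      J[, seq_len(engine$nEdge)] <-
        Ainv[, engine$toIdx, drop = FALSE] *
        rep(-xt[engine$fromIdx], each = n)
      for (k in cond$inh) {
        ki <- match(k, engine$inhIdx)
        lk <- lvals[ki]
        col <- r[, k]
        col[k] <- 0
        J[, engine$nEdge + ki] <-
          as.numeric(Ainv %*% col) * (-(1 + exp(lk) * x[k]))
      }
      jacRows[[ci]] <- J[engine$readoutNode, , drop = FALSE][cond$keep, ,
                                                            drop = FALSE]
    }
  }
  out <- list(sim = simRows)
  if (jacobian) out$jac <- do.call(rbind, jacRows)
  out
}

# Indices (condition, readout column) of the cells engineEval returns,
# condition-major, masking removed.
engineCellIndex <- function(engine) {
  do.call(rbind, lapply(seq_along(engine$conditions), function(ci) {
    keep <- engine$conditions[[ci]]$keep
    cbind(row = rep.int(ci, length(keep)), col = keep)
  }))
}

# Jacobian of retained responses w.r.t. log-magnitude raw parameters at a
# random generic point; used for numerical identifiability ranks.
engineLogJacobian <- function(engine, theta) {
  ev <- engineEval(engine, theta, jacobian = TRUE)
  if (is.null(ev)) return(NULL)
  sweep(ev$jac, 2L, theta, `*`)
}

sampleGenericPoint <- function(engine) {
  th <- 10^stats::runif(engine$nEdge, -1, 1) *
    sample(c(-1, 1), engine$nEdge, replace = TRUE)
  c(th, stats::runif(length(engine$inhNodes), -3, -0.1))
}
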