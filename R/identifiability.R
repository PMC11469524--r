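#' Raw parameter names of a network/design pair
#'
#' Edge coefficients `r_<target>_<source>` in edge order, followed by one
#' inhibitor strength `l_<node>` per node inhibited in any condition.
#'
#' @param network a [SignalingNetwork-class].
#' @param design a [PerturbationDesign-class].
#' @return character vector of parameter names.
#' @export
mraParameters <- function(network, design) {
  inhNodes <- intersect(network@nodes, unique(unlist(design@inhibited)))
  c(edgeNames(network), if (length(inhNodes)) paste0("l_", inhNodes))
}

# Extended symbol list: an inhibitor acts twice, as a basal offset l_k and
# as a dampening factor exp(l_k) on propagated signals. Both actions leave
# distinct monomial fingerprints, so they are tracked as separate symbols.
extendedParameters <- function(network, design) {
  inhNodes <- intersect(network@nodes, unique(unlist(design@inhibited)))
  c(edgeNames(network),
    if (length(inhNodes)) paste0("l_", inhNodes),
    if (length(inhNodes)) paste0("exp(l_", inhNodes, ")"))
}

#' Exponent matrix of the response monomials
#'
#' Enumerates every multiplicative coefficient monomial appearing in any
#' simple perturbation-to-readout path of any condition. A stimulated node
#' contributes the product of edge coefficients along each simple path to
#' each measured (non-masked) readout, times a dampening factor
#' `exp(l_k)` for every inhibited node transmitting along the path. An
#' inhibited node additionally contributes its basal-offset monomials:
#' the inhibitor strength `l_k` times the edge products of its outgoing
#' simple paths (dampened by other inhibitors en route). Rows are
#' deduplicated. Responses through feedback loops are rational rather than
#' polynomial functions; the enumeration deliberately covers simple paths
#' only and [verifyRank()] guards against loop-induced extra
#' identifiability.
#'
#' @param network a [SignalingNetwork-class].
#' @param design a [PerturbationDesign-class].
#' @param warn warn about measured readouts unreachable from every
#'   perturbation (their responses are structurally zero).
#' @return integer matrix, one row per distinct monomial, columns named by
#'   the edge coefficients, inhibitor strengths and dampening factors.
#' @export
buildMonomialMatrix <- function(network, design, warn = TRUE) {
  params <- extendedParameters(network, design)
  g <- asIgraph(network)
  eKey <- paste(network@from, network@to, sep = "\r")
  pathCache <- new.env(parent = emptyenv())
  # simple paths u -> m as lists of node-name vectors
  simplePaths <- function(u, m) {
    key <- paste(u, m, sep = "\r")
    if (!is.null(pathCache[[key]])) return(pathCache[[key]])
    vs <- igraph::all_simple_paths(g, from = u, to = m, mode = "out")
    out <- lapply(vs, names)
    pathCache[[key]] <- out
    out
  }
  monomial <- function(nodesOnPath, lFactor, dampened) {
    e <- integer(length(params))
    k <- length(nodesOnPath)
    idx <- match(paste(nodesOnPath[-k], nodesOnPath[-1], sep = "\r"), eKey)
    e[seq_along(eKey)] <- tabulate(idx, nbins = length(eKey))
    if (!is.na(lFactor)) {
      li <- match(paste0("l_", lFactor), params)
      e[li] <- e[li] + 1L
    }
    for (d in dampened) {
      di <- match(paste0("exp(l_", d, ")"), params)
      e[di] <- e[di] + 1L
    }
    e
  }
  masked <- is.na(applyMasking(
    matrix(0, length(design@conditionIds), length(design@measured),
           dimnames = list(design@conditionIds, names(design@measured))),
    design))
  out <- list()
  reachable <- logical(length(design@measured))
  for (ci in seq_along(design@conditionIds)) {
    inhSet <- design@inhibited[[ci]]
    for (w in which(!masked[ci, ])) {
      m <- design@measured[[w]]
      for (s in design@stimulated[[ci]]) {
        if (s == m) { reachable[w] <- TRUE; next }
        for (pp in simplePaths(s, m)) {
          reachable[w] <- TRUE
          transmitting <- pp[-length(pp)]
          out <- c(out, list(monomial(pp, NA,
                                      intersect(inhSet, transmitting))))
        }
      }
      for (k in inhSet) {
        if (k == m) next
        for (pp in simplePaths(k, m)) {
          reachable[w] <- TRUE
          # the basal offset l_k is not dampened by k itself, only by
          # other inhibited nodes transmitting downstream
          transmitting <- pp[-c(1L, length(pp))]
          out <- c(out, list(monomial(pp, k,
                                      intersect(inhSet, transmitting))))
        }
      }
    }
  }
  M <- if (length(out)) unique(do.call(rbind, out))
  else matrix(0L, 0L, length(params))
  colnames(M) <- params
  if (warn && any(!reachable))
    warning("readout(s) unreachable from every perturbation: ",
            paste(names(design@measured)[!reachable], collapse = ", "))
  M
}

# Exact integer row reduction (fraction-free): reduce v against an echelon
# basis; all intermediates stay integers.
.gcdVec <- function(v) {
  v <- abs(v[v != 0])
  if (!length(v)) return(1)
  Reduce(function(a, b) { while (b) { t <- a %% b; a <- b; b <- t }; a }, v)
}

.reduceAgainst <- function(v, basis) {
  for (b in basis) {
    j <- b$pivot
    if (v[j] != 0) {
      v <- v * b$vec[j] - b$vec * v[j]
      g <- .gcdVec(v)
      if (g > 1) v <- v / g
    }
  }
  v
}

# Collapse the two symbol columns of each inhibitor (l_k and exp(l_k)) into
# one column per underlying parameter: the gradient direction of a monomial
# l^b exp(l)^c w.r.t. l is b/l + c, so with integer substitutes u ~ 1/l the
# combined column b*u + c has the generic rank of the true Jacobian
# (Schwartz-Zippel argument). `u` is a fixed deterministic odd-prime vector.
combineInhibitorColumns <- function(M, params) {
  isE <- startsWith(params, "exp(l_")
  isL <- startsWith(params, "l_")
  base <- params[!isE]
  C <- M[, !isE, drop = FALSE]
  if (any(isE)) {
    primes <- c(3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L, 41L,
                43L, 47L, 53L, 59L, 61L, 67L, 71L, 73L, 79L, 83L, 89L, 97L)
    lNames <- params[isL]
    u <- rep_len(primes, length(lNames))
    for (i in seq_along(lNames)) {
      eCol <- paste0("exp(", lNames[i], ")")
      C[, lNames[i]] <- M[, lNames[i]] * u[i] + M[, eCol]
    }
  }
  colnames(C) <- base
  C
}

#' Reduce response monomials to identifiable coefficient paths
#'
#' Selects a maximal set of monomials whose gradients with respect to the
#' underlying parameters are linearly independent, by exact (integer,
#' fraction-free) Gaussian elimination, preferring the shortest monomials
#' as pivots so path names stay human-readable. Each selected monomial
#' becomes a named coefficient path; the number of paths equals the generic
#' rank of the monomial system.
#'
#' @param M integer exponent matrix from [buildMonomialMatrix()].
#' @param network the network, used for canonical factor ordering
#'   (topological order of the factor's source node, then lexicographic).
#' @return a [CoefficientPaths-class] with one row per identifiable path.
#' @export
reduceToIdentifiablePaths <- function(M, network = NULL) {
  params <- colnames(M)
  if (is.null(params)) params <- paste0("p", seq_len(ncol(M)))
  if (!nrow(M)) {
    return(new("CoefficientPaths", parameters = params,
               exponents = matrix(0L, 0L, length(params),
                                  dimnames = list(NULL, params)),
               values = numeric()))
  }
  C <- combineInhibitorColumns(M, params)
  ord <- order(rowSums(M != 0), apply(M, 1L, function(e)
    pathNameFromExponents(e, params, network)))
  basis <- list()
  chosen <- integer()
  for (i in ord) {
    v <- .reduceAgainst(C[i, ], basis)
    if (any(v != 0)) {
      piv <- which(v != 0)[1]
      if (v[piv] < 0) v <- -v
      basis[[length(basis) + 1L]] <- list(vec = v, pivot = piv)
      chosen <- c(chosen, i)
    }
  }
  exps <- M[chosen, , drop = FALSE]
  storage.mode(exps) <- "integer"
  rownames(exps) <- apply(exps, 1L, pathNameFromExponents, params = params,
                          network = network)
  colnames(exps) <- params
  new("CoefficientPaths", parameters = params, exponents = exps,
      values = rep(NA_real_, nrow(exps)))
}

# Canonical path name: factors ordered by topological position of their
# source node (ties broken lexicographically), joined by '*'; an exponent
# above 1 is rendered with '^'.
pathNameFromExponents <- function(e, params, network = NULL) {
  nz <- which(e != 0)
  if (!length(nz)) return("1")
  facs <- params[nz]
  src <- ifelse(startsWith(facs, "exp(l_"),
                sub("\\)$", "", sub("^exp\\(l_", "", facs)),
                ifelse(startsWith(facs, "l_"), sub("^l_", "", facs),
                       sub("^r_[^_]*_", "", facs)))
  pos <- rep(0L, length(facs))
  if (!is.null(network)) {
    topo <- topologicalOrder(network)
    pos <- match(src, topo)
    pos[is.na(pos)] <- length(topo) + 1L
  }
  o <- order(pos, facs)
  rendered <- ifelse(e[nz] == 1L, facs, paste0(facs, "^", e[nz]))
  paste(rendered[o], collapse = "*")
}

topologicalOrder <- function(network) {
  g <- asIgraph(network)
  topo <- suppressWarnings(tryCatch(
    names(igraph::topo_sort(g, mode = "out")), error = function(e) NULL))
  unique(c(topo, network@nodes))
}

#' Identifiable coefficient paths of a network/design pair
#'
#' Convenience wrapper: [buildMonomialMatrix()] followed by
#' [reduceToIdentifiablePaths()].
#'
#' @inheritParams buildMonomialMatrix
#' @return a [CoefficientPaths-class].
#' @export
coefficientPaths <- function(network, design, warn = TRUE) {
  reduceToIdentifiablePaths(buildMonomialMatrix(network, design, warn = warn),
                            network = network)
}

#' Numerical rank of the response map
#'
#' Rank of the Jacobian of all simulated (non-masked) responses with respect
#' to the log-magnitude raw parameters, evaluated at random generic
#' parameter points. This is the number of identifiable parameter
#' combinations including any extra identifiability contributed by feedback
#' loops, and is the authoritative degrees-of-freedom count for the reduced
#' chi-square and likelihood-ratio tests.
#'
#' @param network a [SignalingNetwork-class].
#' @param design a [PerturbationDesign-class].
#' @param free optional character vector restricting to a subset of raw
#'   parameters (columns); defaults to all.
#' @param seeds integer seeds, one generic point per seed.
#' @param tol singular values below `tol` times the largest are treated as
#'   zero.
#' @return integer, the maximal numerical rank across the sampled points.
#' @export
numericalRank <- function(network, design, free = NULL,
                          seeds = c(101L, 202L), tol = 1e-8) {
  engine <- makeEngine(network, design)
  cols <- if (is.null(free)) seq_len(engine$nParam)
  else match(free, engine$paramNames)
  if (anyNA(cols)) stop("unknown parameter in 'free'")
  ranks <- vapply(seeds, function(s) {
    set.seed(s)
    J <- NULL
    for (try in 1:20) {
      J <- engineLogJacobian(engine, sampleGenericPoint(engine))
      if (!is.null(J)) break
    }
    if (is.null(J)) stop("could not sample a non-singular parameter point")
    J <- J[, cols, drop = FALSE]
    if (!nrow(J) || !ncol(J)) return(0L)
    d <- svd(J, nu = 0, nv = 0)$d
    sum(d > tol * d[1])
  }, integer(1))
  max(ranks)
}

#' Verify the symbolic path count against the numerical Jacobian rank
#'
#' Cross-checks the coefficient-path analysis: at two or more random
#' parameter points the numerical rank of the response Jacobian must equal
#' the number of symbolic paths. A disagreement (possible in networks with
#' feedback loops, whose responses are not polynomial in the coefficients)
#' is reported with a diagnostic; the numerical rank is then authoritative.
#'
#' @param network a [SignalingNetwork-class].
#' @param design a [PerturbationDesign-class].
#' @param paths a [CoefficientPaths-class] for this pair.
#' @param seeds integer seeds (one random point each; at least 2 are used).
#' @param tol rank tolerance, see [numericalRank()].
#' @return `TRUE` if every point agrees; otherwise `FALSE` with a
#'   `diagnostic` attribute listing the discrepant seeds and ranks.
#' @export
verifyRank <- function(network, design, paths, seeds = c(101L, 202L),
                       tol = 1e-8) {
  if (length(seeds) < 2) seeds <- c(seeds, seeds + 1L)
  expected <- nrow(paths@exponents)
  ranks <- vapply(seeds, function(s)
    numericalRank(network, design, seeds = s, tol = tol), integer(1))
  ok <- all(ranks == expected)
  if (!ok) {
    bad <- seeds[ranks != expected]
    attr(ok, "diagnostic") <- paste0(
      "rank disagreement at seed(s) ", paste(bad, collapse = ", "),
      ": numerical rank ", paste(ranks[ranks != expected], collapse = ", "),
      " vs ", expected, " symbolic paths")
  }
  ok
}
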