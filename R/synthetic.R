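#' Packaged B-cell-receptor literature network and perturbation design
#'
#' Returns the packaged literature-style BCR signaling network (20 nodes,
#' 25 edges, stimulus node BCR) together with the perturbation design of
#' the emulated study: 8 kinase inhibitors (JNK, MEK, PI3K, Btk, AKT,
#' mTORC1, IKK, p38), each applied with and without anti-IgM stimulation,
#' plus stimulation alone — 17 conditions — read out on 14
#' phospho-proteins. The AKT and Btk inhibitors act on the phospho-signal
#' of their own targets, so the (AKT inhibitor, AKT readout) and
#' (Btk inhibitor, Btk readout) cells are masked.
#'
#' The `"dlbcl"` variant emulates chronically active BCR signaling: no
#' stimulated condition, and the receptor-proximal stimulus node is removed
#' from the network.
#'
#' The literature topology is a representative encoding of the curated
#' starting network; it is packaged as an editable edge-list CSV
#' (`system.file("extdata", "bcr_literature_network.csv", package =
#' "mranet")`), not as an authoritative reconstruction.
#'
#' @param variant `"bcr"` (default, stimulated Burkitt-lymphoma design) or
#'   `"dlbcl"` (unstimulated chronic-signaling design).
#' @return list with elements `network` ([SignalingNetwork-class]) and
#'   `design` ([PerturbationDesign-class]).
#' @examples
#' fx <- bcrDesignFixture()
#' length(measuredReadouts(fx$design))   # 14
#' @export
bcrDesignFixture <- function(variant = c("bcr", "dlbcl")) {
  variant <- match.arg(variant)
  file <- system.file("extdata", "bcr_literature_network.csv",
                      package = "mranet")
  network <- loadNetwork(file)
  inhTargets <- c(JNKi = "JNK", MEKi = "MEK", PI3Ki = "PI3K", Btki = "Btk",
                  AKTi = "AKT", mTORi = "mTORC1", IKKi = "IKK",
                  p38i = "p38")
  readouts <- c("SYK", "ZAP70", "Btk", "AKT", "RPS6", "BAD", "ERK", "MEK",
                "p90RSK", "GSK3", "NFkB", "HSP27", "JNK", "cJun")
  measured <- stats::setNames(readouts, readouts)
  masked <- data.frame(target = c("AKT", "Btk"),
                       readout = c("AKT", "Btk"),
                       stringsAsFactors = FALSE)
  if (variant == "bcr") {
    ids <- c("aIgM", names(inhTargets), paste0(names(inhTargets), "+aIgM"))
    stimulated <- c(list("BCR"), rep(list(character()), 8L),
                    rep(list("BCR"), 8L))
    inhibited <- c(list(character()), as.list(unname(inhTargets)),
                   as.list(unname(inhTargets)))
  } else {
    keep <- network@from != "BCR" & network@to != "BCR"
    network <- signalingNetwork(
      data.frame(source = network@from[keep], target = network@to[keep],
                 stringsAsFactors = FALSE),
      stimuli = character(),
      nodes = setdiff(network@nodes, "BCR"))
    ids <- names(inhTargets)
    stimulated <- rep(list(character()), 8L)
    inhibited <- as.list(unname(inhTargets))
  }
  design <- perturbationDesign(ids, stimulated, inhibited, measured, masked)
  list(network = network, design = design)
}

#' Sample a ground-truth MRA model
#'
#' Draws edge coefficients with log-uniform magnitude and inhibitor
#' strengths uniform in their range, then verifies that every design
#' condition yields a well-conditioned, bounded steady state (feedback
#' products can otherwise make the linear system unstable); unstable draws
#' are resampled a bounded number of times.
#'
#' @param network a [SignalingNetwork-class].
#' @param design a [PerturbationDesign-class].
#' @param magnitudeRange log-uniform magnitude range for edge coefficients.
#' @param signPolicy `"positive"` (all activating except `negativeEdges`)
#'   or `"random"` (each edge sign drawn fairly).
#' @param negativeEdges data.frame with columns `source`, `target` listing
#'   edges forced negative under the `"positive"` policy (e.g. known
#'   negative feedback).
#' @param inhibitorRange uniform range for inhibitor strengths (negative).
#' @param seed mandatory integer seed.
#' @param maxTries resampling attempts before giving up.
#' @param maxResponse largest admissible |log2 fold change| in any
#'   condition; larger draws are considered unstable and resampled.
#' @return an [MRAModel-class] with values set.
#' @export
generateGroundTruth <- function(network, design,
                                magnitudeRange = c(0.3, 3),
                                signPolicy = c("positive", "random"),
                                negativeEdges = NULL,
                                inhibitorRange = c(-3, -0.5),
                                seed, maxTries = 20L, maxResponse = 30) {
  signPolicy <- match.arg(signPolicy)
  if (missing(seed)) stop("seed is mandatory for ground-truth generation")
  stopifnot(diff(range(magnitudeRange)) >= 0, all(inhibitorRange < 0))
  set.seed(seed)
  engine <- makeEngine(network, design)
  nE <- engine$nEdge
  nL <- length(engine$inhNodes)
  en <- edgeNames(network)
  signs <- rep(1, nE)
  if (signPolicy == "random") {
    # drawn fresh on each attempt below
  } else if (!is.null(negativeEdges)) {
    neg <- paste0("r_", negativeEdges$target, "_", negativeEdges$source)
    signs[en %in% neg] <- -1
  }
  lmag <- log10(magnitudeRange)
  for (try in seq_len(maxTries)) {
    s <- if (signPolicy == "random")
      sample(c(-1, 1), nE, replace = TRUE) else signs
    coefs <- s * 10^stats::runif(nE, lmag[1], lmag[2])
    lv <- stats::runif(nL, inhibitorRange[1], inhibitorRange[2])
    theta <- c(coefs, lv)
    ev <- engineEval(engine, theta)
    if (!is.null(ev) &&
        max(abs(unlist(ev$sim, use.names = FALSE)), 0) <= maxResponse) {
      names(coefs) <- en
      lv <- stats::setNames(lv, engine$inhNodes)
      return(mraModel(network, design, coefs, lv,
                      paths = coefficientPaths(network, design,
                                               warn = FALSE)))
    }
  }
  stop("no stable ground-truth model found in ", maxTries, " draws; ",
       "narrow the magnitude range")
}

#' Generate a noisy perturbation dataset from a ground-truth model
#'
#' Simulates the noiseless steady-state responses, draws `nReplicates`
#' independent Gaussian replicates per cell in log2 space, and returns the
#' replicate mean as the value and the standard error of the mean as the
#' error — exercising SEM-based weighting exactly as a replicated
#' bead-based ELISA experiment would. Masked cells are generated and then
#' flagged missing.
#'
#' @param model an [MRAModel-class] ground truth.
#' @param design a [PerturbationDesign-class]; defaults to the model's own.
#' @param noiseSd replicate noise standard deviation in log2 units; a
#'   scalar, or a named vector with one entry per readout
#'   (antibody-wise noise).
#' @param nReplicates replicates per cell (at least 2 when `errorType` is
#'   `"sem"`).
#' @param seed mandatory integer seed.
#' @param errorType `"sem"` stores the empirical standard error of the
#'   mean; `"known"` stores the true `noiseSd / sqrt(nReplicates)`, for
#'   calibration studies where the weights must match the noise exactly.
#' @return a [PerturbationDataset-class].
#' @export
generateDataset <- function(model, design = model@design, noiseSd = 0.2,
                            nReplicates = 3L, seed,
                            errorType = c("sem", "known")) {
  errorType <- match.arg(errorType)
  if (missing(seed)) stop("seed is mandatory for dataset generation")
  nReplicates <- as.integer(nReplicates)
  if (errorType == "sem" && nReplicates < 2L)
    stop("at least 2 replicates are required to estimate errors")
  readouts <- names(design@measured)
  if (length(noiseSd) == 1L)
    noiseSd <- stats::setNames(rep(noiseSd, length(readouts)), readouts)
  noiseSd <- noiseSd[readouts]
  if (anyNA(noiseSd)) stop("noiseSd missing for some readouts")
  unmaskedDesign <- design
  unmaskedDesign@masked <- data.frame(target = character(),
                                      readout = character())
  sim <- simulateDataset(model, unmaskedDesign)
  set.seed(seed)
  nC <- nrow(sim)
  vals <- errs <- matrix(NA_real_, nC, length(readouts),
                         dimnames = dimnames(sim))
  for (j in seq_along(readouts)) {
    reps <- matrix(stats::rnorm(nC * nReplicates, mean = sim[, j],
                                sd = noiseSd[j]),
                   nC, nReplicates)
    vals[, j] <- rowMeans(reps)
    errs[, j] <- if (errorType == "sem")
      apply(reps, 1L, stats::sd) / sqrt(nReplicates)
    else noiseSd[j] / sqrt(nReplicates)
    # keep errors valid in the noiseless limit
    errs[, j] <- pmax(errs[, j], 1e-12)
  }
  perturbationDataset(vals, errs, design = design,
                      nReplicates = nReplicates)
}
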