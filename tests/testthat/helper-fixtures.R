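# Shared fixtures: all built in code, no stored data.

# Minimal stimulated/inhibited chain: S -> A -> B.
chainNetwork <- function() {
  signalingNetwork(data.frame(source = c("S", "A"), target = c("A", "B")),
                   stimuli = "S")
}

chainDesign <- function() {
  perturbationDesign(
    c("s", "iA", "s+iA"),
    stimulated = list("S", character(), "S"),
    inhibited = list(character(), "A", "A"),
    measured = c(A = "A", B = "B"))
}

# Six-node network with a feedback loop: S -> A -> B -> C, A -> D, B -> E,
# C -> A. Used for recovery and adaptation studies.
net6 <- function() {
  signalingNetwork(data.frame(
    source = c("S", "A", "B", "A", "B", "C"),
    target = c("A", "B", "C", "D", "E", "A")), stimuli = "S")
}

# Fully perturbed design on the five non-stimulus nodes; `which` selects the
# stimulated (training) conditions, the unstimulated inhibitor conditions
# (held-out), or both.
design6 <- function(which = c("full", "train", "heldout")) {
  which <- match.arg(which)
  nodes <- c("A", "B", "C", "D", "E")
  meas <- stats::setNames(nodes, nodes)
  train <- list(ids = c("s", paste0("s+i", nodes)),
                stim = rep(list("S"), 6),
                inh = c(list(character()), as.list(nodes)))
  held <- list(ids = paste0("i", nodes),
               stim = rep(list(character()), 5),
               inh = as.list(nodes))
  sel <- switch(which,
                train = train,
                heldout = held,
                full = list(ids = c(train$ids, held$ids),
                            stim = c(train$stim, held$stim),
                            inh = c(train$inh, held$inh)))
  perturbationDesign(sel$ids, sel$stim, sel$inh, meas)
}

# Split a dataset generated on design6("full") into train and held-out parts.
split6 <- function(data) {
  tr <- design6("train")
  hd <- design6("heldout")
  list(train = perturbationDataset(data@values[tr@conditionIds, ],
                                   data@errors[tr@conditionIds, ],
                                   design = tr,
                                   nReplicates = data@nReplicates),
       heldout = perturbationDataset(data@values[hd@conditionIds, ],
                                     data@errors[hd@conditionIds, ],
                                     design = hd,
                                     nReplicates = data@nReplicates),
       trainDesign = tr, heldoutDesign = hd)
}

# Random DAG on n nodes (node 1 is the stimulated root), edge probability p,
# plus a design that stimulates the root and inhibits/measures a node subset.
# Responses of DAGs are pure monomials, so the symbolic path count must
# match the numerical rank exactly.
randomDag <- function(n, p = 0.4, seed) {
  set.seed(seed)
  nodes <- c("S", paste0("N", seq_len(n - 1)))
  from <- character()
  to <- character()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) {
        from <- c(from, nodes[i])
        to <- c(to, nodes[j])
      }
    }
  }
  if (!length(from)) {
    from <- nodes[1]
    to <- nodes[2]
  }
  signalingNetwork(data.frame(source = from, target = to), stimuli = "S")
}

# Random tree rooted in the stimulus: every node has exactly one parent, so
# every perturbation-to-readout response is a single monomial (no parallel
# paths) and the path enumeration is exact.
randomTree <- function(n, seed) {
  set.seed(seed)
  nodes <- c("S", paste0("N", seq_len(n - 1)))
  parent <- vapply(2:n, function(i) sample(seq_len(i - 1), 1), integer(1))
  signalingNetwork(data.frame(source = nodes[parent], target = nodes[-1]),
                   stimuli = "S")
}

# Study-shaped design: stimulation alone, each inhibitor alone, and each
# inhibitor combined with stimulation (the shape of the emulated
# experiment); a random node subset is inhibited and measured.
studyDesign <- function(network, seed, pInhibit = 0.6, pMeasure = 0.8) {
  set.seed(seed)
  others <- setdiff(networkNodes(network), stimulusNodes(network))
  inh <- others[stats::runif(length(others)) < pInhibit]
  meas <- others[stats::runif(length(others)) < pMeasure]
  if (!length(meas)) meas <- others[length(others)]
  ids <- c("s", if (length(inh)) paste0("i", inh),
           if (length(inh)) paste0("s+i", inh))
  perturbationDesign(
    ids,
    stimulated = c(list("S"), rep(list(character()), length(inh)),
                   rep(list("S"), length(inh))),
    inhibited = c(list(character()), as.list(inh), as.list(inh)),
    measured = stats::setNames(meas, meas))
}

randomDesign <- function(network, seed, pInhibit = 0.6, pMeasure = 0.8) {
  set.seed(seed)
  others <- setdiff(network@nodes, network@stimuli)
  inh <- others[stats::runif(length(others)) < pInhibit]
  meas <- others[stats::runif(length(others)) < pMeasure]
  if (!length(meas)) meas <- others[length(others)]
  ids <- c("s", if (length(inh)) paste0("s+i", inh))
  perturbationDesign(
    ids,
    stimulated = rep(list(network@stimuli), length(ids)),
    inhibited = c(list(character()), as.list(inh)),
    measured = stats::setNames(meas, meas))
}

# Quiet small-problem fit with economical restarts.
quickFit <- function(network, design, data, nStarts = 20L, seed = 1L, ...) {
  suppressWarnings(fitModel(network, design, data, nStarts = nStarts,
                            seed = seed, ...))
}

edgeKey <- function(network) {
  e <- networkEdges(network)
  sort(paste(e$source, e$target, sep = "->"))
}
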