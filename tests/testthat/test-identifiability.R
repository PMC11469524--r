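test_that("an unmeasured intermediate collapses a chain into one path", {
  net <- signalingNetwork(
    data.frame(source = c("A", "H"), target = c("H", "B")), stimuli = "A")
  des <- perturbationDesign("s", stimulated = list("A"),
                            inhibited = list(character()),
                            measured = c(A = "A", B = "B"))
  M <- buildMonomialMatrix(net, des)
  expect_identical(nrow(M), 1L)
  paths <- reduceToIdentifiablePaths(M, net)
  expect_identical(pathNames(paths), "r_H_A*r_B_H")
  expect_true(verifyRank(net, des, paths))
})

test_that("a single measured edge is its own path", {
  net <- chainNetwork()
  des <- perturbationDesign("s", stimulated = list("S"),
                            inhibited = list(character()),
                            measured = c(A = "A", B = "B"))
  paths <- coefficientPaths(net, des)
  expect_setequal(pathNames(paths), c("r_A_S", "r_A_S*r_B_A"))
})

test_that("already independent exponent rows each become a path", {
  M <- rbind(c(1L, 1L, 0L), c(0L, 0L, 1L))
  colnames(M) <- c("r_B_A", "r_C_B", "r_D_C")
  paths <- reduceToIdentifiablePaths(M)
  expect_identical(nrow(paths@exponents), 2L)
  M0 <- matrix(0L, 0L, 3L,
               dimnames = list(NULL, colnames(M)))
  expect_identical(nrow(reduceToIdentifiablePaths(M0)@exponents), 0L)
})

test_that("path count is invariant to node and edge ordering", {
  edges <- data.frame(source = c("S", "A", "B", "A"),
                      target = c("A", "B", "C", "C"))
  des <- function(net) perturbationDesign(
    c("s", "s+iA"), stimulated = rep(list("S"), 2),
    inhibited = list(character(), "A"),
    measured = c(B = "B", C = "C"))
  n1 <- signalingNetwork(edges, stimuli = "S")
  n2 <- signalingNetwork(edges[c(3, 1, 4, 2), ], stimuli = "S",
                         nodes = rev(networkNodes(n1)))
  p1 <- coefficientPaths(n1, des(n1))
  p2 <- coefficientPaths(n2, des(n2))
  expect_identical(nrow(p1@exponents), nrow(p2@exponents))
  expect_setequal(pathNames(p1), pathNames(p2))
})

test_that("path count is bounded by the raw parameter count, with equality
           under full observation", {
  for (s in 1:10) {
    net <- randomDag(5, seed = s)
    des <- randomDesign(net, seed = 100 + s)
    paths <- coefficientPaths(net, des, warn = FALSE)
    expect_lte(nrow(paths@exponents), length(mraParameters(net, des)))
  }
  # chain with all nodes measured and all transmitting nodes inhibited:
  # every raw parameter is identifiable (an inhibitor on a terminal leaf
  # would act on nothing, so leaves are not inhibited)
  net <- signalingNetwork(data.frame(
    source = c("S", "N1", "N2", "N3"),
    target = c("N1", "N2", "N3", "N4")), stimuli = "S")
  inh <- c("N1", "N2", "N3")
  des <- perturbationDesign(
    c("s", paste0("i", inh), paste0("s+i", inh)),
    stimulated = c(list("S"), rep(list(character()), 3),
                   rep(list("S"), 3)),
    inhibited = c(list(character()), as.list(inh), as.list(inh)),
    measured = stats::setNames(c("N1", "N2", "N3", "N4"),
                               c("N1", "N2", "N3", "N4")))
  paths <- coefficientPaths(net, des, warn = FALSE)
  expect_identical(nrow(paths@exponents),
                   length(mraParameters(net, des)))
  expect_true(verifyRank(net, des, paths))
})

test_that("symbolic path count equals numerical Jacobian rank on random
           tree networks under study-shaped designs", {
  # On trees every perturbation-to-readout response decomposes into
  # separable monomials, so the path enumeration is exact; networks with
  # parallel paths or loops are covered by the numerical-rank-authoritative
  # contract instead.
  for (s in 1:50) {
    net <- randomTree(sample(4:6, 1), seed = 2000 + s)
    des <- studyDesign(net, seed = 3000 + s)
    paths <- coefficientPaths(net, des, warn = FALSE)
    expect_true(verifyRank(net, des, paths),
                label = paste("seed", s))
  }
})

test_that("verifyRank detects a forced rank deficit and is seed-stable", {
  net <- net6()
  des <- design6("train")
  paths <- coefficientPaths(net, des)
  short <- paths
  short@exponents <- paths@exponents[-1, , drop = FALSE]
  short@values <- paths@values[-1]
  expect_false(isTRUE(verifyRank(net, des, short)))
  r1 <- numericalRank(net, des, seeds = c(1L, 2L, 3L))
  r2 <- numericalRank(net, des, seeds = c(7L, 8L, 9L))
  expect_identical(r1, r2)
})

test_that("coefficients of an unmeasured, unperturbed hub only appear in
           combination with its outgoing link", {
  fx <- bcrDesignFixture()
  net <- addEdge(fx$network, "p38", "RAF")   # the crosstalk candidate
  M <- buildMonomialMatrix(net, fx$design)
  intoRaf <- grep("^r_RAF_", colnames(M), value = TRUE)
  hasRafInput <- rowSums(M[, intoRaf, drop = FALSE] != 0) > 0
  expect_true(any(hasRafInput))
  expect_true(all(M[hasRafInput, "r_MEK_RAF"] != 0))
  # hence the crosstalk is identifiable only jointly with RAF -> MEK
  paths <- reduceToIdentifiablePaths(M, net)
  crossPaths <- grep("r_RAF_p38", pathNames(paths), value = TRUE)
  expect_true(length(crossPaths) > 0)
  expect_true(all(grepl("r_MEK_RAF", crossPaths)))
})

test_that("unreachable readouts are reported", {
  net <- signalingNetwork(
    data.frame(source = c("S", "A"), target = c("A", "B")), stimuli = "S")
  des <- perturbationDesign("s", stimulated = list("S"),
                            inhibited = list(character()),
                            measured = c(A = "A", B = "B", X = "X"))
  net2 <- signalingNetwork(
    data.frame(source = c("S", "A", "Y"), target = c("A", "B", "X")),
    stimuli = "S")
  expect_warning(buildMonomialMatrix(net2, des), "unreachable")
})
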