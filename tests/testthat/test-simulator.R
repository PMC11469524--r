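test_that("localToGlobal matches hand-inverted systems", {
  # A -> B with coefficient 2
  r <- rbind(c(-1, 0), c(2, -1))
  expect_equal(localToGlobal(r, c(1, 0)), c(1, 2), tolerance = 1e-12)
  # add feedback B -> A with coefficient -0.5
  r2 <- rbind(c(-1, -0.5), c(2, -1))
  expect_equal(localToGlobal(r2, c(1, 0)), c(0.5, 1), tolerance = 1e-12)
  # homogeneous case
  expect_equal(localToGlobal(r2, c(0, 0)), c(0, 0))
  # 3x3 chain, checked against an explicit inverse
  r3 <- rbind(c(-1, 0, 0), c(1.5, -1, 0), c(0, -0.8, -1))
  expect_equal(localToGlobal(r3, c(1, 0, 0)),
               as.numeric(-solve(r3) %*% c(1, 0, 0)), tolerance = 1e-12)
  expect_error(localToGlobal(matrix(0, 2, 2), c(1, 0)), "singular")
})

test_that("simulateCondition implements the twofold inhibitor action", {
  net <- chainNetwork()
  des <- chainDesign()
  m <- mraModel(net, des, coefficients = c(r_A_S = 1, r_B_A = 2),
                inhibitors = c(A = -1))
  # inhibitor alone: basal offset only
  x <- simulateCondition(m, stimulated = character(), inhibited = "A")
  expect_equal(unname(x[c("A", "B")]), c(0, -2), tolerance = 1e-12)
  # stimulus + inhibitor: dampened signal plus offset
  x2 <- simulateCondition(m, stimulated = "S", inhibited = "A")
  expect_equal(unname(x2["B"]), 2 * (exp(-1) - 1), tolerance = 1e-12)
  # stimulus alone
  x3 <- simulateCondition(m, stimulated = "S")
  expect_equal(unname(x3[c("A", "B")]), c(1, 2), tolerance = 1e-12)
})

test_that("simulateDataset projects, masks, and zeroes control conditions", {
  net <- chainNetwork()
  des <- chainDesign()
  m <- mraModel(net, des, coefficients = c(r_A_S = 1, r_B_A = 2),
                inhibitors = c(A = -1))
  sim <- simulateDataset(m)
  expect_equal(unname(sim),
               rbind(c(1, 2), c(0, -2), c(1, 2 * (exp(-1) - 1))),
               tolerance = 1e-6)
  # all-control design gives the zero matrix
  ctrl <- perturbationDesign("ctrl", stimulated = list(character()),
                             inhibited = list(character()),
                             measured = c(A = "A", B = "B"))
  expect_equal(unname(simulateDataset(m, ctrl)), matrix(0, 1, 2))
  # masking the inhibited readout
  desM <- perturbationDesign(
    conditionIds = des@conditionIds, stimulated = des@stimulated,
    inhibited = des@inhibited, measured = des@measured,
    masked = data.frame(target = "A", readout = "A"))
  simM <- simulateDataset(mraModel(net, desM,
                                   coefficients = c(r_A_S = 1, r_B_A = 2),
                                   inhibitors = c(A = -1)))
  expect_true(all(is.na(simM[c("iA", "s+iA"), "A"])))
  expect_false(anyNA(simM["s", ]))
})

test_that("responses are additive in stimulus entries for a fixed inhibitor
           set", {
  net <- signalingNetwork(
    data.frame(source = c("S1", "S2", "A"), target = c("A", "A", "B")),
    stimuli = c("S1", "S2"))
  des <- perturbationDesign("x", stimulated = list(character()),
                            inhibited = list("A"),
                            measured = c(A = "A", B = "B"))
  m <- mraModel(net, des,
                coefficients = c(r_A_S1 = 1.3, r_A_S2 = -0.7, r_B_A = 2),
                inhibitors = c(A = -0.5))
  x1 <- simulateCondition(m, stimulated = "S1", inhibited = "A")
  x2 <- simulateCondition(m, stimulated = "S2", inhibited = "A")
  x0 <- simulateCondition(m, stimulated = character(), inhibited = "A")
  x12 <- simulateCondition(m, stimulated = c("S1", "S2"), inhibited = "A")
  expect_equal(x12, x1 + x2 - x0, tolerance = 1e-12)
})

test_that("inhibitor strengths only act through outgoing coefficients of
           their target", {
  # symbolic: every monomial containing l_k contains an outgoing edge of k
  net <- net6()
  des <- design6("full")
  M <- buildMonomialMatrix(net, des)
  for (k in unique(unlist(des@inhibited))) {
    lcol <- paste0("l_", k)
    outEdges <- paste0("r_", net@to[net@from == k], "_", k)
    rows <- M[, lcol] != 0
    if (!any(rows) || !length(outEdges)) next
    expect_true(all(rowSums(M[rows, outEdges, drop = FALSE] != 0) > 0),
                label = paste("inhibitor", k))
  }
  # numeric: inhibiting a node without outgoing edges changes nothing
  m <- mraModel(chainNetwork(), chainDesign(),
                coefficients = c(r_A_S = 1, r_B_A = 2),
                inhibitors = c(B = -2))
  x <- simulateCondition(m, stimulated = "S", inhibited = "B")
  x0 <- simulateCondition(m, stimulated = "S")
  expect_equal(x, x0, tolerance = 1e-12)
})

test_that("simulateCondition agrees with fixed-point iteration on random
           contractive networks", {
  fixedPoint <- function(model, stimulated, inhibited) {
    nodes <- model@network@nodes
    r <- model@r
    p <- as.numeric(nodes %in% stimulated)
    x <- numeric(length(nodes))
    for (it in 1:10000) {
      xt <- x
      for (k in inhibited) {
        ki <- match(k, nodes)
        lk <- model@inhibitors[[k]]
        xt[ki] <- exp(lk) * x[ki] + lk
      }
      xNew <- numeric(length(nodes))
      for (j in seq_along(nodes)) {
        inc <- which(r[j, ] != 0 & seq_along(nodes) != j)
        xNew[j] <- sum(r[j, inc] * xt[inc]) + p[j]
      }
      if (max(abs(xNew - x)) < 1e-13) break
      x <- xNew
    }
    stats::setNames(x, nodes)
  }
  for (s in 1:50) {
    net <- randomDag(sample(4:6, 1), seed = 4000 + s)
    des <- randomDesign(net, seed = 5000 + s)
    truth <- generateGroundTruth(net, des, magnitudeRange = c(0.1, 0.5),
                                 seed = 6000 + s)
    i <- sample(length(des@conditionIds), 1)
    x <- simulateCondition(truth, condition = i)
    xf <- fixedPoint(truth, des@stimulated[[i]], des@inhibited[[i]])
    expect_equal(x, xf, tolerance = 1e-10, label = paste("seed", s))
  }
})
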