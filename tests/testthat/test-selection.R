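test_that("lrtPvalue matches chi-square quantiles and guards its
           preconditions", {
  expect_equal(lrtPvalue(10, 10, 1), 1)
  expect_equal(lrtPvalue(10 + 3.841, 10, 1), 0.05, tolerance = 1e-3)
  expect_equal(lrtPvalue(10 + 6.635, 10, 1), 0.01, tolerance = 1e-3)
  expect_equal(lrtPvalue(50, 10, 0), 1)
  expect_error(lrtPvalue(5, 10, 1), "fits better")
})

test_that("a truly absent edge is the top removal candidate; noiseless data
           yields no candidates", {
  startNet <- net6()
  des <- design6("train")
  trueNet <- removeEdge(startNet, "C", "A")
  truth <- generateGroundTruth(trueNet, des, seed = 51)
  dat <- generateDataset(truth, noiseSd = 0.1, seed = 52)
  fit <- quickFit(startNet, des, dat, nStarts = 20, seed = 3)
  rem <- suppressWarnings(scanRemovals(fit, dat, nStarts = 5, seed = 4))
  expect_true(rem$candidate[1])
  expect_identical(paste(rem$source[1], rem$target[1]), "C A")
  expect_gt(rem$p[1], 0.5)

  # noiseless data from the full model: every true edge is indispensable
  sim <- simulateDataset(truth, des)
  noiseless <- perturbationDataset(sim, matrix(0.05, nrow(sim), ncol(sim)),
                                   design = des)
  fitT <- quickFit(trueNet, des, noiseless, nStarts = 20, seed = 5,
                   errorFloor = 0.05)
  remT <- suppressWarnings(scanRemovals(fitT, noiseless, nStarts = 5,
                                        seed = 6))
  expect_false(any(remT$candidate))
})

test_that("a planted extra edge is the top addition candidate and stimulus
           targets are never proposed", {
  startNet <- signalingNetwork(data.frame(
    source = c("S", "A", "B", "A", "B"),
    target = c("A", "B", "C", "D", "E")), stimuli = "S")
  trueNet <- addEdge(startNet, "D", "C")
  des <- design6("full")
  truth <- generateGroundTruth(trueNet, des, seed = 61)
  dat <- generateDataset(truth, noiseSd = 0.1, seed = 62)
  fit <- quickFit(startNet, des, dat, nStarts = 20, seed = 7)
  add <- suppressWarnings(scanAdditions(fit, dat, nStarts = 5, seed = 8))
  expect_true(add$candidate[1])
  expect_identical(paste(add$source[1], add$target[1]), "D C")
  expect_false(any(add$target == "S"))
  expect_false(any(add$source == add$target))
})

test_that("consistencyCheck computes the error-reduction percentage", {
  # constructed case: model predictions reduce the null WSSR by 75%
  net <- chainNetwork()
  des <- perturbationDesign("s", stimulated = list("S"),
                            inhibited = list(character()),
                            measured = c(A = "A", B = "B"))
  m <- mraModel(net, des, coefficients = c(r_A_S = 1, r_B_A = 2))
  sim <- simulateDataset(m, des)                   # (1, 2)
  dat <- perturbationDataset(sim / 2, matrix(1, 1, 2), design = des)
  cc <- consistencyCheck(m, des, dat)
  expect_equal(cc$wssrNullmodel, 0.25 + 1)
  expect_equal(cc$wssrSimulation, 0.25 + 1)
  expect_equal(cc$errorReductionPct, 0)
  dat2 <- perturbationDataset(sim, matrix(1, 1, 2), design = des)
  expect_equal(consistencyCheck(m, des, dat2)$errorReductionPct, 100)
  # model worse than null: negative percentage
  dat3 <- perturbationDataset(-sim, matrix(1, 1, 2), design = des)
  expect_lt(consistencyCheck(m, des, dat3)$errorReductionPct, 0)
  # all-zero held-out data: null undefined
  dat0 <- perturbationDataset(sim * 0, matrix(1, 1, 2), design = des)
  expect_error(consistencyCheck(m, des, dat0), "zero")
})

test_that("adaptation accepts no change when the data came from the start
           structure without noise", {
  net <- net6()
  trainDes <- design6("train")
  heldDes <- design6("heldout")
  truth <- generateGroundTruth(net, design6("full"), seed = 71)
  sim <- simulateDataset(truth, design6("full"))
  dat <- perturbationDataset(sim, matrix(0.05, nrow(sim), ncol(sim)),
                             design = design6("full"))
  sp <- list(
    train = perturbationDataset(sim[1:6, ], matrix(0.05, 6, 5),
                                design = trainDes),
    held = perturbationDataset(sim[7:11, ], matrix(0.05, 5, 5),
                               design = heldDes))
  res <- suppressWarnings(adaptNetwork(net, trainDes, sp$train, heldDes,
                                       sp$held, seed = 2,
                                       nStartsFull = 20, nStartsScan = 5))
  expect_identical(sum(res$trace$accepted), 0L)
  expect_identical(edgeKey(res$fit@model@network), edgeKey(net))
})

test_that("adaptation without held-out data warns and disables the gate", {
  net <- net6()
  trainDes <- design6("train")
  truth <- generateGroundTruth(net, trainDes, seed = 81)
  dat <- generateDataset(truth, noiseSd = 0.1, seed = 82)
  expect_warning(
    adaptNetwork(net, trainDes, dat, seed = 3, nStartsFull = 15,
                 nStartsScan = 4, maxSteps = 2L),
    "consistency gate disabled")
})

test_that("accepted adaptation steps never worsen fit statistic or drop
           consistency beyond tolerance", {
  startNet <- signalingNetwork(data.frame(
    source = c("S", "A", "B", "A", "B"),
    target = c("A", "B", "C", "D", "E")), stimuli = "S")
  trueNet <- addEdge(removeEdge(startNet, "A", "D"), "D", "C")
  deltaPct <- 2
  truth <- generateGroundTruth(trueNet, design6("full"), seed = 91)
  full <- generateDataset(truth, noiseSd = 0.1, seed = 92)
  tr <- design6("train")
  hd <- design6("heldout")
  train <- perturbationDataset(full@values[1:6, ], full@errors[1:6, ],
                               design = tr)
  held <- perturbationDataset(full@values[7:11, ], full@errors[7:11, ],
                              design = hd)
  res <- suppressWarnings(adaptNetwork(startNet, tr, train, hd, held,
                                       deltaPct = deltaPct, seed = 4,
                                       nStartsFull = 20, nStartsScan = 5))
  acc <- res$trace[res$trace$accepted, ]
  expect_gt(nrow(acc), 0)
  expect_true(all(acc$xrAfter <= acc$xrBefore * (1 + 1e-6)))
  reds <- acc$errorReductionPct
  if (length(reds) > 1)
    expect_true(all(diff(reds) >= -deltaPct - 1e-9))
  # determinism: same inputs and seed give the identical trace
  res2 <- suppressWarnings(adaptNetwork(startNet, tr, train, hd, held,
                                        deltaPct = deltaPct, seed = 4,
                                        nStartsFull = 20, nStartsScan = 5))
  expect_identical(res$trace, res2$trace)
})
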