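test_that("profile CIs bracket the estimate and shrink as noise drops", {
  net <- chainNetwork()
  des <- chainDesign()
  truth <- generateGroundTruth(net, des, seed = 11)
  widths <- vapply(c(0.3, 0.03), function(sd) {
    dat <- generateDataset(truth, noiseSd = sd, seed = 12,
                           errorType = "known")
    fit <- quickFit(net, des, dat, nStarts = 10, seed = 1,
                    errorFloor = 1e-6)
    prof <- profileLikelihood(fit, dat, pathName = "r_A_S",
                              errorFloor = 1e-6)
    expect_false(prof$niLower || prof$niUpper)
    expect_lte(prof$lower, prof$estimate)
    expect_gte(prof$upper, prof$estimate)
    prof$upper - prof$lower
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("a structurally redundant path is non-identifiable in both
           directions", {
  # A -> B directly and via H, with only A and B measured: the data only
  # constrain the SUM r_B_A + r_H_A*r_B_H, so neither path is identifiable
  # on its own.
  net <- signalingNetwork(
    data.frame(source = c("A", "A", "H"), target = c("B", "H", "B")),
    stimuli = "A")
  des <- perturbationDesign("s", stimulated = list("A"),
                            inhibited = list(character()),
                            measured = c(A = "A", B = "B"))
  paths <- coefficientPaths(net, des)
  expect_identical(nrow(paths@exponents), 2L)       # symbolic count
  expect_identical(numericalRank(net, des), 1L)     # data constrain 1 combo
  truth <- generateGroundTruth(net, des, seed = 13)
  dat <- generateDataset(truth, noiseSd = 0.1, seed = 14)
  fit <- quickFit(net, des, dat, nStarts = 10, seed = 2)
  prof <- profileLikelihood(fit, dat, pathName = "r_B_A", bound = 100)
  expect_true(prof$niLower && prof$niUpper)
})

test_that("profiling an unknown or fully fixed path errors", {
  net <- chainNetwork()
  des <- chainDesign()
  truth <- generateGroundTruth(net, des, seed = 15)
  dat <- generateDataset(truth, noiseSd = 0.1, seed = 16)
  fit <- quickFit(net, des, dat, nStarts = 10, seed = 3)
  expect_error(profileLikelihood(fit, dat, pathName = "r_X_Y"),
               "unknown path")
})

test_that("compareModels flags a tenfold-changed path but not identical
           models", {
  net <- chainNetwork()
  des <- chainDesign()
  truth1 <- generateGroundTruth(net, des, seed = 17)
  # identical data, identical models: nothing is flagged
  dat <- generateDataset(truth1, noiseSd = 0.1, seed = 18)
  f1 <- quickFit(net, des, dat, nStarts = 10, seed = 4)
  cmpSame <- compareModels(list(a = f1, b = f1), list(dat, dat))
  expect_false(any(cmpSame$shared$significant))
  expect_identical(nrow(cmpSame$individual), 0L)

  # second model: one path value changed tenfold
  raw <- rawParameterValues(truth1)
  raw["r_A_S"] <- raw["r_A_S"] * 10
  truth2 <- mraModel(net, des, raw[c("r_A_S", "r_B_A")],
                     raw[startsWith(names(raw), "l_")])
  dat2 <- generateDataset(truth2, noiseSd = 0.1, seed = 19)
  f2 <- quickFit(net, des, dat2, nStarts = 10, seed = 4)
  cmp <- compareModels(list(a = f1, b = f2), list(dat, dat2))
  expect_true(cmp$shared$significant[cmp$shared$path == "r_A_S"])
})

test_that("inhibitor strengths can be fixed to a reference model or to the
           cross-model mean", {
  net <- chainNetwork()
  des <- chainDesign()
  truth <- generateGroundTruth(net, des, seed = 20)
  d1 <- generateDataset(truth, noiseSd = 0.1, seed = 21)
  d2 <- generateDataset(truth, noiseSd = 0.1, seed = 22)
  f1 <- quickFit(net, des, d1, nStarts = 8, seed = 1)
  f2 <- quickFit(net, des, d2, nStarts = 8, seed = 1)
  fits <- list(a = f1, b = f2)
  datas <- list(d1, d2)
  ref <- suppressWarnings(
    fixInhibitorsAcrossModels(fits, datas, reference = "a", nStarts = 4L))
  expect_equal(inhibitorStrengths(ref[[2]]), inhibitorStrengths(f1),
               tolerance = 1e-12)
  avg <- suppressWarnings(
    fixInhibitorsAcrossModels(fits, datas, nStarts = 4L))
  expect_equal(unname(inhibitorStrengths(avg[[1]])["A"]),
               mean(c(inhibitorStrengths(f1)["A"],
                      inhibitorStrengths(f2)["A"])),
               tolerance = 1e-12)
  expect_lt(avg[[1]]@nParameters, f1@nParameters)
})

test_that("transferring a structure onto its own training data reproduces
           the native fit", {
  net <- net6()
  des <- design6("train")
  truth <- generateGroundTruth(net, des, seed = 23)
  dat <- generateDataset(truth, noiseSd = 0.1, seed = 24)
  native <- quickFit(net, des, dat, nStarts = 15, seed = 5)
  transferred <- suppressWarnings(
    transferStructure(net, des, dat, nStarts = 15, seed = 5))
  expect_equal(transferred@wssrFit, native@wssrFit, tolerance = 1e-9)
  expect_identical(transferred@nParameters, native@nParameters)
  # a design naming unknown nodes is rejected
  badDes <- perturbationDesign("s", stimulated = list("S"),
                               inhibited = list(character()),
                               measured = c(Q = "Q"))
  expect_error(transferStructure(net, badDes, dat), "absent from")
})

test_that("a foreign structure fits data from its own family as well as the
           native one, and worse when misspecified", {
  netA <- net6()
  des <- design6("full")
  # "cell line B": same structure, different path values
  truthB <- generateGroundTruth(netA, des, seed = 25)
  datB <- generateDataset(truthB, noiseSd = 0.1, seed = 26,
                          errorType = "known")
  transferred <- quickFit(netA, des, datB, nStarts = 15, seed = 6)
  expect_lt(abs(transferred@reducedChiSquare - 1), 0.5)
  # data from a different structure fit distinctly worse
  netC <- addEdge(removeEdge(netA, "A", "D"), "D", "C")
  truthC <- generateGroundTruth(netC, des, seed = 27)
  datC <- generateDataset(truthC, noiseSd = 0.1, seed = 28,
                          errorType = "known")
  mis <- quickFit(netA, des, datC, nStarts = 15, seed = 6)
  expect_gt(mis@wssrFit, transferred@wssrFit)
})

test_that("binCoefficient partitions the line into the five states", {
  expect_identical(binCoefficient(1.5), "amplification")
  expect_identical(binCoefficient(-1.2), "enforced inhibition")
  expect_identical(binCoefficient(0), "no link")
  expect_identical(binCoefficient(0.3), "dampening to neutral relay")
  expect_identical(binCoefficient(-0.4), "attenuating to neutral inhibition")
  # boundaries fall to the neutral side
  expect_identical(binCoefficient(1), "dampening to neutral relay")
  expect_identical(binCoefficient(-1), "attenuating to neutral inhibition")
  # every value maps to exactly one state
  vals <- c(stats::rnorm(200, sd = 2), 0, 1, -1, 1e-12, -1e-12)
  bins <- binCoefficient(vals)
  expect_false(any(bins == ""))
  expect_identical(length(bins), length(vals))
})

test_that("composePath multiplies coefficients with sign propagation", {
  expect_equal(composePath(c(2, 0.5)), 1)
  expect_equal(composePath(c(-0.5, -2)), 1)
  expect_equal(composePath(3.7), 3.7)
})

test_that("consensusNetwork applies k-of-n voting with five-state bins", {
  net <- function(extra = NULL) {
    e <- data.frame(source = c("S", "A"), target = c("A", "B"))
    if (!is.null(extra)) e <- rbind(e, extra)
    signalingNetwork(e, stimuli = "S", nodes = c("S", "A", "B", "C"))
  }
  des <- perturbationDesign("s", stimulated = list("S"),
                            inhibited = list(character()),
                            measured = c(A = "A", B = "B", C = "C"))
  mk <- function(network, vals) mraModel(network, des, vals)
  withAC <- net(data.frame(source = "A", target = "C"))
  models <- list(
    m1 = mk(withAC, c(2, 0.5, 1.5)),
    m2 = mk(withAC, c(1.8, 0.4, 2.2)),
    m3 = mk(withAC, c(2.1, -0.3, 1.1)),
    m4 = mk(net(), c(0.5, 0.6)))
  cons <- consensusNetwork(models, k = 3)
  ce <- cons@edges
  # A -> C present in 3 of 4: kept; every edge in >= 3 models
  expect_true(any(ce$source == "A" & ce$target == "C"))
  expect_true(all(ce$votes >= 3))
  expect_identical(ce$consensus[ce$source == "A" & ce$target == "C"],
                   "amplification")
  # an edge in only 2 of 4 models is dropped
  withBC <- net(data.frame(source = "B", target = "C"))
  models2 <- list(mk(withBC, c(1, 1, 1)), mk(withBC, c(1, 1, 1)),
                  mk(net(), c(1, 1)), mk(net(), c(1, 1)))
  cons2 <- consensusNetwork(models2, k = 3)
  expect_false(any(cons2@edges$source == "B" & cons2@edges$target == "C"))
  # four identical models: consensus equals each member
  same <- list(mk(withAC, c(2, 0.5, 1.5)), mk(withAC, c(2, 0.5, 1.5)),
               mk(withAC, c(2, 0.5, 1.5)), mk(withAC, c(2, 0.5, 1.5)))
  cons3 <- consensusNetwork(same, k = 4)
  expect_identical(nrow(cons3@edges), 3L)
  # k = 1 is the union, k = n the intersection, k > n an error
  expect_identical(nrow(consensusNetwork(models2, k = 1)@edges), 3L)
  expect_identical(nrow(consensusNetwork(models2, k = 4)@edges), 2L)
  expect_error(consensusNetwork(models2, k = 5), "exceeds")
})
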