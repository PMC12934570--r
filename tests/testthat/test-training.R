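test_that("binary cross-entropy matches the elementwise formula", {
  expect_lt(bceLoss(c(1 - 1e-12, 1e-12), c(1, 0)), 1e-10)
  expect_equal(bceLoss(rep(0.5, 4), c(0, 1, 0, 1)), log(2), tolerance = 1e-12)
  set.seed(2)
  p <- runif(50, 0.01, 0.99); y <- rbinom(50, 1, 0.5)
  direct <- -sum(y * log(p) + (1 - y) * log(1 - p)) / 50
  expect_equal(bceLoss(p, y), direct, tolerance = 1e-10)
  expect_warning(bceLoss(c(0, 0.5), c(0, 1)), "clamped")
})

test_that("AUROC is the rank statistic with half-weight ties", {
  expect_equal(aurocScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(aurocScore(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  expect_equal(aurocScore(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_error(aurocScore(c(0.2, 0.4), c(1, 1)), "at least one")
  ## random instances incl. ties match the pairwise-concordance oracle
  set.seed(6)
  for (i in 1:10) {
    sc <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(aurocScore(sc, y), pairwiseAuroc(sc, y), tolerance = 1e-12)
  }
})

## shared fast training fixture
trainFixture <- function(seed = 4L) {
  b <- tinyBundle(seed = seed, nLabeledInteractions = 60L)
  g <- assembleGraph(b$residues, b$drugs, b$ppi, b$bind, b$bindMP)
  plan <- drugSplit(b$bind, b$fingerprints, b$bindMP, b$fingerprints,
                    nClusters = 6L, nFolds = 3L, testFraction = 0.2,
                    seed = seed, tolerance = 0.15)
  list(b = b, g = g, plan = plan,
       mcfg = modelConfig(embedDim = 8L, headHidden = 8L))
}

test_that("supervision edges never message-pass and the adjacency is audited every epoch", {
  fx <- trainFixture()
  tcfg <- trainConfig(maxEpochs = 3L, seed = 1L)
  fit <- trainModel(fx$g, fx$plan, fold = "fold_0", mcfg = fx$mcfg, tcfg = tcfg)
  expect_true(all(fit@epochLog$mp_ok))
  expect_true(all(fit@epochLog$mp_hash == fit@mpSignature))
  ## the adjacency used contains no labeled pair, in either arm
  gd <- pocketDTI:::.graphData(fx$g, pocketDTI:::.runMp(fx$plan, "fold_0", TRUE))
  mpPairs <- if (!is.null(gd$rel$bind_mp_d2t)) {
    paste(names(gd$di)[gd$rel$bind_mp_d2t$src - gd$nT],
          names(gd$ti)[gd$rel$bind_mp_d2t$dst])
  } else character(0)
  labeled <- paste(fx$plan@interactions$drug, fx$plan@interactions$target)
  expect_length(intersect(labeled, mpPairs), 0L)
  ## a plan failing the audit is refused
  broken <- fx$plan
  it <- broken@interactions
  d <- it$drug[it$partition == "fold_0"][1L]
  it$partition[it$drug == d][1L] <- "fold_1"
  broken@interactions <- it
  expect_error(trainModel(fx$g, broken, fold = "fold_0", mcfg = fx$mcfg,
                          tcfg = tcfg), "refusing to train")
})

test_that("auxiliary edges contribute no gradient: loss is over labeled records only", {
  fx <- trainFixture()
  gd <- pocketDTI:::.graphData(fx$g, pocketDTI:::.runMp(fx$plan, "fold_0", TRUE))
  it <- fx$plan@interactions
  tr <- it[!it$partition %in% c("fold_0", "test"), ]
  px <- pocketDTI:::.pairIdx(gd, tr)
  ## every supervision index pair comes from the labeled table
  labeled <- paste(it$drug, it$target)
  got <- paste(names(gd$di)[px$d - gd$nT], names(gd$ti)[px$t])
  expect_true(all(got %in% labeled))
  aux <- paste(fx$b$bindMP$drug, fx$b$bindMP$target)
  expect_length(intersect(got, aux), 0L)
})

test_that("the selected epoch maximizes validation AUROC (earliest on ties)", {
  fx <- trainFixture()
  tcfg <- trainConfig(maxEpochs = 8L, seed = 2L)
  fit <- trainModel(fx$g, fx$plan, fold = "fold_0", mcfg = fx$mcfg, tcfg = tcfg)
  log <- fit@epochLog
  expect_equal(fit@bestEpoch, which.max(log$val_auroc))
  expect_true(all(log$val_auroc[fit@bestEpoch] >= log$val_auroc))
  ## evaluating at the stored parameters reproduces the best val AUROC
  ev <- evaluateModel(fit, fx$g, fx$plan, "validation")
  expect_equal(ev$auroc, max(log$val_auroc), tolerance = 1e-12)
})

test_that("training memorizes a small supervision set (overfit sanity)", {
  for (seed in 1:3) {
    b <- tinyBundle(seed = seed, nLabeledInteractions = 30L, labelNoise = 0)
    g <- assembleGraph(b$residues, b$drugs, b$ppi, b$bind, b$bindMP)
    plan <- randomSplit(b$bind, c(0.8, 0.1, 0.1), seed = seed)
    mcfg <- modelConfig(embedDim = 8L, headHidden = 8L)
    ## memorization check: augmentations off, this is a pure capacity /
    ## optimizer sanity test
    tcfg <- trainConfig(maxEpochs = 200L, seed = seed, featureDropout = 0,
                        edgeDropout = 0, featureNoise = 0)
    fit <- trainModel(g, plan, mcfg = mcfg, tcfg = tcfg)
    ev <- evaluateModel(fit, g, plan, "train", at = "final")
    expect_gte(ev$auroc, 0.95)
    ## training AUROC at memorization dominates validation AUROC
    expect_gte(ev$auroc,
               evaluateModel(fit, g, plan, "validation", at = "final")$auroc)
  }
})

test_that("training and evaluation are reproducible under a fixed seed", {
  fx <- trainFixture()
  tcfg <- trainConfig(maxEpochs = 5L, seed = 3L)
  f1 <- trainModel(fx$g, fx$plan, fold = "fold_0", mcfg = fx$mcfg, tcfg = tcfg)
  f2 <- trainModel(fx$g, fx$plan, fold = "fold_0", mcfg = fx$mcfg, tcfg = tcfg)
  expect_equal(f1@epochLog$loss, f2@epochLog$loss, tolerance = 1e-6)
  expect_equal(f1@epochLog$val_auroc, f2@epochLog$val_auroc, tolerance = 1e-6)
  e1 <- evaluateModel(f1, fx$g, fx$plan, "test")
  e2 <- evaluateModel(f1, fx$g, fx$plan, "test")
  expect_identical(e1$scores$score, e2$scores$score)
  ## evaluate is compositional: auroc(scores, labels) of the exported table
  expect_equal(e1$auroc, aurocScore(e1$scores$score, e1$scores$label))
})

test_that("the ablation table has one row per plan and setting, and an empty aux set is a null toggle", {
  fx <- trainFixture()
  rplan <- randomSplit(fx$b$bind, c(0.7, 0.15, 0.15), seed = 1L)
  tcfg <- trainConfig(maxEpochs = 2L, seed = 1L)
  res <- ablationRun(fx$g, list(random = rplan, drug = fx$plan),
                     mcfg = fx$mcfg, tcfg = tcfg, seeds = 1L,
                     folds = "fold_0")
  expect_equal(nrow(res$summary), 4L)
  expect_setequal(paste(res$summary$plan, res$summary$aux_mp),
                  c("random TRUE", "random FALSE", "drug TRUE", "drug FALSE"))
  expect_true(all(c("val_auroc_mean", "val_auroc_sd", "test_auroc_mean",
                    "test_auroc_sd") %in% names(res$summary)))
  ## with no auxiliary records in the graph both arms coincide
  b0 <- tinyBundle(seed = 5, auxFraction = 0, nLabeledInteractions = 60L)
  g0 <- assembleGraph(b0$residues, b0$drugs, b0$ppi, b0$bind, b0$bindMP)
  plan0 <- randomSplit(b0$bind, seed = 2L)
  r0 <- ablationRun(g0, list(random = plan0), mcfg = fx$mcfg,
                    tcfg = trainConfig(maxEpochs = 2L), seeds = 1L)
  expect_equal(r0$runs$test_auroc[r0$runs$aux_mp],
               r0$runs$test_auroc[!r0$runs$aux_mp], tolerance = 1e-12)
})
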