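test_that("tanimoto similarity matches set arithmetic", {
  expect_equal(tanimoto(c(1L, 5L, 9L), c(1L, 5L, 9L)), 1.0)
  expect_equal(tanimoto(c(1L, 2L), c(3L, 4L)), 0.0)
  expect_equal(tanimoto(c(1L, 2L, 3L), c(2L, 3L, 4L)), 0.5)
  expect_warning(z <- tanimoto(integer(0), integer(0)), "empty")
  expect_equal(z, 0)
  ## symmetry and bounds on random bit sets
  set.seed(4)
  for (i in 1:10) {
    a <- sample.int(64, 10); b <- sample.int(64, 12)
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_gte(tanimoto(a, b), 0); expect_lte(tanimoto(a, b), 1)
  }
})

test_that("clustering recovers planted chemotypes and honors forced cases", {
  b <- tinyBundle(seed = 6)
  ## labeled drugs only: aux-only drugs have deliberately decoupled fingerprints
  fps <- fingerprintSet(b$fingerprints$bits[b$truth$labeledDrugs],
                        b$fingerprints$size)
  ## n_clusters = n_drugs: all singletons, each its own medoid
  all1 <- clusterDrugs(fps, length(fps$bits))
  expect_equal(sort(unname(all1$medoids)), sort(names(fps$bits)))
  expect_equal(max(table(all1$clusters)), 1L)
  ## two planted chemotypes, k = 2: clusters equal the planted groups
  cl2 <- clusterDrugs(fps, 2L)
  truth <- b$truth$chemotype[names(cl2$clusters)]
  expect_equal(length(unique(cl2$clusters[truth == 1])), 1L)
  expect_equal(length(unique(cl2$clusters[truth == 2])), 1L)
  expect_false(cl2$clusters[truth == 1][1] == cl2$clusters[truth == 2][1])
  ## medoid of a singleton is its only member
  singletonId <- names(all1$clusters)[1]
  expect_equal(unname(all1$medoids[as.character(all1$clusters[singletonId])]),
               singletonId)
  expect_error(clusterDrugs(fps, 0L), "nClusters")
  expect_error(clusterDrugs(fps, length(fps$bits) + 1L), "exceeds")
})

test_that("cluster partitioning hits the test fraction or fails loudly", {
  ## one cluster holding everything cannot satisfy the test fraction
  fps1 <- fingerprintSet(list(a = 1:4, b = 1:4), 16L)
  one <- clusterDrugs(fps1, 1L)
  it1 <- data.frame(drug = rep(c("a", "b"), 5), target = paste0("t", 1:10),
                    label = rep(0:1, 5))
  expect_error(partitionClusters(one, it1, nFolds = 2L, testFraction = 0.1),
               "cluster interaction counts")

  ## 10 equal singleton clusters, 5 folds, 10% test: exactly one test cluster
  bits <- lapply(1:10, function(i) (10 * i):(10 * i + 5))
  names(bits) <- sprintf("d%02d", 1:10)
  fps <- fingerprintSet(bits, 128L)
  cl <- clusterDrugs(fps, 10L)
  it <- data.frame(drug = names(bits), target = paste0("t", 1:10),
                   label = rep(0:1, 5))
  plan <- partitionClusters(cl, it, nFolds = 5L, testFraction = 0.1, seed = 1L)
  expect_equal(sum(plan@partition$partition == "test"), 1L)
  expect_equal(sum(plan@interactions$partition == "test"), 1L)

  ## every interaction in exactly one partition
  expect_equal(nrow(plan@interactions), nrow(it))
  expect_true(all(plan@interactions$partition %in%
                    c(paste0("fold_", 0:4), "test")))
})

test_that("all interactions of a drug share one partition (cluster atomicity)", {
  b <- tinyBundle(seed = 8)
  plan <- drugSplit(b$bind, b$fingerprints, b$bindMP, b$fingerprints,
                    nClusters = 6L, nFolds = 3L, testFraction = 0.2,
                    seed = 2L, tolerance = 0.15)
  it <- plan@interactions
  expect_true(all(tapply(it$partition, it$drug,
                         function(p) length(unique(p))) == 1))
  ## cluster atomicity: a cluster's drugs all carry the cluster's partition
  cl <- setNames(plan@clusters$cluster_id, plan@clusters$drug_id)
  pt <- setNames(plan@partition$partition, plan@partition$cluster_id)
  expect_equal(unname(pt[as.character(cl[it$drug])]), it$partition)
})

test_that("external drugs go to the nearest medoid with deterministic ties", {
  bits <- list(`1` = c(0L, 1L, 2L, 3L), `2` = c(10L, 11L, 12L, 13L))
  asg <- list(medoidFps = fingerprintSet(bits, 32L))
  ## identical to a medoid: that cluster
  expect_equal(assignExternalDrug(c(0L, 1L, 2L, 3L), asg), 1L)
  ## equidistant: smaller cluster id
  expect_equal(assignExternalDrug(c(0L, 1L, 10L, 11L), asg), 1L)
  ## random fingerprints match a linear-scan oracle over 5 medoids
  set.seed(9)
  bits5 <- setNames(lapply(1:5, function(i) sample.int(64, 8) - 1L), 1:5)
  asg5 <- list(medoidFps = fingerprintSet(bits5, 64L))
  for (i in 1:10) {
    fp <- sample.int(64, 8) - 1L
    sims <- vapply(bits5, function(m) tanimoto(fp, m), numeric(1))
    expect_equal(assignExternalDrug(fp, asg5),
                 as.integer(names(sims))[which.max(sims)])
  }
  expect_error(assignExternalDrug(1:3, list(medoidFps = NULL)), "medoid")
})

test_that("the allowlist admits only drugs nearest a training cluster", {
  b <- tinyBundle(seed = 10)
  plan <- drugSplit(b$bind, b$fingerprints, b$bindMP, b$fingerprints,
                    nClusters = 6L, nFolds = 3L, testFraction = 0.2,
                    seed = 3L, tolerance = 0.15)
  partOf <- setNames(plan@partition$partition,
                     as.character(plan@partition$cluster_id))
  asg <- list(medoidFps = do.call(fingerprintSet, plan@medoidFps))
  for (f in paste0("fold_", 0:2)) {
    allow <- selectMpEdges(plan, f, b$bindMP[, c("drug", "target")],
                           b$fingerprints)
    trainParts <- setdiff(paste0("fold_", 0:2), f)
    for (d in unique(b$bindMP$drug)) {
      cid <- assignExternalDrug(b$fingerprints$bits[[d]], asg)
      inAllow <- d %in% allow$drug
      expect_equal(inAllow, partOf[[as.character(cid)]] %in% trainParts,
                   info = paste(f, d))
    }
  }
  ## empty auxiliary list yields an empty allowlist
  empty <- selectMpEdges(plan, "fold_0", b$bindMP[0, c("drug", "target")],
                         b$fingerprints)
  expect_equal(nrow(empty), 0L)
  ## shrinking the training clusters never grows the allowlist: a drug allowed
  ## for no fold stays excluded everywhere (test-cluster drugs)
  testClusters <- plan@partition$cluster_id[plan@partition$partition == "test"]
  auxTest <- plan@auxAssignment$drug_id[plan@auxAssignment$cluster_id %in%
                                          testClusters]
  for (f in paste0("fold_", 0:2)) {
    expect_false(any(auxTest %in% plan@mpAllowlist[[f]]$drug))
  }
})

test_that("random splits honor sizes, determinism, and seed sensitivity", {
  it <- data.frame(drug = paste0("d", 1:10), target = paste0("t", 1:10),
                   label = rep(0:1, 5))
  plan <- randomSplit(it, c(0.8, 0.1, 0.1), seed = 5L)
  expect_equal(as.vector(table(plan@interactions$partition)[c("train", "validation", "test")]),
               c(8L, 1L, 1L))
  plan2 <- randomSplit(it, c(0.8, 0.1, 0.1), seed = 5L)
  expect_identical(plan@interactions, plan2@interactions)
  ## different seeds give different assignments with high probability
  it100 <- data.frame(drug = paste0("d", 1:100), target = paste0("t", 1:100),
                      label = rep(0:1, 50))
  assigns <- vapply(1:20, function(s)
    paste(randomSplit(it100, seed = s)@interactions$partition, collapse = ""),
    character(1))
  expect_gt(length(unique(assigns)), 15L)
  expect_error(randomSplit(it, c(0.8, 0.1, 0.2)), "summing to 1")
})

test_that("the leakage audit passes clean plans and flags constructed violations", {
  b <- tinyBundle(seed = 12)
  g <- assembleGraph(b$residues, b$drugs, b$ppi, b$bind, b$bindMP)
  plan <- drugSplit(b$bind, b$fingerprints, b$bindMP, b$fingerprints,
                    nClusters = 6L, nFolds = 3L, testFraction = 0.2,
                    seed = 4L, tolerance = 0.15)
  expect_equal(nrow(auditLeakage(plan, g)), 0L)

  ## (a) one drug moved across partitions
  broken <- plan
  it <- broken@interactions
  d <- it$drug[it$partition == "fold_0"][1L]
  it$partition[it$drug == d][1L] <- "fold_1"
  broken@interactions <- it
  aud <- auditLeakage(broken, g)
  expect_equal(sum(aud$type == "drug_in_two_partitions"), 1L)

  ## (c) auxiliary edge injected for a test-cluster drug
  testClusters <- plan@partition$cluster_id[plan@partition$partition == "test"]
  auxTest <- plan@auxAssignment$drug_id[plan@auxAssignment$cluster_id %in%
                                          testClusters]
  if (length(auxTest)) {
    rec <- b$bindMP[b$bindMP$drug == auxTest[1L], c("drug", "target")][1L, ]
    broken2 <- plan
    broken2@mpAllowlist$fold_0 <- rbind(broken2@mpAllowlist$fold_0, rec)
    aud2 <- auditLeakage(broken2, g)
    expect_equal(sum(aud2$type == "allowlist_cluster_rule"), 1L)
  }

  ## (b) a held-out labeled pair present in the graph's message-passing set
  broken3 <- plan
  ho <- it[it$partition == "test", ][1L, ]
  g2 <- g
  g2@bindMP <- rbind(g2@bindMP, data.frame(drug = ho$drug, target = ho$target))
  aud3 <- auditLeakage(broken3, g2)
  expect_gte(sum(aud3$type == "held_out_pair_in_mp"), 1L)
})

test_that("split plans serialize byte-identically under a fixed seed", {
  b <- tinyBundle(seed = 14)
  mk <- function() drugSplit(b$bind, b$fingerprints, b$bindMP, b$fingerprints,
                             nClusters = 6L, nFolds = 3L, testFraction = 0.2,
                             seed = 7L, tolerance = 0.15)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeSplitPlan(mk(), f1)
  writeSplitPlan(mk(), f2)
  expect_identical(readLines(f1), readLines(f2))
  ## and the round trip preserves the plan content
  back <- readSplitPlan(f1)
  orig <- mk()
  expect_equal(back@interactions, orig@interactions)
  expect_equal(back@partition, orig@partition)
  expect_equal(back@mpAllowlist, orig@mpAllowlist)
})
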