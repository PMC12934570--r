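test_that("transformer convolution handles isolated and single-neighbor nodes", {
  p <- randomConvParams(3L, 3L, seed = 1)
  x <- matrix(rnorm(9), 3)
  ## isolated nodes: x' = W1 x
  out0 <- transformerConv(x, matrix(integer(0), 0, 2), p)
  expect_equal(unname(out0), unname(x %*% p$W1), ignore_attr = TRUE)
  ## exactly one in-neighbor: alpha = 1, x' = W1 x + W2 x_j
  e <- cbind(2L, 1L)
  out1 <- transformerConv(x, e, p)
  expect_equal(out1[1, ], (x[1, ] %*% p$W1 + x[2, ] %*% p$W2)[1, ],
               ignore_attr = TRUE)
  expect_equal(attr(out1, "alpha"), 1)
  expect_error(transformerConv(matrix(c(1, NA), 1), e, p), "non-finite")
})

test_that("transformer convolution equals the dense masked-attention oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:10, 1)
    d <- sample(2:5, 1)
    x <- matrix(rnorm(n * d), n)
    ## random directed edge set
    ne <- sample(1:(n * 2), 1)
    edges <- unique(cbind(sample.int(n, ne, replace = TRUE),
                          sample.int(n, ne, replace = TRUE)))
    p <- randomConvParams(d, d, seed = seed + 100)
    got <- transformerConv(x, edges, p)
    want <- denseAttentionOracle(x, edges, p)
    expect_equal(unname(got), unname(want), tolerance = 1e-5,
                 ignore_attr = TRUE)
    ## attention normalization per destination
    alpha <- attr(got, "alpha")
    sums <- tapply(alpha, edges[, 2], sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
})

test_that("encoding has the contracted shape and the virtual row", {
  g <- tinyGraph()
  mcfg <- modelConfig(embedDim = 8L, headHidden = 8L)
  m <- initModel(g, mcfg, seed = 1)
  H <- encodeGraph(g, m)
  expect_equal(dim(H), c(length(targetIds(g)) + length(drugIds(g)) + 1L, 8L))
  expect_equal(rownames(H)[nrow(H)], "<virtual>")
  expect_true(all(is.finite(H)))
})

test_that("an edgeless graph reduces to per-layer affine maps of own features", {
  inp <- toyAssemblyInputs()
  ## strip all cross-node structure: no ppi, no aux, dissimilar embeddings
  inp$ppi <- inp$ppi[0, ]
  inp$drugs$embedding <- rbind(c(1, 0), c(0, 1))
  res <- inp$residues[c(1, 4), ]  # one orthogonal residue each for t1, t3
  g <- assembleGraph(res, inp$drugs, inp$ppi,
                     data.frame(drug = c("d1", "d2"), target = c("t1", "t3"),
                                label = c(1L, 0L)), NULL)
  expect_equal(nrow(edgeTable(g, "target_sim")) + nrow(edgeTable(g, "drug_sim")) +
                 nrow(edgeTable(g, "ppi")), 0L)
  mcfg <- modelConfig(embedDim = 2L, headHidden = 2L)
  m <- initModel(g, mcfg, seed = 2)
  ## message passing excludes bind edges by construction, so with bind_mp off
  ## targets receive no messages at all
  H <- encodeGraph(g, m, mp = list(bind_mp = FALSE))
  p <- m@params
  ## closed-form forward pass for a target node: three affine maps + ReLU
  h <- g@targetFeatures["t1", , drop = FALSE] %*% p$proj$target$W + p$proj$target$b
  for (l in 1:3) {
    h <- h %*% p$trunk[[l]]$self$target
    if (l < 3) h <- pmax(h, 0)
  }
  expect_equal(H["t1", ], h[1, ], tolerance = 1e-10)
  ## drugs additionally receive virtual-node messages: they must differ
  hD <- g@drugFeatures["d1", , drop = FALSE] %*% p$proj$drug$W + p$proj$drug$b
  for (l in 1:3) {
    hD <- hD %*% p$trunk[[l]]$self$drug
    if (l < 3) hD <- pmax(hD, 0)
  }
  expect_false(isTRUE(all.equal(H["d1", ], hD[1, ], tolerance = 1e-8)))
})

test_that("encoding is equivariant under node relabeling", {
  b <- tinyBundle(seed = 17)
  g1 <- assembleGraph(b$residues, b$drugs, b$ppi, b$bind, b$bindMP)
  ## relabel: reverse the lexicographic order by renaming ids
  flipId <- function(x, ids) {
    names(ids) <- rev(ids)
    unname(ids[x])
  }
  tIds <- targetIds(g1); dIds <- drugIds(g1)
  res <- b$residues; res$target_id <- flipId(res$target_id, tIds)
  dr <- b$drugs; dr$drug_id <- flipId(dr$drug_id, dIds)
  ppi <- b$ppi
  ppi$target_a <- flipId(ppi$target_a, tIds); ppi$target_b <- flipId(ppi$target_b, tIds)
  bd <- b$bind; bd$drug <- flipId(bd$drug, dIds); bd$target <- flipId(bd$target, tIds)
  mp <- b$bindMP; mp$drug <- flipId(mp$drug, dIds); mp$target <- flipId(mp$target, tIds)
  g2 <- assembleGraph(res, dr, ppi, bd, mp)
  mcfg <- modelConfig(embedDim = 6L, headHidden = 6L)
  m <- initModel(g1, mcfg, seed = 5)
  m2 <- m; m2@graphHash <- graphHash(g2)
  H1 <- encodeGraph(g1, m)
  H2 <- encodeGraph(g2, m2)
  ## node t of g1 was renamed to flip(t) in g2: the embeddings must match
  for (t in tIds) expect_equal(unname(H1[t, ]), unname(H2[flipId(t, tIds), ]),
                               tolerance = 1e-10)
  for (d in dIds) expect_equal(unname(H1[d, ]), unname(H2[flipId(d, dIds), ]),
                               tolerance = 1e-10)
})

test_that("dropping an empty edge type changes no embedding", {
  inp <- toyAssemblyInputs()
  g <- assembleGraph(inp$residues, inp$drugs, inp$ppi[0, ], inp$bind,
                     inp$bindMP)
  expect_equal(nrow(edgeTable(g, "ppi")), 0L)
  m <- initModel(g, modelConfig(embedDim = 4L, headHidden = 4L), seed = 3)
  H1 <- encodeGraph(g, m, mp = list(ppi = TRUE))
  H2 <- encodeGraph(g, m, mp = list(ppi = FALSE))
  expect_identical(H1[, ], H2[, ])
})

test_that("link scores are sigmoid-bounded, deterministic, and 0.5 at zero weights", {
  g <- tinyGraph()
  mcfg <- modelConfig(embedDim = 4L, headHidden = 4L)
  m <- initModel(g, mcfg, seed = 9)
  H <- encodeGraph(g, m)
  d1 <- H[drugIds(g)[1], ]; t1 <- H[targetIds(g)[1], ]
  s1 <- linkScore(d1, t1, m)
  expect_gt(s1, 0); expect_lt(s1, 1)
  expect_identical(s1, linkScore(d1, t1, m))
  mZero <- m
  mZero@params$head <- lapply(mZero@params$head, function(w) w * 0)
  expect_equal(linkScore(d1, t1, mZero), 0.5)
  expect_error(linkScore(d1[1:2], t1, m), "dimension")
})

test_that("analytic gradients match central finite differences", {
  b <- tinyBundle(seed = 3)
  g <- assembleGraph(b$residues, b$drugs, b$ppi, b$bind, b$bindMP)
  mcfg <- modelConfig(embedDim = 5L, headHidden = 4L)
  m <- initModel(g, mcfg, seed = 7)
  gd <- pocketDTI:::.graphData(g, list(bind_mp = TRUE))
  px <- pocketDTI:::.pairIdx(gd, g@bind[1:10, ])
  params <- m@params
  theta <- unlist(params)
  lossAt <- function(th) {
    p <- utils::relist(th, params)
    fw <- pocketDTI:::.forwardTrunk(p, gd, mcfg)
    hd <- pocketDTI:::.headForward(p, fw$H, px$d, px$t, mcfg$leakySlope)
    bceLoss(pmin(pmax(hd$p, 1e-12), 1 - 1e-12), px$y)
  }
  fw <- pocketDTI:::.forwardTrunk(params, gd, mcfg)
  hd <- pocketDTI:::.headForward(params, fw$H, px$d, px$t, mcfg$leakySlope)
  gr <- unlist(pocketDTI:::.backwardFull(params, gd, mcfg, fw, hd,
                                         px$d, px$t, px$y))
  set.seed(1)
  idx <- sample(length(theta), 10)
  for (i in idx) {
    h <- 1e-5 * (abs(theta[i]) + 1e-2)
    tp <- theta
    tp[i] <- theta[i] + h; l1 <- lossAt(tp)
    tp[i] <- theta[i] - h; l2 <- lossAt(tp)
    fd <- (l1 - l2) / (2 * h)
    denom <- max(abs(fd), abs(gr[i]), 1e-8)
    expect_lt(abs(fd - gr[i]) / denom, 1e-4)
  }
})
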