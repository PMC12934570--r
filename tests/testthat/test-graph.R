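test_that("graph assembly applies every filter on the hand-built toy", {
  inp <- toyAssemblyInputs()
  g <- assembleGraph(inp$residues, inp$drugs, inp$ppi, inp$bind, inp$bindMP)
  expect_equal(targetIds(g), c("t1", "t2", "t3"))
  expect_equal(drugIds(g), c("d1", "d2"))
  expect_equal(nrow(edgeTable(g, "target_sim")), 1L)  # t1-t2 share a residue
  expect_equal(edgeTable(g, "target_sim")$a, "t1")
  expect_equal(nrow(edgeTable(g, "drug_sim")), 1L)    # identical embeddings
  expect_equal(nrow(edgeTable(g, "ppi")), 1L)         # second record fails evidence
  expect_equal(nrow(edgeTable(g, "bind")), 2L)
  expect_equal(nrow(edgeTable(g, "bind_mp")), 1L)
})

test_that("binding records for pocketless targets are dropped with their target", {
  inp <- toyAssemblyInputs()
  inp$bind <- rbind(inp$bind,
                    data.frame(drug = "d2", target = "t9", label = 1L))
  g <- assembleGraph(inp$residues, inp$drugs, inp$ppi, inp$bind, inp$bindMP)
  expect_false("t9" %in% targetIds(g))
  expect_false("t9" %in% edgeTable(g, "bind")$target)
  expect_equal(g@metadata$droppedBindPocketless, 1L)
})

test_that("graphs carry no self-loops and one row per unordered pair", {
  g <- tinyGraph()
  for (ty in c("ppi", "target_sim", "drug_sim")) {
    e <- edgeTable(g, ty)
    expect_true(all(e$a != e$b))
    expect_true(all(e$a < e$b))
    expect_equal(anyDuplicated(paste(e$a, e$b)), 0L)
  }
  bp <- edgeTable(g, "bind")
  expect_true(all(bp$drug %in% drugIds(g)) && all(bp$target %in% targetIds(g)))
})

test_that("pairs in both binding sources stay supervised and leave message passing", {
  inp <- toyAssemblyInputs()
  inp$bindMP <- rbind(inp$bindMP,
                      data.frame(drug = "d1", target = "t1"))  # also labeled
  g <- assembleGraph(inp$residues, inp$drugs, inp$ppi, inp$bind, inp$bindMP)
  expect_equal(g@metadata$dedupMP, 1L)
  expect_false(any(paste(g@bindMP$drug, g@bindMP$target) == "d1 t1"))
  expect_true(any(paste(g@bind$drug, g@bind$target) == "d1 t1"))
})

test_that("conflicting duplicate labels are an error, same-label duplicates collapse", {
  inp <- toyAssemblyInputs()
  conflict <- rbind(inp$bind, data.frame(drug = "d1", target = "t1", label = 0L))
  expect_error(assembleGraph(inp$residues, inp$drugs, inp$ppi, conflict,
                             inp$bindMP), "conflicting")
  dup <- rbind(inp$bind, data.frame(drug = "d1", target = "t1", label = 1L))
  g <- assembleGraph(inp$residues, inp$drugs, inp$ppi, dup, inp$bindMP)
  expect_equal(nrow(edgeTable(g, "bind")), 2L)
})

test_that("assembly is deterministic with stable node ordering", {
  b <- tinyBundle(seed = 9)
  g1 <- assembleGraph(b$residues, b$drugs, b$ppi, b$bind, b$bindMP)
  g2 <- assembleGraph(b$residues, b$drugs, b$ppi, b$bind, b$bindMP)
  expect_identical(targetIds(g1), targetIds(g2))
  expect_identical(edgeTable(g1, "target_sim"), edgeTable(g2, "target_sim"))
  expect_identical(nodeFeatures(g1, "drug"), nodeFeatures(g2, "drug"))
  expect_false(is.unsorted(targetIds(g1)))
  expect_false(is.unsorted(drugIds(g1)))
})

test_that("largest component matches a union-find oracle and its tie rule", {
  ## connected toy graph returns itself
  g <- tinyGraph()
  lc <- largestComponent(g)
  expect_equal(targetIds(lc), targetIds(g))
  expect_equal(drugIds(lc), drugIds(g))

  ## forced 3-vs-2 split: drop enough binding records to disconnect
  inp <- toyAssemblyInputs()
  inp$ppi <- inp$ppi[0, ]
  inp$bindMP <- inp$bindMP[0, ]
  ## components: {t1, t2} via target_sim; {d1, d2, t3} via drug_sim + bind
  inp$bind <- data.frame(drug = c("d1", "d2"), target = c("t3", "t3"),
                         label = c(1L, 0L), stringsAsFactors = FALSE)
  g2 <- assembleGraph(inp$residues, inp$drugs, inp$ppi, inp$bind, NULL)
  lc2 <- largestComponent(g2)
  expect_equal(sort(c(targetIds(lc2), drugIds(lc2))), c("d1", "d2", "t3"))

  ## random sparse fixture: membership equals the union-find oracle
  b <- tinyBundle(seed = 21)
  g3 <- assembleGraph(b$residues, b$drugs, b$ppi, b$bind, b$bindMP)
  nodes <- c(paste0("t:", targetIds(g3)), paste0("d:", drugIds(g3)))
  edges <- rbind(
    cbind(paste0("t:", g3@ppi$a), paste0("t:", g3@ppi$b)),
    cbind(paste0("t:", g3@targetSim$a), paste0("t:", g3@targetSim$b)),
    cbind(paste0("d:", g3@drugSim$a), paste0("d:", g3@drugSim$b)),
    cbind(paste0("d:", g3@bind$drug), paste0("t:", g3@bind$target)),
    cbind(paste0("d:", g3@bindMP$drug), paste0("t:", g3@bindMP$target)))
  roots <- unionFindComponents(nodes, edges)
  sizes <- table(roots)
  biggest <- names(roots)[roots == names(sizes)[which.max(sizes)]]
  lc3 <- largestComponent(g3)
  expect_setequal(c(paste0("t:", targetIds(lc3)), paste0("d:", drugIds(lc3))),
                  biggest)
})

test_that("graph stats report the per-type counts", {
  g <- tinyGraph()
  st <- graphStats(g)
  v <- setNames(st$value, st$property)
  expect_equal(v[["n_target_nodes"]], length(targetIds(g)))
  expect_equal(v[["n_bind_edges"]], nrow(edgeTable(g, "bind")))
  expect_equal(v[["n_edges"]],
               sum(sapply(c("ppi", "target_sim", "drug_sim", "bind", "bind_mp"),
                          function(t) nrow(edgeTable(g, t)))))
})

test_that("graph bundles round-trip through the directory format", {
  g <- tinyGraph(seed = 2)
  dir <- withr::local_tempdir()
  writeGraphBundle(g, dir)
  g2 <- readGraphBundle(dir)
  expect_equal(targetIds(g2), targetIds(g))
  expect_equal(drugIds(g2), drugIds(g))
  expect_equal(edgeTable(g2, "bind"), edgeTable(g, "bind"))
  expect_equal(unname(nodeFeatures(g2, "drug")), unname(nodeFeatures(g, "drug")),
               tolerance = 1e-6)
})
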