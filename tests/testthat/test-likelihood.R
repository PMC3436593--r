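test_that("pruning equals exhaustive state summation on tiny trees", {
  tr <- readNewick("((a:0.2,b:0.35):0.1,(c:0.15,d:0.4):0.3);")
  mod <- substitutionModel("GTR", pi = c(0.3, 0.2, 0.3, 0.2),
                           rates = c(1.5, 4, 0.7, 1.2, 5, 1),
                           pInv = 0.2, alpha = 0.6)
  aln <- alnFromStrings(a = "ACGN", b = "AC-T", c = "GCTT", d = "ACTA")
  expect_equal(treeLogLik(aln, tr, mod), bruteForceLogLik(aln, tr, mod),
               tolerance = 1e-8)
  tr5 <- readNewick("(((a:0.2,b:0.3):0.1,c:0.25):0.2,(d:0.3,e:0.1):0.15);")
  aln5 <- alnFromStrings(a = "ACG", b = "ACT", c = "GCA", d = "TTG",
                         e = "ACG")
  mod5 <- substitutionModel("HKY85", pi = c(0.35, 0.15, 0.2, 0.3),
                            kappa = 4, alpha = 0.9)
  expect_equal(treeLogLik(aln5, tr5, mod5),
               bruteForceLogLik(aln5, tr5, mod5), tolerance = 1e-8)
})

test_that("single-site two-taxon likelihood matches the closed form", {
  jc <- substitutionModel("JC69")
  t <- 0.37
  tr <- readNewick(sprintf("(a:%f,b:%f);", t / 2, t / 2))
  # JC transition probability: 1/4 + 3/4 exp(-4t/3) same, else
  # 1/4 - 1/4 exp(-4t/3)
  pSame <- 0.25 + 0.75 * exp(-4 * t / 3)
  expect_equal(treeLogLik(alnFromStrings(a = "A", b = "A"), tr, jc),
               log(0.25 * pSame), tolerance = 1e-10)
  expect_equal(treeLogLik(alnFromStrings(a = "A", b = "C"), tr, jc),
               log(0.25 * (1 - pSame) / 3), tolerance = 1e-10)
})

test_that("likelihood is invariant under re-rooting and all-gap taxa", {
  ds <- simulateDataset(4, 1, 2, 40,
                        model = substitutionModel("GTR",
                          pi = c(0.3, 0.2, 0.3, 0.2),
                          rates = c(1.5, 4, 0.7, 1.2, 5, 1), alpha = 0.7),
                        nSites = 300, seed = 71)
  mod <- substitutionModel("GTR", pi = c(0.3, 0.2, 0.3, 0.2),
                           rates = c(1.5, 4, 0.7, 1.2, 5, 1), alpha = 0.7)
  tr <- ds$tree
  ll <- treeLogLik(ds$alignment, tr, mod)
  rerooted <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[1],
                        resolve.root = TRUE)
  expect_equal(treeLogLik(ds$alignment, rerooted, mod), ll,
               tolerance = 1e-6)
  # pulley principle holds for the unrooted representation too
  expect_equal(treeLogLik(ds$alignment, ape::unroot(tr), mod), ll,
               tolerance = 1e-6)

  # an all-gap taxon contributes a factor of one: gapping a tip's row is
  # equivalent to pruning the tip from the tree
  m <- maskedMatrix(ds$alignment)
  gapTaxon <- tr$tip.label[1]
  m[gapTaxon, ] <- "-"
  llGapped <- treeLogLik(barcodeAlignment(m), tr, mod)
  pruned <- ape::drop.tip(tr, gapTaxon)
  llPruned <- treeLogLik(ds$alignment, pruned, mod)
  expect_equal(llGapped, llPruned, tolerance = 1e-6)
})

test_that("strict-clock LR test: nesting always, power under rate shifts", {
  mod <- substitutionModel("HKY85", kappa = 3)
  # clock-true data: the clock fit can never beat the free fit
  ds <- simulateDataset(3, 1, 2, 30, model = mod, nSites = 400, seed = 81)
  res <- strictClockTest(ds$alignment, ds$tree, mod)
  expect_lte(res$logLClock, res$logLFree + 1e-4)
  expect_equal(res$df, length(ds$tree$tip.label) - 2)
  expect_true(res$p >= 0 && res$p <= 1)

  # one 5x accelerated terminal branch: rejected in nearly all replicates
  rej <- 0
  nrep <- 8
  for (s in seq_len(nrep)) {
    tr <- simulateYuleTree(8, 1, seed = 90 + s)
    tr$edge.length <- tr$edge.length / max(nodeAges(tr)) * 0.1
    term <- which(tr$edge[, 2] == 1)
    tr$edge.length[term] <- tr$edge.length[term] * 5
    aln <- simulateAlignment(tr, mod, 800, seed = 190 + s)
    res <- strictClockTest(aln, tr, mod)
    if (res$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej, nrep - 1)
})

test_that("strict-clock test holds its nominal size on clock data", {
  mod <- substitutionModel("JC69")
  rej <- 0
  nrep <- 15
  for (s in seq_len(nrep)) {
    tr <- simulateYuleTree(6, 1, seed = 400 + s)
    tr$edge.length <- tr$edge.length / max(nodeAges(tr)) * 0.15
    aln <- simulateAlignment(tr, mod, 500, seed = 500 + s)
    res <- strictClockTest(aln, tr, mod)
    if (res$p < 0.05) rej <- rej + 1
  }
  # nominal 5%: allow 2 binomial SDs above the expectation
  expect_lte(rej, ceiling(nrep * 0.05 + 2 * sqrt(nrep * 0.05 * 0.95)))
})
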