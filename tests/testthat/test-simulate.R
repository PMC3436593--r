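test_that("Yule trees match the analytic waiting-time moments", {
  tr <- simulateYuleTree(6, 1, seed = 1)
  expect_equal(length(tr$tip.label), 6)
  expect_equal(tr$Nnode, 5)                  # binary: n-1 internal nodes
  expect_true(ape::is.binary(tr))
  expect_true(isUltrametric(tr))

  # root-to-first-split interval ~ Exponential(2 lambda)
  lambda <- 2
  gaps <- vapply(1:2000, function(s) {
    a <- nodeAges(simulateYuleTree(3, lambda, seed = s))[4:5]
    max(a) - min(a)
  }, 0)
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 1 / (2 * lambda)), 3 * se)
})

test_that("coalescent grafting preserves ultrametry and the partition", {
  sp <- simulateYuleTree(4, 0.5, seed = 3)
  sim <- simulateSpeciesCoalescents(sp, c(3, 1, 2, 4), 0.01, seed = 4)
  expect_true(isUltrametric(sim$tree))
  expect_equal(sort(unname(speciesSizes(sim$partition))), c(1, 2, 3, 4))
  expect_equal(length(sim$tree$tip.label), 10)
  # one sample per species: the species tree itself
  sim1 <- simulateSpeciesCoalescents(sp, 1, 0.01, seed = 5)
  spRenamed <- sp
  spRenamed$tip.label <- paste0(sp$tip.label, "_1")
  expect_equal(ape::dist.topo(ape::unroot(sim1$tree),
                              ape::unroot(spRenamed)), 0,
               ignore_attr = TRUE)

  # two samples: mean pair-coalescence height ~ theta
  theta <- 0.02
  h <- vapply(1:400, function(s) {
    tr <- simulateCoalescentTree(2, theta, seed = s)
    max(nodeAges(tr))
  }, 0)
  se <- sd(h) / sqrt(length(h))
  expect_lt(abs(mean(h) - theta), 3 * se)
})

test_that("sequence simulation obeys the model and is reproducible", {
  mod <- substitutionModel("GTR", pi = c(0.4, 0.1, 0.2, 0.3),
                           rates = c(1.5, 4, 0.7, 1.2, 5, 1), alpha = 0.8)
  # zero-length tree: identical rows
  tr0 <- readNewick("(a:0,b:0,c:0);")
  aln0 <- simulateAlignment(tr0, mod, 100, seed = 2)
  m0 <- maskedMatrix(aln0)
  expect_true(all(m0[1, ] == m0[2, ]) && all(m0[1, ] == m0[3, ]))

  # long-run base composition approaches pi
  tr <- readNewick("(a:0.05,b:0.05);")
  aln <- simulateAlignment(tr, mod, 20000, seed = 3)
  f <- empiricalBaseFreqs(aln)
  se <- sqrt(0.4 * 0.6 / 40000)
  expect_lt(max(abs(f - mod@pi)), 5 * se)

  # two-taxon JC distance d: E[p] = 3/4 (1 - exp(-4 d / 3))
  d <- 0.2
  trd <- readNewick(sprintf("(a:%f,b:%f);", d / 2, d / 2))
  jc <- substitutionModel("JC69")
  ps <- vapply(1:40, function(s) {
    m <- maskedMatrix(simulateAlignment(trd, jc, 500, seed = s))
    pDistance(m[1, ], m[2, ])
  }, 0)
  expected <- 0.75 * (1 - exp(-4 * d / 3))
  expect_lt(abs(mean(ps) - expected), 3 * sd(ps) / sqrt(length(ps)))

  # bit-reproducibility
  a1 <- simulateAlignment(tr, mod, 300, seed = 11)
  a2 <- simulateAlignment(tr, mod, 300, seed = 11)
  expect_identical(a1@seqs, a2@seqs)
  expect_identical(writeNewick(simulateYuleTree(7, 1, seed = 9)),
                   writeNewick(simulateYuleTree(7, 1, seed = 9)))
})

test_that("the duplication fixture has the published pair-count profile", {
  fx <- makeDuplicationFixture(seed = 6, withSequences = FALSE)
  sz <- speciesSizes(fx$partition)
  expect_equal(sum(sz), 64)
  expect_equal(sum(choose(sz, 2)), 114)
  expect_equal(length(fx$modification$duplications), 2)
  expect_true(all(sz[speciesOf(fx$partition,
    names(fx$modification$duplications))] == 1))
  expect_true(isUltrametric(fx$tree))
})

test_that("end-to-end: simulated species survive distance + GMYC recovery", {
  mod <- substitutionModel("GTR", pi = c(0.3, 0.2, 0.3, 0.2),
                           rates = c(1.5, 4, 0.7, 1.2, 5, 1), alpha = 0.8)
  hits <- 0
  for (s in 1:5) {
    ds <- simulateDataset(5, 1, 4, 100, model = mod, nSites = 2000,
                          seed = 800 + s)
    g <- fitGmyc(ds$tree, "single")
    if (nEntities(g) == 5) hits <- hits + 1
    # sequence distances separate intra from inter at these settings
    dm <- distanceMatrix(ds$alignment, method = "ml", model = mod)
    spd <- partitionDistances(dm, ds$partition)
    expect_lt(max(spd$intra), min(spd$inter))
  }
  expect_gte(hits, 4)
})
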