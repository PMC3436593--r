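test_that("Newick IO validates and round-trips simulated trees", {
  tr <- readNewick("((a:1,b:1):1,c:2);")
  expect_equal(length(tr$tip.label), 3)
  expect_true(isUltrametric(tr))
  expect_false(isUltrametric(readNewick("((a:1,b:2):1,c:2);")))
  expect_error(readNewick("((a:1,b:1):1,c:2;"))
  expect_error(readNewick("((a:1,a:1):1,c:2);"), "duplicate")

  for (s in 1:20) {
    tr <- simulateYuleTree(2 + (s %% 8) + 1, 1, seed = s)
    txt <- writeNewick(tr)
    tr2 <- readNewick(txt)
    expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = TRUE))
    expect_true(isUltrametric(tr2))
  }
})

test_that("neighbor joining recovers additive quartets (enumeration oracle)", {
  # additive matrix from a known quartet: ((a,b),(c,d)) with internal 0.3
  quartetDist <- function(bl) {
    d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    d["a", "b"] <- d["b", "a"] <- bl[1] + bl[2]
    d["a", "c"] <- d["c", "a"] <- bl[1] + bl[5] + bl[3]
    d["a", "d"] <- d["d", "a"] <- bl[1] + bl[5] + bl[4]
    d["b", "c"] <- d["c", "b"] <- bl[2] + bl[5] + bl[3]
    d["b", "d"] <- d["d", "b"] <- bl[2] + bl[5] + bl[4]
    d["c", "d"] <- d["d", "c"] <- bl[3] + bl[4]
    d
  }
  # brute-force oracle: the quartet split with the smallest sum-criterion
  bestSplit <- function(d) {
    s <- c(ab.cd = d["a", "b"] + d["c", "d"],
           ac.bd = d["a", "c"] + d["b", "d"],
           ad.bc = d["a", "d"] + d["b", "c"])
    names(which.min(s))
  }
  quartetTree <- function(split) {
    p <- strsplit(split, "\\.")[[1]]
    readNewick(sprintf("((%s:1,%s:1):1,(%s:1,%s:1):1);",
                       substr(p[1], 1, 1), substr(p[1], 2, 2),
                       substr(p[2], 1, 1), substr(p[2], 2, 2)))
  }
  set.seed(77)
  for (rep in 1:20) {
    bl <- runif(5, 0.05, 0.5)
    d <- quartetDist(bl)
    tr <- neighborJoining(d)
    oracle <- bestSplit(d)           # four-point condition
    expect_equal(ape::dist.topo(ape::unroot(tr),
                                ape::unroot(quartetTree(oracle))), 0,
                 ignore_attr = TRUE)
  }
  expect_equal(oracle, "ab.cd")      # sanity: generating topology wins
})

test_that("3-taxon NJ has the closed-form star resolution", {
  d <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighborJoining(d)
  # branch lengths: x_a = (d_ab + d_ac - d_bc)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(bl["b"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(bl["c"]), (0.5 + 0.6 - 0.3) / 2)
})

test_that("NJ on clock-tree distances reproduces the topology; saturation errors", {
  ds <- simulateDataset(5, 1, 2, 20, seed = 13)
  d <- ape::cophenetic.phylo(ds$tree)
  tr <- neighborJoining(d[ds$tree$tip.label, ds$tree$tip.label])
  expect_equal(ape::dist.topo(ape::unroot(ds$tree), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  dm <- distanceMatrix(alnFromStrings(a = "AC", b = "CA", c = "AA",
                                      d = "CC"), method = "k2p_closed")
  expect_error(neighborJoining(dm), "saturated")
})

test_that("LTT curves step once per internal node", {
  # one step per internal node, closed by a row at the present
  bal <- readNewick("((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(lttCurve(bal)$lineages, c(2, 3, 4, 4))
  expect_equal(lttCurve(bal)$time, c(-2, -1, -1, 0))
  cat4 <- readNewick("(((a:1,b:1):1,c:2):1,d:3);")
  expect_equal(lttCurve(cat4)$lineages, c(2, 3, 4, 4))
  expect_equal(lttCurve(cat4)$time, c(-3, -2, -1, 0))
  for (s in 1:5) {
    tr <- simulateYuleTree(7, 1, seed = 50 + s)
    cu <- lttCurve(tr)
    expect_equal(nrow(cu), 7)          # n-1 internal-node steps + present
    expect_equal(cu$lineages[1], 2)
    expect_equal(cu$lineages[nrow(cu)], 7)
    expect_true(all(diff(cu$lineages) >= 0))
  }
  expect_error(lttCurve(readNewick("((a:1,b:2):1,c:2);")), "ultrametric")
})

test_that("NJ bootstrap is reproducible and bounded", {
  tr <- simulateYuleTree(6, 1, seed = 61)
  tr$edge.length <- tr$edge.length / max(nodeAges(tr)) * 0.25
  aln <- simulateAlignment(tr, substitutionModel("K80", kappa = 2), 500,
                           seed = 62)
  b1 <- njBootstrap(aln, nReplicates = 20, seed = 5)
  b2 <- njBootstrap(aln, nReplicates = 20, seed = 5)
  expect_identical(attr(b1, "support"), attr(b2, "support"))
  expect_true(all(attr(b1, "support") >= 0 & attr(b1, "support") <= 100))
  # strong signal: deep split supported near 100%
  expect_gt(max(attr(b1, "support")), 90)
  b3 <- njBootstrap(aln, nReplicates = 1, seed = 9)
  expect_equal(attr(b3, "dropped"), 0L)
})
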