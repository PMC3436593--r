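test_that("binning follows the closed-lower/open-upper convention", {
  fd <- binDistances(c(0.000, 0.0049, 0.005), 0.005)
  expect_equal(fd@counts, c(2L, 1L))
  expect_equal(fd@nTotal, 3L)
  # 0.287 lands in class 58 = [0.285, 0.290[
  expect_equal(length(binDistances(0.287, 0.005)@counts), 58L)
  empty <- binDistances(numeric(0))
  expect_equal(empty@nTotal, 0L)
  expect_equal(length(empty@counts), 0L)
  expect_error(binDistances(c(0.1, -0.2)), "index 2")
  expect_error(binDistances(c(NaN)), "index 1")
})

test_that("binning is exhaustive and exclusive for random values", {
  set.seed(123)
  v <- runif(1e5, 0, 0.4)
  fd <- binDistances(v, 0.005)
  expect_equal(sum(fd@counts), length(v))
  # each value sits in exactly the class its bounds describe
  tab <- frequencyTable(fd)
  for (k in sample(which(tab$count > 0), 5))
    expect_equal(sum(v >= tab$lower[k] & v < tab$upper[k]), tab$count[k])
})

test_that("intra/inter partitioning satisfies the pair-count identities", {
  ds <- simulateDataset(3, 1, c(2, 2, 1), 50, seed = 7)
  dm0 <- ape::cophenetic.phylo(ds$tree)
  dm <- new("PairwiseDistances", values = dm0,
            saturated = matrix(FALSE, nrow(dm0), ncol(dm0),
                               dimnames = dimnames(dm0)),
            modelTag = "tree", units = "expected substitutions per site")
  sp <- partitionDistances(dm, ds$partition)
  expect_equal(length(sp$intra), 2)          # C(2,2)+C(2,2)
  expect_equal(length(sp$inter), choose(5, 2) - 2)

  # brute-force oracle on random partitions
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    labels <- paste0("t", seq_len(n))
    spp <- sample(paste0("S", 1:5), n, replace = TRUE)
    part <- speciesPartition(setNames(spp, labels))
    v <- matrix(0, n, n, dimnames = list(labels, labels))
    v[lower.tri(v)] <- runif(choose(n, 2)); v <- v + t(v)
    dmr <- new("PairwiseDistances", values = v,
               saturated = matrix(FALSE, n, n, dimnames = dimnames(v)),
               modelTag = "x", units = "proportion")
    got <- partitionDistances(dmr, part)
    brute <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (spp[i] == spp[j]) brute <- brute + 1
    expect_equal(length(got$intra), brute)
    expect_equal(length(got$intra), sum(choose(speciesSizes(part), 2)))
    expect_equal(length(got$intra) + length(got$inter), choose(n, 2))
  }
  # single species: all pairs intraspecific
  part1 <- speciesPartition(setNames(rep("S", 5), rownames(dm0)))
  expect_equal(length(partitionDistances(dm, part1)$intra), choose(5, 2))
  expect_error(partitionDistances(dm, speciesPartition(
    setNames("S1", rownames(dm0)[1]))), "unassigned")
})

test_that("gap detection reports interior empty classes and minima only", {
  fdOf <- function(counts) new("FrequencyDistribution", classWidth = 0.005,
                               counts = as.integer(counts),
                               intra = integer(0), inter = integer(0),
                               nTotal = sum(as.integer(counts)))
  g <- findGaps(fdOf(c(5, 3, 0, 7)))
  expect_equal(g$emptyClasses, 3L)
  # strictly unimodal: no empty classes, no interior minima
  g2 <- findGaps(fdOf(c(1, 4, 9, 4, 1)))
  expect_equal(length(g2$emptyClasses), 0)
  expect_equal(nrow(g2$minima), 0)
  # trailing zeros are not interior gaps
  g3 <- findGaps(fdOf(c(5, 2, 0, 0)))
  expect_equal(length(g3$emptyClasses), 0)
  # an interior local minimum with its flanks
  g4 <- findGaps(fdOf(c(9, 2, 8, 1)))
  expect_equal(g4$minima$class, 2)
  expect_equal(g4$minima$left, 9)
  expect_equal(g4$minima$right, 8)
})

test_that("duplicate_and_recode mirrors the taxon-sampling experiment", {
  aln <- alnFromStrings(a = "ACGTACGT", b = "ACGAACGT", c = "ACTTACGA")
  part <- speciesPartition(c(a = "S1", b = "S1", c = "S2"))
  # duplicate one taxon once: distance of the copy to its source is zero
  mod <- duplicateAndRecode(aln, part, duplications = c(a = 1L))
  expect_equal(taxa(mod$data), c("a", "b", "c", "a__dup1"))
  dm <- distanceMatrix(mod$data, method = "p")
  expect_equal(distanceValues(dm)["a", "a__dup1"], 0)
  expect_equal(distanceValues(dm)["b", "a__dup1"],
               distanceValues(dm)["b", "a"])
  expect_equal(speciesOf(mod$partition, "a__dup1"), "S1")

  # recoding only: the distance matrix is unchanged
  dmOnly <- distanceMatrix(aln, method = "p")
  mod2 <- duplicateAndRecode(dmOnly, part, recodings = c(b = "S3"))
  expect_equal(distanceValues(mod2$data), distanceValues(dmOnly))
  expect_equal(unname(speciesSizes(mod2$partition)[c("S1", "S3")]),
               c(1L, 1L))

  expect_error(duplicateAndRecode(aln, speciesPartition(c(a = "S1")),
                                  duplications = c(b = 1L)), "unassigned")

  # the intraspecific-pair delta of the published recipe is +18
  fx <- makeDuplicationFixture(seed = 2, withSequences = FALSE)
  dm0 <- ape::cophenetic.phylo(fx$tree)
  dmFx <- new("PairwiseDistances", values = dm0,
              saturated = matrix(FALSE, nrow(dm0), ncol(dm0),
                                 dimnames = dimnames(dm0)),
              modelTag = "tree", units = "expected substitutions per site")
  res <- duplicateAndRecode(dmFx, fx$partition,
                            duplications = fx$modification$duplications,
                            recodings = fx$modification$recodings)
  expect_equal(res$summary$intra[2] - res$summary$intra[1], 18)
})
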