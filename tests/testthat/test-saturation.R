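test_that("sitewise entropies match hand values and exclude gapped columns", {
  aln <- alnFromStrings(a = "AAC-G", b = "AACTG", c = "ACGTG", d = "ACGTG")
  H <- sitewiseEntropy(aln)
  expect_equal(attr(H, "excluded"), 1L)           # the gapped column 4
  expect_equal(unname(H[1]), 0)                   # constant A
  expect_equal(unname(H[2]), 1)                   # half A half C
  expect_equal(unname(H[3]), 1)                   # half C half G
  uniform <- alnFromStrings(a = "A", b = "C", c = "G", d = "T")
  expect_equal(unname(sitewiseEntropy(uniform)[1]), 2)
})

test_that("the saturation index hits its analytic limits", {
  # invariant data: Iss -> 0 / no signal
  m <- matrix(rep(c("A", "C", "G", "T"), 50), nrow = 8, ncol = 200,
              byrow = TRUE)
  rownames(m) <- paste0("t", 1:8)
  inv <- issTest(barcodeAlignment(m), pInv = 0, nOtu = 8, seed = 1)
  expect_lt(inv@iss, 1e-12)
  # with the invariable fraction removed there is nothing left
  inv2 <- issTest(barcodeAlignment(m), pInv = 1 - 1e-9, nOtu = 8, seed = 1)
  expect_equal(inv2@verdict, "no signal")

  # i.i.d. uniform rows (full saturation): Iss -> 1
  set.seed(5)
  mu <- matrix(sample(c("A", "C", "G", "T"), 32 * 2000, TRUE), nrow = 32)
  rownames(mu) <- paste0("t", 1:32)
  sat <- issTest(barcodeAlignment(mu), pInv = 0, nOtu = 32, seed = 2)
  expect_lt(abs(sat@iss - 1), 0.05)
})

test_that("Iss is invariant under taxon and column permutation", {
  ds <- simulateDataset(4, 1, 2, 40,
                        model = substitutionModel("JC69", alpha = 0.8),
                        nSites = 300, seed = 55)
  m <- maskedMatrix(ds$alignment)
  set.seed(8)
  mp <- m[sample(nrow(m)), sample(ncol(m))]
  r1 <- issTest(barcodeAlignment(m), nOtu = 8, seed = 3)
  r2 <- issTest(barcodeAlignment(mp), nOtu = 8, seed = 3)
  expect_equal(r1@iss, r2@iss, tolerance = 1e-12)
})

test_that("Iss increases monotonically with simulated depth", {
  jc <- substitutionModel("JC69")
  medIss <- vapply(c(0.1, 1, 10), function(scale) {
    vals <- vapply(1:8, function(s) {
      tr <- simulateYuleTree(8, 1, seed = 60 + s)
      tr$edge.length <- tr$edge.length / max(nodeAges(tr)) * 0.3 * scale
      aln <- simulateAlignment(tr, jc, 400, seed = 160 + s)
      issTest(aln, nOtu = 8, seed = s)@iss
    }, 0)
    median(vals)
  }, 0)
  expect_true(all(diff(medIss) > 0))
})

test_that("resampling averages reduce to the full set at 32 taxa", {
  set.seed(12)
  m <- matrix(sample(c("A", "C", "G", "T"), 32 * 300, TRUE,
                     prob = c(0.4, 0.2, 0.2, 0.2)), nrow = 32)
  rownames(m) <- paste0("t", 1:32)
  aln <- barcodeAlignment(m)
  direct <- issTest(aln, nOtu = 32, seed = 1)
  expect_equal(direct@nResamples, 1L)
  # adding taxa forces resampling; with all rows i.i.d. the estimator
  # stays near the 32-taxon value
  m2 <- rbind(m, matrix(sample(c("A", "C", "G", "T"), 8 * 300, TRUE,
                               prob = c(0.4, 0.2, 0.2, 0.2)), nrow = 8,
                        dimnames = list(paste0("u", 1:8), NULL)))
  res <- issTest(barcodeAlignment(m2), nOtu = 32, nResamples = 30,
                 seed = 2)
  expect_equal(res@nResamples, 30L)
  expect_lt(abs(res@iss - direct@iss), 0.02)
})

test_that("the verdict follows the four-way decision table", {
  tab <- data.frame(n_otu = 8, n_sites = 300,
                    topology = rep(c("symmetric", "asymmetric"), 2),
                    iss_c = c(0.9, 0.8, 0.9, 0.8))
  ds <- simulateDataset(4, 1, 2, 40,
                        model = substitutionModel("JC69"), nSites = 300,
                        seed = 66)
  low <- issTest(ds$alignment, nOtu = 8, seed = 1, criticalTable = tab)
  expect_equal(low@verdict, "low saturation")
  expect_lt(low@pSym, 0.05)
  # critical value just below the observed index: useless
  tabHi <- transform(tab, iss_c = max(low@iss - 0.2, 0.01))
  useless <- issTest(ds$alignment, nOtu = 8, seed = 1,
                     criticalTable = tabHi)
  expect_equal(useless@verdict, "useless")
  # critical value inside the noise band: not significant
  tabMid <- transform(tab, iss_c = low@iss + 1e-4)
  mid <- issTest(ds$alignment, nOtu = 8, seed = 1, criticalTable = tabMid)
  expect_equal(mid@verdict, "substantial saturation")
  expect_gt(mid@pSym, 0.05)
  expect_error(issTest(alnFromStrings(a = "AC", b = "AC", c = "AC"),
                       nOtu = 4, seed = 1), "4 taxa")
})
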