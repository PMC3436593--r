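test_that("waiting-time schedules capture the threshold geometry", {
  tr <- readNewick("((a:1,b:1):2,(c:1,d:1):2);")
  # switch older than the root: one species, schedule equals coalescent
  schedAll <- buildSchedule(tr, 10)
  expect_equal(schedAll@k, rep(0L, 3))
  expect_equal(schedAll@coalPairs, c(2, 6, 12))   # N(N-1)
  expect_equal(sum(schedAll@times), 3)
  # switch younger than every node: all diversification
  schedNone <- buildSchedule(tr, 0.5)
  expect_equal(schedNone@k, c(2L, 3L, 4L))
  expect_equal(schedNone@coalPairs, rep(0, 3))
  # switch between the root and the two cheek nodes
  sched2 <- buildSchedule(tr, 2)
  expect_equal(sched2@k[1], 2L)                   # two species lineages
  expect_equal(sched2@coalPairs[2], 2)            # first cluster opened
  expect_equal(sched2@coalPairs[3], 4)            # both clusters of 2
  # explicit node classification gives the same all-coalescent schedule
  n <- length(tr$tip.label)
  cls <- setNames(rep("coalescent", tr$Nnode), (n + 1):(n + tr$Nnode))
  expect_equal(buildSchedule(tr, cls)@coalPairs, schedAll@coalPairs)
  # inconsistent assignment: a diversification node below the (coalescent)
  # root is rejected
  bad <- cls
  bad[as.character(n + 2)] <- "diversification"
  expect_error(buildSchedule(tr, bad), "inconsistent")
})

test_that("waiting-time log-likelihood matches closed forms", {
  # one interval ending in an event: exponential density log b - b x
  sched <- new("WaitingTimeSchedule", times = 0.7, lineages = 2L,
               k = 2L, coalCounts = matrix(0, 0, 1), coalPairs = 0,
               event = TRUE, speciesRoots = integer(0))
  lam <- 1.3
  expect_equal(waitingTimeLogLik(sched, lam, 1, 0, 1),
               log(lam * 2) - lam * 2 * 0.7)
  # zero hazard over an event interval: -Inf, not an error
  expect_identical(waitingTimeLogLik(sched, 0, 1, 0, 1), -Inf)

  # pure-Yule maximum-likelihood rate: (n-2) / sum(k_i x_i)
  tr <- simulateYuleTree(12, 1, seed = 17)
  sched <- buildSchedule(tr, 0)        # all diversification
  n <- 12
  lamHat <- (n - 2) / sum(as.numeric(sched@k) * sched@times)
  ll <- function(l) waitingTimeLogLik(sched, l, 1, 0, 1)
  expect_gt(ll(lamHat), ll(lamHat * 1.05))
  expect_gt(ll(lamHat), ll(lamHat * 0.95))
  opt <- optimize(ll, c(1e-3, 100), maximum = TRUE, tol = 1e-10)
  expect_equal(opt$maximum, lamHat, tolerance = 1e-4)

  # invariance under tip-label permutation within a species
  ds <- simulateDataset(4, 1, 3, 80, seed = 23)
  s1 <- buildSchedule(ds$tree, 10)
  expect_equal(waitingTimeLogLik(s1, 0.5, 1, 2, 0.8),
               waitingTimeLogLik(buildSchedule(ds$tree, 10), 0.5, 1, 2, 0.8))
})

test_that("GMYC nesting and null-consistency invariants hold", {
  for (s in c(2, 5, 8)) {
    ds <- simulateDataset(4, 1, 4, 30, seed = 600 + s)
    g0 <- fitGmyc(ds$tree, "null")
    g1 <- fitGmyc(ds$tree, "single")
    gm <- fitGmyc(ds$tree, "multiple")
    expect_lte(g0@logLik, g1@logLik + 1e-8)
    expect_lte(g1@logLik, gm@logLik + 1e-8)
    # the threshold at/beyond the root reproduces the null model
    cand <- g1@candidates
    expect_equal(min(cand$logL[which.min(cand$threshold)]),
                 g0@logLik, tolerance = 1e-6)
    # clusters and singletons partition the tips
    tips <- sort(c(unlist(g1@clusters), g1@singletons))
    expect_equal(tips, sort(ds$tree$tip.label))
    expect_equal(nEntities(g1),
                 length(g1@clusters) + length(g1@singletons))
  }
})

test_that("entity count decreases as the single threshold moves rootward", {
  ds <- simulateDataset(5, 1, 4, 60, seed = 33)
  cand <- fitGmyc(ds$tree, "single")@candidates
  ord <- order(cand$threshold)              # most negative = most rootward
  expect_true(all(diff(cand$nEntities[ord]) >= 0))
})

test_that("single-threshold GMYC recovers strongly separated species", {
  hits <- 0
  for (s in 1:8) {
    ds <- simulateDataset(5, 1, 5, 100, seed = 700 + s)
    g <- fitGmyc(ds$tree, "single")
    if (nEntities(g) == 5) hits <- hits + 1
    # delimited clusters must coincide with the true species when counted
    if (length(g@clusters) == 5) {
      got <- lapply(g@clusters, sort)
      truth <- split(names(ds$partition@assignments),
                     ds$partition@assignments)
      expect_setequal(vapply(got, paste, "", collapse = ","),
                      vapply(lapply(truth, sort), paste, "",
                             collapse = ","))
    }
  }
  expect_gte(hits, 7)
})

test_that("multiple-threshold search nests and finds split switch regimes", {
  # one global switch: no significant improvement over the single model
  ds <- simulateDataset(5, 1, 5, 100, seed = 307)
  g1 <- fitGmyc(ds$tree, "single")
  gm <- fitGmyc(ds$tree, "multiple")
  expect_gte(gm@logLik, g1@logLik - 1e-8)
  cmp <- compareGmyc(gm, g1)
  expect_true(is.na(cmp$p) || cmp$p > 0.05)

  # two clades whose within-species coalescent depths differ 30-fold:
  # the greedy search opens separate switch levels for separate lineages
  sp <- simulateYuleTree(6, 0.4, seed = 36)
  sp$edge.length <- sp$edge.length / min(nodeAges(sp)[7:11])
  sim <- suppressWarnings(
    simulateSpeciesCoalescents(sp, 5, rep(c(0.004, 0.12), each = 3),
                               seed = 46))
  g12 <- fitGmyc(sim$tree, "single")
  gm2 <- fitGmyc(sim$tree, "multiple")
  expect_gt(gm2@logLik, g12@logLik)
  expect_gte(length(gm2@thresholds), 2)
  expect_gte(length(gm2@clusters), length(g12@clusters))
})

test_that("cluster membership is stable under tiny height jitter", {
  # a near-polytomy of identical sequences: heights ~1e-3 of root height,
  # jittered by ~1e-9 of root height
  mk <- function(jit) {
    h <- 1e-3
    readNewick(sprintf(
      "((a:%.12f,(b:%.12f,c:%.12f):%.12f):%.12f,((d:1,e:1):0.5,f:1.5):0.5);",
      h + jit, h / 2, h / 2 + jit, h / 2 - jit, 2 - h - jit))
  }
  g0 <- fitGmyc(mk(0), "single")
  g1 <- fitGmyc(mk(1e-12), "single")    # jitter ~1e-9 of root height
  idOf <- function(g) sort(vapply(lapply(g@clusters, sort), paste, "",
                                  collapse = ","))
  expect_identical(idOf(g0), idOf(g1))
  expect_identical(sort(g0@singletons), sort(g1@singletons))
})

test_that("entity extraction is deterministic and complete", {
  ds <- simulateDataset(4, 1, 3, 80, seed = 44)
  g <- fitGmyc(ds$tree, "single")
  tab <- extractEntities(g)
  expect_equal(sort(tab$tip), sort(ds$tree$tip.label))
  expect_equal(length(unique(tab$entity)), nEntities(g))
  tf <- tempfile()
  extractEntities(g, tf)
  expect_identical(read.table(tf, header = TRUE, sep = "\t"), tab)
})
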