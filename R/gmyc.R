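# Shared preprocessing for the mixed Yule-coalescent machinery: node ages,
# parent map, the event order (internal nodes from the root toward the
# present) and the inter-event waiting times.  Interval i spans
# [age_{i+1}, age_i] directly after the i-th oldest branching event; the
# last interval ends at the present without an event.
gmycPrep <- function(tree, tol = 1e-6) {
  assertUltrametric(tree, tol)
  n <- length(tree$tip.label)
  ages <- nodeAges(tree)
  ages[seq_len(n)] <- 0            # snap tips exactly to the present
  internal <- (n + 1):(n + tree$Nnode)
  ord <- internal[order(-ages[internal], internal)]
  evAges <- ages[ord]
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- split(tree$edge[, 2], tree$edge[, 1])
  pre <- integer(0)                # preorder: parents before children
  stack <- internal[1]
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    pre <- c(pre, v)
    ch <- children[[as.character(v)]]
    if (!is.null(ch)) stack <- c(stack, rev(ch))
  }
  evIndex <- integer(n + tree$Nnode)
  evIndex[ord] <- seq_along(ord)
  list(tree = tree, n = n, ages = ages, events = ord, evAges = evAges,
       evIndex = evIndex,
       x = c(-diff(evAges), evAges[length(evAges)]),
       parent = parent, children = children, preorder = pre,
       root = internal[1])
}

# A delimitation state: an antichain of "domain" root nodes covering all
# tips, each with its own switch level (the age of a node inside the
# domain; -1 = no switch, the whole domain keeps diversifying).  Lineages
# of a domain are in the coalescent class during intervals whose upper age
# is <= the domain level, and in the diversification (Yule) class above
# it; species are the maximal subtrees of a domain whose root age is <=
# the level, plus singleton tips.
stateEval <- function(prep, domainNodes, domainLevels) {
  n <- prep$n
  nNode <- n + prep$tree$Nnode
  domOf <- integer(nNode)
  for (d in seq_along(domainNodes)) domOf[domainNodes[d]] <- d
  for (v in prep$preorder) {
    for (ch in prep$children[[as.character(v)]])
      if (domOf[ch] == 0) domOf[ch] <- domOf[v]
  }
  lev <- ifelse(domOf > 0, domainLevels[pmax(domOf, 1)], -1)
  coal <- prep$ages <= lev & domOf > 0
  # species roots: coalescent nodes whose parent is not coalescent
  pa <- prep$parent
  spRootFlag <- coal & (pa == 0 | !coal[pmax(pa, 1)])
  spRoots <- which(spRootFlag)
  spOf <- integer(nNode)
  for (v in prep$preorder) {
    if (spRootFlag[v]) spOf[v] <- v
    else if (pa[v] > 0 && coal[v]) spOf[v] <- spOf[pa[v]]
  }

  nEv <- n - 1
  evSp <- spOf[prep$events]                 # 0 = diversification event
  ages_i <- prep$evAges
  coalLin <- numeric(nEv); C <- numeric(nEv)
  counts <- matrix(0, length(spRoots), nEv)
  for (ri in seq_along(spRoots)) {
    r <- spRoots[ri]
    lj <- lev[r]
    active <- ages_i <= lj
    if (!any(active)) next
    occ <- cumsum(tabulate(which(evSp == r), nbins = nEv))
    counts[ri, ] <- active * (1 + occ)
    coalLin <- coalLin + active * (1 + occ)
    C <- C + active * (1 + occ) * occ
  }
  lin <- seq_len(nEv) + 1
  k <- lin - coalLin
  clusters <- spRoots[spRoots > n]
  singleTips <- seq_len(n)[spRootFlag[seq_len(n)] | !coal[seq_len(n)]]
  list(k = as.integer(k), C = C, counts = counts, x = prep$x,
       event = c(rep(TRUE, nEv - 1), FALSE),
       lineages = as.integer(lin),
       spRoots = spRoots, clusterRoots = clusters,
       singletonTips = singleTips)
}

#' Build the waiting-time schedule for a node classification
#'
#' Derives the per-interval diversification-class lineage counts and the
#' pooled coalescent pair counts from an assignment of every internal node
#' to the diversification (speciation) or the coalescent process.  The
#' assignment must be temporally consistent (no coalescent node ancestral
#' to a diversification node).  Species are the maximal subtrees whose
#' root node is coalescent; each species' switch is placed just rootward
#' of its root node, and tips hanging from diversification nodes are
#' singletons.  A single numeric threshold age may be given instead: all
#' lineages then switch at that age (nodes younger than it coalesce).
#'
#' @param tree rooted binary ultrametric phylo.
#' @param assignment character vector named by internal node number with
#'   values \code{"diversification"}/\code{"coalescent"}, or one numeric
#'   threshold age.
#' @return A \linkS4class{WaitingTimeSchedule}.
#' @export
buildSchedule <- function(tree, assignment) {
  prep <- gmycPrep(tree)
  internal <- prep$events
  if (is.numeric(assignment) && length(assignment) == 1) {
    # global threshold: one domain rooted at the root, level = largest
    # node age below the threshold
    below <- prep$evAges[prep$evAges < assignment]
    lev <- if (length(below)) max(below) else -1
    ev <- stateEval(prep, prep$root, lev)
  } else {
    cls <- assignment[as.character(internal)]
    if (any(is.na(cls)))
      stop("assignment must cover every internal node")
    coal <- internal[cls == "coalescent"]
    isCoal <- logical(prep$n + tree$Nnode); isCoal[coal] <- TRUE
    for (v in setdiff(internal, coal)) {
      pa <- prep$parent[v]
      if (pa > 0 && isCoal[pa])
        stop("inconsistent assignment: coalescent node ", pa,
             " is ancestral to diversification node ", v)
    }
    # per-species domains: each maximal coalescent subtree switches just
    # rootward of its own root; remaining tips keep diversifying
    roots <- coal[!vapply(coal, function(v) {
      pa <- prep$parent[v]; pa > 0 && isCoal[pa]
    }, TRUE)]
    freeTips <- which(!isCoal[prep$parent[seq_len(prep$n)]])
    freeTips <- freeTips[!freeTips %in% roots]
    domainNodes <- c(roots, freeTips)
    domainLevels <- c(prep$ages[roots], rep(-1, length(freeTips)))
    if (!length(domainNodes)) stop("no domains derivable")
    ev <- stateEval(prep, domainNodes, domainLevels)
  }
  new("WaitingTimeSchedule", times = ev$x, lineages = ev$lineages,
      k = ev$k, coalCounts = ev$counts, coalPairs = ev$C,
      event = ev$event, speciesRoots = as.integer(sort(ev$spRoots)))
}

#' Mixed Yule-coalescent waiting-time log-likelihood
#'
#' \deqn{\log L = \sum_{i \in events} \log b_i - \sum_i b_i x_i}
#' with hazard
#' \eqn{b_i = \lambda_{div} k_i^{p_{div}} +
#'   \lambda_{coal} (\sum_j n_{i,j}(n_{i,j}-1))^{p_{coal}}};
#' a class with zero lineages contributes 0 to the hazard.  The final
#' interval (youngest branching event to the present) contributes only its
#' survival term, which is what makes the pure-Yule maximum-likelihood
#' rate equal \eqn{(n-2)/\sum_i k_i x_i}.  A zero hazard on an interval
#' ending in an event yields \code{-Inf}, not an error.
#'
#' @param schedule a \linkS4class{WaitingTimeSchedule}.
#' @param lambdaDiv,pDiv rate and scaling exponent of the diversification
#'   class.
#' @param lambdaCoal,pCoal rate and scaling exponent of the pooled
#'   coalescent class.
#' @param pooled pool the coalescent pair counts across species before
#'   applying the exponent (the default, matching the reference
#'   behaviour); \code{FALSE} applies the exponent per species:
#'   \eqn{\lambda_{coal} \sum_j (n_{i,j}(n_{i,j}-1))^{p_{coal}}}.
#' @return log-likelihood.
#' @export
waitingTimeLogLik <- function(schedule, lambdaDiv, pDiv, lambdaCoal,
                              pCoal, pooled = TRUE) {
  if (lambdaDiv < 0 || lambdaCoal < 0) stop("rates must be non-negative")
  if (!pooled) {
    # per-species exponent: hazard term lambda * sum_j (n_j(n_j-1))^p
    nn <- schedule@coalCounts * (schedule@coalCounts - 1)
    b <- ifelse(schedule@k > 0, lambdaDiv * schedule@k^pDiv, 0) +
      lambdaCoal * colSums(ifelse(nn > 0, nn^pCoal, 0))
    ev <- schedule@event
    if (any(b[ev] <= 0)) return(-Inf)
    return(sum(log(b[ev])) - sum(b * schedule@times))
  }
  mixedLogLik(schedule@k, schedule@coalPairs, schedule@times,
              schedule@event, lambdaDiv, pDiv, lambdaCoal, pCoal)
}

mixedLogLik <- function(k, C, x, ev, lambdaDiv, pDiv, lambdaCoal, pCoal) {
  b <- ifelse(k > 0, lambdaDiv * k^pDiv, 0) +
    ifelse(C > 0, lambdaCoal * C^pCoal, 0)
  if (any(b[ev] <= 0)) return(-Inf)
  sum(log(b[ev])) - sum(b * x)
}

# profile fit of a single-class hazard b = lambda * g^p (g given)
profileSingleClass <- function(g, x, ev, pBounds) {
  nEv <- sum(ev & g > 0)
  if (nEv == 0 || any(g[ev] <= 0)) return(NULL)
  prof <- function(p) {
    gp <- g^p
    lam <- nEv / sum(gp * x)
    sum(log(lam * gp[ev])) - lam * sum(gp * x)
  }
  opt <- optimize(prof, pBounds, maximum = TRUE, tol = 1e-9)
  p <- opt$maximum
  lam <- nEv / sum(g^p * x)
  list(logLik = opt$objective, lambda = lam, p = p)
}

# maximise the 4-parameter mixed likelihood; exact profile fits are used
# when one class is empty throughout
fitMixedRaw <- function(k, C, x, ev, pBounds = c(0, 10)) {
  if (all(k == 0)) {
    f <- profileSingleClass(C, x, ev, pmax(pBounds, c(1e-4, 1)))
    if (is.null(f)) return(NULL)
    return(list(logLik = f$logLik,
                parameters = c(lambdaDiv = 0, pDiv = NA_real_,
                               lambdaCoal = f$lambda, pCoal = f$p)))
  }
  if (all(C == 0)) {
    f <- profileSingleClass(as.numeric(k), x, ev,
                            pmax(pBounds, c(1e-4, 1)))
    if (is.null(f)) return(NULL)
    return(list(logLik = f$logLik,
                parameters = c(lambdaDiv = f$lambda, pDiv = f$p,
                               lambdaCoal = 0, pCoal = NA_real_)))
  }
  obj <- function(par) {
    ll <- mixedLogLik(k, C, x, ev, exp(par[1]), par[2], exp(par[3]),
                      par[4])
    if (!is.finite(ll)) 1e10 else -ll
  }
  lamStart <- function(g) {
    denom <- sum(g * x)
    if (denom <= 0) 1 else max(sum(ev & g > 0) / denom, 1e-8)
  }
  s1 <- c(log(lamStart(as.numeric(k))), 1, log(lamStart(C)), 1)
  s2 <- c(s1[1], 0.5, s1[3], 0.5)
  best <- NULL
  for (st in list(s1, s2)) {
    fit <- tryCatch(
      nlminb(st, obj,
             lower = c(-30, pBounds[1], -30, pBounds[1]),
             upper = c(30, pBounds[2], 30, pBounds[2]),
             control = list(iter.max = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best) || best$objective >= 1e10) return(NULL)
  par <- best$par
  list(logLik = -best$objective,
       parameters = c(lambdaDiv = exp(par[1]), pDiv = par[2],
                      lambdaCoal = exp(par[3]), pCoal = par[4]))
}

#' Fit the GMYC model
#'
#' Fits the general mixed Yule-coalescent model on a rooted, strictly
#' bifurcating ultrametric tree.  \code{mode = "null"} fits the
#' coalescent-only model \eqn{b_i = \lambda (n_i(n_i-1))^p};
#' \code{"single"} scans every distinct branching time as a candidate
#' switch from diversification to coalescence (evaluated just rootward of
#' the node), optimising the rate/scaling parameters at each candidate;
#' \code{"multiple"} starts from the single-threshold optimum and greedily
#' re-assigns individual subtree switch points to other local node heights
#' (move, split-and-move and merge proposals) while the log-likelihood
#' improves by more than \code{tolImprove}, so that different lineages may
#' switch at different times.
#'
#' Clusters are the maximal subtrees below a switch with at least two
#' tips; remaining tips are singletons; entities = clusters + singletons.
#' The cluster-count confidence range covers all evaluated solutions
#' within 2 log-likelihood units of the optimum.  Thresholds are reported
#' as negative relative times before the present.
#'
#' @param tree rooted binary ultrametric phylo with at least 3 tips.
#' @param mode \code{"single"}, \code{"multiple"} or \code{"null"}.
#' @param pBounds box bounds for the scaling exponents.
#' @param tolImprove minimal accepted improvement of the greedy search.
#' @return A \linkS4class{GmycFit}.
#' @export
fitGmyc <- function(tree, mode = c("single", "multiple", "null"),
                    pBounds = c(0, 10), tolImprove = 1e-4) {
  mode <- match.arg(mode)
  prep <- gmycPrep(tree)
  n <- prep$n
  if (n < 3) stop("need at least 3 tips")
  nEv <- n - 1
  evFlag <- c(rep(TRUE, nEv - 1), FALSE)
  lin <- seq_len(nEv) + 1
  gNull <- as.numeric(lin) * (lin - 1)
  nullFit <- profileSingleClass(gNull, prep$x, evFlag,
                                c(1e-4, max(pBounds[2], 1)))
  if (is.null(nullFit)) stop("null model could not be fitted")

  if (mode == "null") {
    return(new("GmycFit", mode = "null", thresholds = -max(prep$evAges),
               parameters = c(lambda = nullFit$lambda, p = nullFit$p),
               logLik = nullFit$logLik, nullLogLik = nullFit$logLik,
               LR = 0, df = 0, pValue = NA_real_,
               clusters = list(tree$tip.label),
               singletons = character(0), confidence = c(1, 1),
               candidates = data.frame(), tree = tree))
  }

  evalState <- function(domainNodes, domainLevels) {
    ev <- stateEval(prep, domainNodes, domainLevels)
    fit <- fitMixedRaw(ev$k, ev$C, ev$x, ev$event, pBounds)
    if (is.null(fit)) return(NULL)
    clusters <- lapply(ev$clusterRoots, function(v)
      tree$tip.label[phangorn::Descendants(tree, v, "tips")[[1]]])
    c(fit, list(domainNodes = domainNodes, domainLevels = domainLevels,
                clusters = clusters,
                singletons = tree$tip.label[ev$singletonTips],
                nClusters = length(clusters),
                nEntities = length(clusters) + length(ev$singletonTips)))
  }

  # --- single-threshold scan over distinct branching ages -------------
  levels <- c(unique(prep$evAges), -1)   # -1: switch younger than all
  cands <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    res <- evalState(prep$root, levels[i])
    if (is.null(res)) { warning("candidate threshold skipped"); next }
    res$threshold <- if (levels[i] < 0) 0 else -levels[i]
    cands[[i]] <- res
  }
  cands <- cands[!vapply(cands, is.null, TRUE)]
  if (!length(cands)) stop("no candidate threshold could be optimised")
  lls <- vapply(cands, `[[`, 0, "logLik")
  best <- cands[[which.max(lls)]]
  candTab <- data.frame(
    threshold = vapply(cands, `[[`, 0, "threshold"),
    logL = lls,
    nClusters = vapply(cands, `[[`, 0L, "nClusters"),
    nEntities = vapply(cands, `[[`, 0L, "nEntities"))
  conf <- range(candTab$nClusters[candTab$logL >= max(lls) - 2])

  LR1 <- 2 * (best$logLik - nullFit$logLik)
  singleFit <- new("GmycFit", mode = "single",
                   thresholds = best$threshold,
                   parameters = best$parameters,
                   logLik = best$logLik, nullLogLik = nullFit$logLik,
                   LR = LR1, df = 3,
                   pValue = pchisq(max(0, LR1), 3, lower.tail = FALSE),
                   clusters = best$clusters,
                   singletons = best$singletons,
                   confidence = as.numeric(conf), candidates = candTab,
                   tree = tree)
  if (mode == "single") return(singleFit)

  # --- multiple-threshold greedy search -------------------------------
  seen <- new.env(parent = emptyenv())
  keyOf <- function(nodes, levs) {
    o <- order(nodes)
    paste(nodes[o], signif(levs[o], 12), sep = "@", collapse = ",")
  }
  evalCached <- function(nodes, levs) {
    key <- keyOf(nodes, levs)
    if (!is.null(seen[[key]])) return(seen[[key]])
    res <- evalState(nodes, levs)
    seen[[key]] <- if (is.null(res)) list(NULL) else res
    res
  }
  # candidate switch levels inside each subtree; every lineage must end
  # in the coalescent class (singletons switch on their terminal branch),
  # so the no-switch level is not available to the greedy search
  subtreeLevels <- lapply(seq_len(n + tree$Nnode), function(v) {
    if (v <= n) return(numeric(0))
    desc <- c(v, phangorn::Descendants(tree, v, "all")[[1]])
    sort(unique(prep$ages[desc[desc > n]]), decreasing = TRUE)
  })
  cur <- evalCached(best$domainNodes, best$domainLevels)
  repeat {
    nodes <- cur$domainNodes; levs <- cur$domainLevels
    proposals <- list()
    addProp <- function(nd, lv) proposals[[length(proposals) + 1]] <<-
      list(nd = nd, lv = lv)
    for (d in seq_along(nodes)) {
      v <- nodes[d]
      for (l in setdiff(subtreeLevels[[v]], levs[d]))
        addProp(nodes, replace(levs, d, l))       # move the switch
      if (v > n) {   # split, the moved child re-levelled, the other
        ch <- prep$children[[as.character(v)]]      # inheriting the switch
        for (ci in 1:2) for (l in subtreeLevels[[ch[ci]]]) {
          lv2 <- c(levs[-d], ifelse(1:2 == ci, l, levs[d]))
          addProp(c(nodes[-d], ch), lv2)
        }
      }
    }
    for (v in prep$events) {                       # merge siblings
      ch <- prep$children[[as.character(v)]]
      if (all(ch %in% nodes)) {
        i1 <- match(ch[1], nodes); i2 <- match(ch[2], nodes)
        for (l in unique(c(levs[c(i1, i2)], prep$ages[v])))
          addProp(c(nodes[-c(i1, i2)], v), c(levs[-c(i1, i2)], l))
      }
    }
    if (!length(proposals)) break
    results <- lapply(proposals, function(p) evalCached(p$nd, p$lv))
    ok <- !vapply(results, function(z)
      is.null(z) || is.null(z$logLik), TRUE)
    results <- results[ok]
    if (!length(results)) break
    pll <- vapply(results, `[[`, 0, "logLik")
    gain <- pll - cur$logLik
    if (max(gain) <= tolImprove) break
    top <- which(gain >= max(gain) - 1e-9)
    if (length(top) > 1) {      # ties broken toward fewer thresholds
      nth <- vapply(results[top], function(z)
        length(unique(z$domainLevels[z$domainLevels >= 0])), 0L)
      top <- top[which.min(nth)]
    } else top <- top[1]
    cur <- results[[top]]
  }
  thr <- sort(unique(cur$domainLevels[cur$domainLevels >= 0]),
              decreasing = TRUE)
  if (!length(thr)) thr <- 0
  allEval <- mget(ls(seen), envir = seen)
  allEval <- allEval[vapply(allEval, function(z) !is.null(z$logLik), TRUE)]
  ell <- vapply(allEval, `[[`, 0, "logLik")
  ecl <- vapply(allEval, `[[`, 0L, "nClusters")
  confM <- range(ecl[ell >= cur$logLik - 2])
  dfM <- 3 + max(0, length(thr) - 1)
  LRm <- 2 * (cur$logLik - nullFit$logLik)
  new("GmycFit", mode = "multiple", thresholds = -thr,
      parameters = cur$parameters,
      logLik = cur$logLik, nullLogLik = nullFit$logLik,
      LR = LRm, df = dfM,
      pValue = pchisq(max(0, LRm), dfM, lower.tail = FALSE),
      clusters = cur$clusters, singletons = cur$singletons,
      confidence = as.numeric(confM), candidates = candTab,
      tree = tree)
}

#' @describeIn fitGmyc number of delimited entities.
#' @param fit a GmycFit.
#' @export
nEntities <- function(fit) length(fit@clusters) + length(fit@singletons)

#' Compare two nested GMYC fits by likelihood ratio
#'
#' Single vs null uses 3 degrees of freedom; multiple vs single uses the
#' number of extra thresholds.
#'
#' @param fitA the richer model.
#' @param fitB the nested model.
#' @return list LR, df, p.
#' @export
compareGmyc <- function(fitA, fitB) {
  LR <- 2 * (fitA@logLik - fitB@logLik)
  df <- if (fitA@mode == "multiple" && fitB@mode == "single")
    max(1, length(fitA@thresholds) - length(fitB@thresholds))
  else max(1, abs(fitA@df - fitB@df))
  list(LR = LR, df = df,
       p = pchisq(max(0, LR), df, lower.tail = FALSE))
}

#' Entity listing of a GMYC fit
#'
#' @param fit a GmycFit.
#' @param path optional TSV output path (columns tip, entity, type).
#' @return data.frame, one row per tip.
#' @export
extractEntities <- function(fit, path = NULL) {
  rows <- list()
  for (i in seq_along(fit@clusters))
    rows[[length(rows) + 1]] <-
      data.frame(tip = fit@clusters[[i]],
                 entity = paste0("cluster", i), type = "cluster")
  for (i in seq_along(fit@singletons))
    rows[[length(rows) + 1]] <-
      data.frame(tip = fit@singletons[i],
                 entity = paste0("singleton", i), type = "singleton")
  tab <- do.call(rbind, rows)
  tab <- tab[order(match(tab$tip, fit@tree$tip.label)), ]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

setMethod("show", "GmycFit", function(object) {
  cat("GMYC fit (", object@mode, " threshold model )\n", sep = "")
  cat(sprintf("  logLik = %.4f  (null %.4f)\n", object@logLik,
              object@nullLogLik))
  if (object@mode != "null") {
    cat(sprintf("  LR vs null = %.3f, df = %d, p = %.4g\n", object@LR,
                as.integer(object@df), object@pValue))
    cat("  threshold time(s):",
        paste(format(object@thresholds, digits = 4), collapse = ", "),
        "\n")
    cat(sprintf("  %d cluster(s), %d singleton(s), %d entities",
                length(object@clusters), length(object@singletons),
                nEntities(object)))
    cat(sprintf("  [cluster-count confidence %d-%d]\n",
                as.integer(object@confidence[1]),
                as.integer(object@confidence[2])))
  }
})
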