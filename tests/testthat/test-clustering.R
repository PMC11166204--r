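test_that("the effector matrix removes regulators and zero-fills absences", {
  wds <- data.frame(bait = c("A", "A", "B"), prey = c("P1", "GAP1", "P2"),
                    wds = c(5, 9, 3))
  m <- buildEffectorMatrix(wds, gapIds = "GAP1")
  expect_equal(sort(colnames(m)), c("P1", "P2"))
  expect_equal(m["A", "P2"], 0)
  expect_equal(m["B", "P2"], 3)
  expect_error(buildEffectorMatrix(wds, gapIds = c("GAP1", "P1", "P2")),
               "effector")
})

test_that("effector matrix entries equal the WDS scores from scoring", {
  sim <- simulateScreen(simConfig(n_baits = 2, n_preys = 100, seed = 3))
  sc <- scoreInteractions(sim@screen)
  m <- buildEffectorMatrix(sc)
  set.seed(1)
  for (i in sample(nrow(sc), 10)) {
    expect_equal(m[sc$bait[i], sc$prey[i]], sc$wds[i])
  }
})

test_that("Canberra prey distances follow the term-by-term definition", {
  m <- rbind(B1 = c(1, 0, 2, 5), B2 = c(0, 1, 1, 5))
  colnames(m) <- paste0("P", 1:4)
  d <- as.matrix(preyDistances(m))
  expect_equal(d["P1", "P2"], 2)        # (1 vs 0) + (0 vs 1)
  expect_equal(d["P3", "P4"], 3 / 7 + 4 / 6)
  expect_equal(d["P4", "P4"], 0)
  m2 <- rbind(B1 = c(2, 1), B2 = c(2, 1))
  expect_equal(as.numeric(preyDistances(m2)), 1 / 3 + 1 / 3)
})

test_that("bait distances are 1 - Pearson correlation", {
  m <- rbind(B1 = c(1, 2, 3), B2 = c(2, 4, 6), B3 = c(3, 2, 1))
  d <- as.matrix(baitDistances(m))
  expect_equal(d["B1", "B2"], 0)        # scale invariance
  expect_equal(d["B1", "B3"], 2)        # perfect anti-correlation
  expect_equal(diag(d), c(B1 = 0, B2 = 0, B3 = 0))
  m_flat <- rbind(B1 = c(1, 1, 1), B2 = c(1, 2, 3))
  expect_error(baitDistances(m_flat), "B1")
})

test_that("distance constructions are symmetric with zero self-distance", {
  set.seed(51)
  for (i in 1:5) {
    m <- matrix(rexp(30) * rbinom(30, 1, 0.7), 5, 6,
                dimnames = list(paste0("B", 1:5), paste0("P", 1:6)))
    m <- m + 0.01  # avoid zero-variance baits
    dp <- as.matrix(preyDistances(m))
    db <- as.matrix(baitDistances(m))
    expect_equal(dp, t(dp))
    expect_equal(db, t(db))
    expect_true(all(diag(dp) == 0))
    expect_equal(diag(db), setNames(rep(0, 5), rownames(m)))
  }
})

test_that("Ward agglomeration reproduces a hand Lance-Williams trace", {
  # d(1,2)=1, d(1,3)=4, d(2,3)=5: merge {1,2} at 1, then
  # d({12},3) = (2*4 + 2*5 - 1)/3 = 17/3
  d <- as.dist(matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3, 3))
  h <- wardCluster(d)
  expect_equal(h$height, c(1, 17 / 3))
  expect_equal(h$merge[1, ], c(-1, -2))

  # two well-separated pairs merge within pairs first
  d2 <- dist(c(0, 0.1, 10, 10.1))
  h2 <- wardCluster(d2)
  expect_equal(sort(h2$height[1:2]), c(0.1, 0.1))

  dn <- as.matrix(d)
  dn[1, 2] <- dn[2, 1] <- NA
  expect_error(wardCluster(as.dist(dn)), "NA")
})

test_that("merge heights are invariant to leaf permutation", {
  set.seed(61)
  x <- matrix(rnorm(40), 20, 2)
  d <- dist(x)
  h <- wardCluster(d)
  perm <- sample(20)
  hp <- wardCluster(dist(x[perm, ]))
  expect_equal(sort(h$height), sort(hp$height), tolerance = 1e-12)
})

test_that("silhouette-guided k recovers planted blocks", {
  # two planted blocks
  d2 <- as.dist(matrix(c(0, 0.1, 5, 5,
                         0.1, 0, 5, 5,
                         5, 5, 0, 0.1,
                         5, 5, 0.1, 0), 4, 4))
  r2 <- selectK(d2, wardCluster(d2), 2:3)
  expect_equal(r2$k, 2)

  # five planted blocks with tiny within- and large between-block
  # distances: k = 5 with a strong silhouette matching the direct formula
  set.seed(95)
  n_per <- 8
  block <- rep(1:5, each = n_per)
  dm <- matrix(0, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    if (i != j)
      dm[i, j] <- if (block[i] == block[j]) runif(1, 0.05, 0.15)
                  else runif(1, 4, 5)
  }
  dm[lower.tri(dm)] <- t(dm)[lower.tri(dm)]
  d5 <- as.dist(dm)
  h <- wardCluster(d5)
  res <- selectK(d5, h, 2:10)
  expect_equal(res$k, 5)
  expect_gt(max(res$silhouetteProfile), 0.8)
  labs <- stats::cutree(h, k = 5)
  expect_equal(unname(res$silhouetteProfile["5"]),
               silhouetteOracle(labs, d5), tolerance = 1e-12)

  # the planted WDS effector generator is recovered at the planted k too
  sim <- simulateEffectorMatrix(seed = 4)
  dp <- preyDistances(sim$wds)
  resw <- selectK(dp, wardCluster(dp), 2:10)
  expect_equal(resw$k, 5)
})

test_that("uniform random dissimilarities yield weak silhouettes + warning", {
  set.seed(71)
  n <- 30
  dm <- matrix(runif(n * n, 0.5, 1), n, n)
  dm <- (dm + t(dm)) / 2
  diag(dm) <- 0
  d <- as.dist(dm)
  expect_warning(res <- selectK(d, wardCluster(d), 2:8), "weak")
  expect_lt(max(res$silhouetteProfile), 0.25)
})

test_that("refining a cut from k to k+1 splits exactly one cluster", {
  sim <- simulateEffectorMatrix(seed = 8)
  d <- preyDistances(sim$wds)
  h <- wardCluster(d)
  for (k in 2:8) {
    a <- stats::cutree(h, k)
    b <- stats::cutree(h, k + 1)
    crossed <- table(a, b)
    expect_equal(sum(rowSums(crossed > 0) == 2), 1)
    expect_equal(sum(rowSums(crossed > 0) == 1), k - 1)
  }
})

test_that("planted bait families and prey modules are recovered", {
  sim <- simulateEffectorMatrix(seed = 2)
  res <- clusterEffectors(sim$wds, 2:10, 2:10)
  expect_equal(res$preys$clusters$k, 5)
  expect_equal(res$baits$clusters$k, 4)
  ari_p <- mclust::adjustedRandIndex(res$preys$clusters$labels,
                                     sim$preyModules)
  expect_gte(ari_p, 0.9)
  expect_equal(ari_p, ariOracle(res$preys$clusters$labels, sim$preyModules),
               tolerance = 1e-12)
  expect_gte(mclust::adjustedRandIndex(res$baits$clusters$labels,
                                       sim$baitFamilies), 0.9)
})
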