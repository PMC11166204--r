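mkScored <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, as.data.frame))
}

row_ <- function(bait = "ARF1", prey = "GBF1", cell_line = "HEK293",
                 avg_p = 0.96, avg_spec = 5, caax_ratio = 2) {
  data.frame(bait = bait, prey = prey, cell_line = cell_line,
             avg_p = avg_p, avg_spec = avg_spec, caax_ratio = caax_ratio)
}

test_that("the filter stack keeps exactly the records passing every gate", {
  sc <- mkScored(
    row_(),                                         # kept (HEK293, 5 >= 4.5)
    row_(prey = "P2", cell_line = "HeLa"),          # dropped: 5 < 6
    row_(prey = "KRT1"),                            # dropped: blocklist
    row_(prey = "P3", avg_p = 0.9),                 # dropped: AvgP
    row_(prey = "P4", caax_ratio = 1.6),            # dropped: CAAX ratio
    row_(prey = "P5", avg_spec = 4.5),              # kept: inclusive bound
    row_(prey = "P6", caax_ratio = Inf))            # kept: absent from CAAX
  f <- applyFilters(sc, FilterConfig())
  expect_setequal(f$records$prey, c("GBF1", "P5", "P6"))
  expect_equal(f$n_in - sum(f$attrition$removed), f$n_out)
  att <- setNames(f$attrition$removed, f$attrition$filter)
  expect_equal(att[["blocklist"]], 1)
  expect_equal(att[["avg_p"]], 1)
  expect_equal(att[["avg_spec"]], 1)
  expect_equal(att[["caax_ratio"]], 1)
})

test_that("an unconfigured cell line is rejected", {
  expect_error(applyFilters(row_(cell_line = "U2OS"), FilterConfig()),
               "U2OS")
})

test_that("raising any threshold never adds records (monotonicity)", {
  set.seed(21)
  sc <- data.frame(bait = "B", prey = sprintf("P%03d", 1:300),
                   cell_line = sample(c("HEK293", "HeLa"), 300, TRUE),
                   avg_p = runif(300), avg_spec = rexp(300, 0.1),
                   caax_ratio = rexp(300, 0.5))
  base <- applyFilters(sc, FilterConfig())$records$prey
  for (cfg in list(FilterConfig(avgPMin = 0.99),
                   FilterConfig(avgSpecMin = c(HEK293 = 6, HeLa = 8)),
                   FilterConfig(caaxRatioMin = 2.5))) {
    expect_true(all(applyFilters(sc, cfg)$records$prey %in% base))
  }
})

test_that("recall labels restrict to calibration baits", {
  gold <- GoldStandard(data.frame(bait = c("ARF1", "ARL2"),
                                  prey = c("GBF1", "TBCD")),
                       baitSubset = "ARF1")
  sc <- mkScored(row_(), row_(prey = "XYZ"),
                 row_(bait = "ARL2", prey = "TBCD"))
  lab <- labelRecall(sc, gold)
  expect_equal(nrow(lab), 2)              # ARL2 excluded from calibration
  expect_equal(lab$label[lab$prey == "GBF1"], 1)
  expect_equal(lab$label[lab$prey == "XYZ"], 0)

  gold_miss <- GoldStandard(data.frame(bait = "ARF1", prey = "NOPE"),
                            baitSubset = "ARF1")
  expect_error(labelRecall(sc, gold_miss), "positive")
})

test_that("ROC cutpoints maximize Youden J with smallest-threshold ties", {
  # perfect separation
  r <- rocCutpoint(c(10, 12, 1, 2), c(1, 1, 0, 0))
  expect_equal(rocAuc(r), 1)
  expect_equal(cutpoint(r), 10)

  # hand-enumerated 4-threshold instance: J maxes at t = 3 and t = 8 (0.5)
  r2 <- rocCutpoint(c(3, 8, 2, 5), c(1, 1, 0, 0))
  expect_equal(cutpoint(r2), 3)
  expect_equal(max(r2@rocPoints$j), 0.5)

  expect_error(rocCutpoint(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC cutpoint equals exhaustive search; null AUC is ~0.5", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(20:400, 1)
    scores <- round(rexp(n, 0.2), 2)
    labels <- rbinom(n, 1, plogis(scale(scores) * runif(1, -2, 2)))
    if (length(unique(labels)) < 2) next
    expect_equal(cutpoint(rocCutpoint(scores, labels)),
                 rocOracle(scores, labels))
  }
  scores <- rnorm(10000)
  labels <- rbinom(10000, 1, 0.5)
  expect_gt(rocAuc(rocCutpoint(scores, labels)), 0.45)
  expect_lt(rocAuc(rocCutpoint(scores, labels)), 0.55)
})

test_that("ROC AUC agrees with an independent implementation", {
  set.seed(7)
  scores <- c(rnorm(150, 1), rnorm(150))
  labels <- rep(c(1, 0), each = 150)
  expect_equal(rocAuc(rocCutpoint(scores, labels)),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-8)
})

test_that("CDA cutpoints sit at the maximum ECDF gap", {
  r <- cdaCutpoint(c(10, 12, 1, 2), c(1, 1, 0, 0))
  expect_equal(cutpoint(r, "cda"), 2)       # largest negative score
  expect_equal(max(r@cdaCurve$gap), 1)

  # hand ECDF table: pos {1,3,5}, neg {2,4} -> max gap 1/3 at s = 4
  r2 <- cdaCutpoint(c(1, 3, 5, 2, 4), c(1, 1, 1, 0, 0))
  expect_equal(cutpoint(r2, "cda"), 4)
  expect_equal(max(r2@cdaCurve$gap), 1 / 3)

  expect_warning(
    r3 <- cdaCutpoint(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0)),
    "indistinguishable")
  expect_equal(cutpoint(r3, "cda"), 1)      # smallest score on full tie
})

test_that("calibration ranks the grid and reports both cutpoint analyses", {
  sim <- simulateScreen(simConfig(n_baits = 12, n_preys = 800, seed = 13))
  truth <- simTruth(sim)
  gold <- GoldStandard(unique(truth$true_edges[, c("bait", "prey")]),
                       baitSubset = truth$baits[1:4])
  sc <- scoreInteractions(sim@screen)
  cal <- calibrate(sc, gold)
  expect_s4_class(cal$reports$avg_spec, "CutpointReport")
  expect_s4_class(cal$reports$caax_ratio, "CutpointReport")
  # Youden J is flat near the optimum at this sample size, so the
  # estimated cutpoint scatters around the model-derived separation
  expect_lte(abs(cutpoint(cal$reports$avg_spec, "cda") -
                 truth$planted_avg_spec_threshold), 3)
  rng <- range(sc$avg_spec[sc$bait %in% truth$baits[1:4]])
  expect_gte(cutpoint(cal$reports$avg_spec), rng[1])
  expect_lte(cutpoint(cal$reports$avg_spec), rng[2])
  expect_equal(cal$grid$rank, seq_len(nrow(cal$grid)))

  one <- calibrate(sc, gold, avgSpecGrid = 4.5, caaxGrid = 1.7)
  expect_equal(nrow(one$grid), 1)
  expect_equal(one$grid$rank, 1)

  only_pos <- sc[paste(sc$bait, sc$prey) %in%
                 paste(gold@edges$bait, gold@edges$prey), ]
  expect_error(calibrate(only_pos, gold), "positive|degenerate")

  expect_error(calibrate(sc, gold, avgSpecGrid = numeric()), "empty")
})

test_that("the surviving set is independent of filter application order", {
  set.seed(41)
  sc <- data.frame(bait = "B", prey = sprintf("P%03d", 1:200),
                   cell_line = "HEK293",
                   avg_p = runif(200), avg_spec = rexp(200, 0.2),
                   caax_ratio = rexp(200, 0.5))
  sc$prey[1:10] <- "KRT1"
  cfg <- FilterConfig()
  full <- applyFilters(sc, cfg)$records
  keyOf <- function(d) sort(paste(d$prey, d$avg_p, d$avg_spec, d$caax_ratio))
  # apply each gate singly in every order; conjunction must agree
  gates <- list(
    function(d) d[d$avg_p >= cfg@avgPMin, ],
    function(d) d[d$avg_spec >= cfg@avgSpecMin[d$cell_line], ],
    function(d) d[d$caax_ratio >= cfg@caaxRatioMin, ],
    function(d) d[!d$prey %in% cfg@blocklist, ])
  for (perm in list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    d <- sc
    for (g in perm) d <- gates[[g]](d)
    expect_equal(keyOf(d), keyOf(full))
  }
})
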