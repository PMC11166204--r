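# small screens built from avg-spec matrices (rows = baits, cols = preys)

test_that("WD reduces to sqrt(X) for a uniformly detected prey", {
  X <- matrix(9, 4, 1, dimnames = list(paste0("B", 1:4), "P1"))
  wd <- computeWD(screenFromMatrix(X), "HEK293")
  expect_equal(wd$wd, rep(3, 4))  # K/f = 1, omega = 1
})

test_that("WD follows the pinned formula for a unique reproducible prey", {
  # K = 4 baits, prey seen by 1 bait with avg_spec 8 in both replicates
  rec <- data.frame(bait = paste0("B", 1:4), prey = c("P1", "P2", "P2", "P2"),
                    cell_line = "HEK293", avg_spec = c(8, 3, 3, 3),
                    avg_p = 0.99)
  rec$replicate_specs <- list(c(8, 8), NULL, NULL, NULL)
  wd <- computeWD(BioidScreen(rec), "HEK293")
  expect_equal(wd$wd[wd$bait == "B1"], sqrt(8 * (4 * 1)^2))  # sqrt(128)
})

test_that("zero average spectral count always scores zero", {
  rec <- data.frame(bait = c("B1", "B2"), prey = "P1",
                    cell_line = "HEK293", avg_spec = c(0, 5), avg_p = 0.9)
  wd <- computeWD(BioidScreen(rec), "HEK293")
  expect_equal(wd$wd[wd$bait == "B1"], 0)
  expect_gt(wd$wd[wd$bait == "B2"], 0)
})

test_that("control baits are excluded from K, f and omega", {
  X <- rbind(B1 = c(8, 0), B2 = c(0, 4), CTRL = c(50, 50))
  colnames(X) <- c("P1", "P2")
  scr <- screenFromMatrix(X, controlBaits = c(gfp = "CTRL"))
  wd <- computeWD(scr, "HEK293")
  expect_false("CTRL" %in% wd$bait)
  # K = 2, f = 1 for each prey despite the control detecting both
  expect_equal(wd$wd[wd$bait == "B1"], sqrt(8 * 2))
})

test_that("WD matches the brute-force oracle on random replicate screens", {
  set.seed(101)
  for (i in 1:12) {
    X <- matrix(rpois(6 * 20, 3) * rbinom(6 * 20, 1, 0.5), 6, 20,
                dimnames = list(paste0("B", 1:6), paste0("P", 1:20)))
    ndet <- matrix(sample(1:2, 120, replace = TRUE), 6, 20)
    idx <- which(X > 0, arr.ind = TRUE)
    rec <- data.frame(bait = rownames(X)[idx[, 1]],
                      prey = colnames(X)[idx[, 2]],
                      cell_line = "HEK293", avg_spec = X[idx], avg_p = 0.99)
    rec$replicate_specs <- lapply(seq_len(nrow(idx)), function(r) {
      n <- ndet[idx[r, 1], idx[r, 2]]
      x <- X[idx[r, 1], idx[r, 2]]
      if (n == 2) rep(x, 2) else c(2 * x, 0)  # mean preserved, n detections
    })
    wd <- computeWD(BioidScreen(rec), "HEK293")
    W <- wdOracle(X, ndet)
    expect_equal(wd$wd, W[cbind(match(wd$bait, rownames(X)),
                                match(wd$prey, colnames(X)))],
                 tolerance = 1e-9)
  }
})

test_that("WD is increasing in avg_spec and non-increasing in frequency", {
  base <- matrix(c(10, 0, 0, 0, 0, 0), 6, 1,
                 dimnames = list(paste0("B", 1:6), "P1"))
  wd_base <- computeWD(screenFromMatrix(base), "HEK293")$wd[1]
  up <- base; up[1, 1] <- 20
  expect_gt(computeWD(screenFromMatrix(up), "HEK293")$wd[1], wd_base)
  freq <- base; freq[2, 1] <- 10
  wd_freq <- computeWD(screenFromMatrix(freq), "HEK293")
  expect_lte(wd_freq$wd[wd_freq$bait == "B1"], wd_base)
})

test_that("WDS sums across cell lines with absence as zero, symmetrically", {
  wd1 <- data.frame(bait = c("A", "A"), prey = c("P1", "P2"), wd = c(5, 4.2))
  attr(wd1, "cell_line") <- "HEK293"
  wd2 <- data.frame(bait = "A", prey = "P1", wd = 3)
  attr(wd2, "cell_line") <- "HeLa"
  wds <- sumWDS(wd1, wd2)
  expect_equal(wds$wds[wds$prey == "P1"], 8)
  expect_equal(wds$wds[wds$prey == "P2"], 4.2)
  expect_equal(sumWDS(wd2, wd1), wds)
  expect_error(sumWDS(wd1, wd1), "same cell line")
  # single-cell-line mode: WDS = WD
  expect_equal(sumWDS(wd1)$wds, wd1$wd)
})

caax_screen <- function(bait_spec, caax_spec) {
  rec <- data.frame(bait = c("B1", "CAAX"), prey = "P1",
                    cell_line = "HEK293",
                    avg_spec = c(bait_spec, caax_spec), avg_p = 0.99)
  BioidScreen(rec[rec$avg_spec > 0 | rec$bait == "CAAX", ],
              controlBaits = c(caax = "CAAX"))
}

test_that("CAAX ratios divide bait by membrane-control abundance", {
  expect_equal(caaxRatio(caax_screen(17, 10))$caax_ratio, 1.7)
  expect_equal(caaxRatio(caax_screen(3, 6))$caax_ratio, 0.5)
  expect_equal(caaxRatio(caax_screen(5, 0))$caax_ratio, Inf)

  no_caax <- screenFromMatrix(matrix(5, 1, 1, dimnames = list("B1", "P1")))
  expect_error(caaxRatio(no_caax), "CAAX")

  # scale equivariance: multiplying every count leaves ratios unchanged
  expect_equal(caaxRatio(caax_screen(34, 20))$caax_ratio, 1.7)
})

test_that("log2 fold change uses the negative-control mean with pseudocount", {
  mk <- function(bait_spec, ev, gfp) {
    rec <- data.frame(bait = c("B1", "EV", "GFP"), prey = "P1",
                      cell_line = "HEK293",
                      avg_spec = c(bait_spec, ev, gfp), avg_p = 0.99)
    rec <- rec[rec$avg_spec > 0 | rec$bait == "B1", ]
    BioidScreen(rec, controlBaits = c(empty_vector = "EV", gfp = "GFP"))
  }
  expect_equal(log2fcControls(mk(7, 7, 7))$log2fc, 0)
  expect_equal(log2fcControls(mk(15, 0, 0))$log2fc, 4)   # log2(16/1)
  expect_equal(log2fcControls(mk(0, 3, 3))$log2fc, -2)   # log2(1/4)
})

test_that("CBNP rescales by median prey-inventory complexity", {
  # equal inventories: CBNP equals AvgSpec
  X <- matrix(c(4, 7, 5, 2, 9, 1), 3, 2,
              dimnames = list(paste0("B", 1:3), c("P1", "P2")))
  cb <- cbnp(screenFromMatrix(X))
  expect_equal(cb$cbnp, cb$cbnp * 0 + X[cbind(match(cb$bait, rownames(X)),
                                              match(cb$prey, colnames(X)))])

  # a bait identifying twice the median inventory is halved
  n_preys <- 200
  rec <- rbind(
    data.frame(bait = "BIG", prey = sprintf("P%03d", 1:n_preys),
               cell_line = "HEK293", avg_spec = 8, avg_p = 0.99),
    data.frame(bait = c("S1", "S2"),
               prey = rep(sprintf("P%03d", 1:100), each = 2),
               cell_line = "HEK293", avg_spec = 6, avg_p = 0.99))
  cb2 <- cbnp(BioidScreen(rec))
  expect_equal(unique(cb2$cbnp[cb2$bait == "BIG"]), 4)   # 8 * 100/200
  # locality: doubling BIG's counts leaves the small baits unchanged
  rec2 <- rec
  rec2$avg_spec[rec2$bait == "BIG"] <- 16
  cb3 <- cbnp(BioidScreen(rec2))
  expect_equal(cb3$cbnp[cb3$bait != "BIG"], cb2$cbnp[cb2$bait != "BIG"])
})

test_that("the scored table carries every derived quantity coherently", {
  sim <- simulateScreen(simConfig(n_baits = 6, n_preys = 200, seed = 9))
  sc <- scoreInteractions(sim@screen)
  expect_true(all(c("wd", "wds", "caax_ratio", "log2fc", "cbnp")
                  %in% names(sc)))
  expect_false(any(is.na(sc$wd)))
  expect_true(all(sc$wds >= sc$wd - 1e-12))
  # wds = sum of the two cell lines' wd for shared pairs
  key <- paste(sc$bait, sc$prey)
  shared <- names(which(table(key) == 2))
  for (k in head(shared, 5)) {
    rows <- sc[key == k, ]
    expect_equal(unique(rows$wds), sum(rows$wd), tolerance = 1e-9)
  }
})
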