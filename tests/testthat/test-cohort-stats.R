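test_that("position change computes differences and extension-based rates", {
  pc <- positionChange(makeTestRecord("s1", "supine", 6000),
                       makeTestRecord("s1", "extension", 9000))
  vol <- pc[pc$descriptor == "volume_mm3", ]
  expect_equal(vol$difference, 3000)
  expect_equal(vol$rate_pct, 100 * 3000 / 9000, tolerance = 1e-9)

  pcS <- positionChange(makeTestRecord("s1", "supine", 6000),
                        makeTestRecord("s1", "extension", 9000),
                        denominator = "supine")
  expect_equal(pcS$rate_pct[pcS$descriptor == "volume_mm3"], 50)

  same <- positionChange(makeTestRecord("s2", "supine", 5000),
                         makeTestRecord("s2", "extension", 5000))
  expect_true(all(same$difference == 0))
  expect_true(all(same$rate_pct == 0))
})

test_that("position change on Pappus phantom volumes matches the analytics", {
  bent <- phantomVolumeAnalytic(phantomSpec(tubeRadius = 5, pathLength = 80,
                                            bendAngle = 90))
  straight <- phantomVolumeAnalytic(phantomSpec(tubeRadius = 5,
                                                pathLength = 100,
                                                bendAngle = 0))
  pc <- positionChange(makeTestRecord("p1", "supine", bent),
                       makeTestRecord("p1", "extension", straight))
  vol <- pc[pc$descriptor == "volume_mm3", ]
  expect_equal(vol$difference, pi * 25 * 20, tolerance = 1e-9)  # 1570.80
  expect_equal(vol$rate_pct, 20, tolerance = 1e-9)
})

test_that("position change rejects mispaired records, NAs a zero denominator", {
  expect_error(positionChange(makeTestRecord("a", "supine", 1),
                              makeTestRecord("b", "extension", 2)),
               "pairing error")
  expect_error(positionChange(makeTestRecord("a", "extension", 1),
                              makeTestRecord("a", "extension", 2)),
               "pairing error")
  r0 <- makeTestRecord("a", "extension", 2)
  r0@volume <- 0
  pc <- positionChange(makeTestRecord("a", "supine", 1), r0)
  expect_true(is.na(pc$rate_pct[pc$descriptor == "volume_mm3"]))
})

test_that("pooled t-test matches the hand-computed example and edge cases", {
  gc <- groupCompare(c(10, 12, 14), c(20, 22, 24))
  expect_equal(gc$t, -6.124, tolerance = 1e-3)
  expect_equal(gc$df, 4)
  expect_equal(gc$p, 0.0036, tolerance = 0.01)
  expect_equal(sign(gc$t), sign(gc$meanA - gc$meanB))

  eq <- groupCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  flat <- groupCompare(c(2, 2), c(5, 5))
  expect_true(is.infinite(flat$t) && flat$t < 0)
  expect_equal(flat$p, 0)

  expect_error(groupCompare(1, c(1, 2)), "at least 2")
  expect_error(groupCompare(c(1, NA, 2), c(1, 2)), "non-finite")
})

test_that("pooled and Welch variants coincide for balanced equal variances", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  gp <- groupCompare(a, b, "pooled")
  gw <- groupCompare(a, b, "welch")
  expect_equal(gp$t, gw$t, tolerance = 1e-12)
  expect_equal(gp$p, gw$p, tolerance = 1e-12)
  expect_equal(gw$variant, "welch")
})

test_that("pooled t p-values agree with a permutation oracle", {
  set.seed(11)
  for (rep in 1:3) {
    a <- stats::rnorm(8); b <- stats::rnorm(8, mean = 0.8)
    pT <- groupCompare(a, b)$p
    pooled <- c(a, b)
    obs <- abs(mean(a) - mean(b))
    perm <- replicate(5000, {
      idx <- sample.int(16, 8)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    })
    pPerm <- mean(perm >= obs - 1e-12)
    expect_lt(abs(pT - pPerm), 0.05)
  }
})

test_that("noncentral-t power matches frozen values and stats::power.t.test", {
  expect_equal(powerTwoSampleT(0, 20), 0.05, tolerance = 1e-9)
  expect_equal(powerTwoSampleT(c(0.2, 0.5, 0.8), 20),
               c(0.09459, 0.33794, 0.69343), tolerance = 1e-4)
  # independent reference implementation (strict = both rejection tails)
  for (d in c(0.2, 0.5, 0.8, 1.1))
    expect_equal(powerTwoSampleT(d, 20),
                 stats::power.t.test(n = 20, delta = d, sd = 1,
                                     strict = TRUE)$power,
                 tolerance = 1e-8)
  expect_equal(powerTwoSampleT(5, 20), 1, tolerance = 1e-6)
})

test_that("power increases strictly with effect size and sample size", {
  ds <- seq(0.1, 1.2, by = 0.1)
  expect_true(all(diff(powerTwoSampleT(ds, 20)) > 0))
  ns <- seq(5, 50, by = 5)
  pw <- vapply(ns, function(n) powerTwoSampleT(0.5, n), 0)
  expect_true(all(diff(pw) > 0))
  expect_equal(powerTwoSampleT(1e-8, 20), 0.05, tolerance = 1e-6)
})

test_that("cohort summaries report mean, sd and n per group-position cell", {
  recs <- list(makeTestRecord("s1", "supine", 6000),
               makeTestRecord("s2", "supine", 6200),
               makeTestRecord("s3", "supine", 6400),
               makeTestRecord("s1", "extension", 9000),
               makeTestRecord("s2", "extension", 9100),
               makeTestRecord("s3", "extension", 9200))
  sm <- summarizeCohort(recs)
  vol <- sm[sm$descriptor == "volume_mm3" & sm$position == "supine", ]
  expect_equal(vol$mean, 6200)
  expect_equal(vol$sd, 200)
  expect_equal(vol$n, 3L)
  dup <- summarizeCohort(list(makeTestRecord("s1", "supine", 5000),
                              makeTestRecord("s2", "supine", 5000)))
  expect_true(all(dup$sd == 0))
  expect_warning(summarizeCohort(list(makeTestRecord("s1", "supine", 1),
                                      makeTestRecord("s1", "extension", 2),
                                      makeTestRecord("s2", "extension", 3))),
                 "fewer than 2")
})

test_that("two-group comparison report covers positions, differences, rates", {
  recs <- c(
    lapply(1:4, function(i) makeTestRecord(paste0("a", i), "supine",
                                           6000 + 100 * i)),
    lapply(1:4, function(i) makeTestRecord(paste0("a", i), "extension",
                                           9000 + 120 * i)),
    lapply(1:4, function(i) makeTestRecord(paste0("b", i), "supine",
                                           5000 + 110 * i,
                                           group = "B_difficult")),
    lapply(1:4, function(i) makeTestRecord(paste0("b", i), "extension",
                                           6600 + 130 * i,
                                           group = "B_difficult")))
  rep_ <- compareCohorts(recs)
  vol <- rep_[rep_$descriptor == "volume_mm3", ]
  expect_setequal(vol$quantity,
                  c("supine", "extension", "difference", "rate_pct"))
  sup <- vol[vol$quantity == "supine", ]
  expect_equal(sup$mean_a, mean(6000 + 100 * (1:4)))
  expect_equal(sup$mean_b, mean(5000 + 110 * (1:4)))
  expect_true(all(rep_$p >= 0 & rep_$p <= 1))
  expect_true(all(sign(rep_$t[is.finite(rep_$t)]) ==
                    sign((rep_$mean_a - rep_$mean_b)[is.finite(rep_$t)])))
})
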