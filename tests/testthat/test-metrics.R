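test_that("confusion counts match direct tallies", {
  cc <- confusion(c(1, 0), c(1, 0))
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  cc2 <- confusion(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(cc2$fp, 2L)
  expect_equal(cc2$fn, 2L)
  expect_equal(cc2$tp + cc2$tn, 0L)
  set.seed(20)
  p <- random_mask(10); g <- random_mask(10)
  expect_equal(unclass(confusion(p, g))[c("tp", "tn", "fp", "fn")],
               confusion_loop(p, g))
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "shape")
  expect_error(confusion(c(2, 0), c(1, 0)), "binary")
})

test_that("IoU metric handles the standard and degenerate cases", {
  m <- random_mask(6, 0.5)
  if (sum(m) == 0) m[1] <- 1
  expect_equal(iou_metric(m, m), 1)
  cc <- structure(list(tp = 1L, tn = 0L, fp = 0L, fn = 1L),
                  class = "confusion_counts")
  expect_equal(iou_metric(cc), 0.5)
  a <- matrix(c(1, 0, 0, 0), 2, 2); b <- matrix(c(0, 0, 0, 1), 2, 2)
  expect_equal(iou_metric(a, b), 0)
  expect_warning(v <- iou_metric(matrix(0, 2, 2), matrix(0, 2, 2)), "empty")
  expect_equal(v, 1)
  # symmetry
  set.seed(21)
  x <- random_mask(8); y <- random_mask(8)
  expect_equal(suppressWarnings(iou_metric(x, y)),
               suppressWarnings(iou_metric(y, x)))
})

test_that("report reproduces direct formula evaluation", {
  perfect <- structure(list(tp = 50L, tn = 50L, fp = 0L, fn = 0L),
                       class = "confusion_counts")
  rp <- metrics_report(perfect)
  for (m in c("iou", "accuracy", "specificity", "sensitivity", "precision",
              "f1"))
    expect_equal(rp[[m]], 1)

  mixed <- structure(list(tp = 50L, tn = 30L, fp = 10L, fn = 10L),
                     class = "confusion_counts")
  rm_ <- metrics_report(mixed)
  expect_equal(rm_$accuracy, 0.8)
  expect_equal(rm_$sensitivity, 50 / 60, tolerance = 1e-4)
  expect_equal(rm_$specificity, 0.75)
  expect_equal(rm_$precision, 50 / 60, tolerance = 1e-4)
  expect_equal(rm_$f1, 2 * (5 / 6)^2 / (2 * 5 / 6))
})

test_that("zero-denominator metrics are NA, never silently zero", {
  allneg <- confusion(matrix(0, 4, 4), matrix(0, 4, 4))
  rp <- metrics_report(allneg)
  expect_true(is.na(rp$sensitivity))
  expect_true(is.na(rp$precision))
  expect_true(is.na(rp$iou))
  expect_true(is.na(rp$f1))
  expect_equal(rp$accuracy, 1)
  expect_equal(rp$specificity, 1)
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  # a printed percentage pair reproduces its printed F1 at 1 d.p.
  expect_equal(round(f1_score(95.2, 100.0), 1), 97.5)
  expect_equal(f1_score(1, 1), 1)
  expect_true(is.na(f1_score(0, 0)))
  set.seed(22)
  for (i in 1:20) {
    pr <- runif(1); se <- runif(1)
    expect_equal(f1_score(pr, se), 2 * pr * se / (pr + se))
  }
})

test_that("report formulas agree with the loop oracle on random tables", {
  set.seed(23)
  for (i in 1:200) {
    cc <- confusion(random_mask(8, runif(1, 0, 1)),
                    random_mask(8, runif(1, 0, 1)))
    got <- metrics_report(cc)
    want <- metrics_loop(cc)
    for (m in names(want))
      expect_equal(got[[m]], want[[m]], info = m)
  }
})

test_that("zone aggregation takes arithmetic means and order statistics", {
  iou5 <- c(0.804, 0.726, 0.892, 0.759, 0.752)
  agg <- aggregate_zones(iou5)
  expect_equal(round(agg$iou[agg$statistic == "mean"], 3), 0.787)
  expect_equal(agg$iou[agg$statistic == "max"], 0.892)
  expect_equal(agg$iou[agg$statistic == "median"], 0.759)

  # a single report aggregates to itself
  cc <- structure(list(tp = 8L, tn = 4L, fp = 2L, fn = 2L),
                  class = "confusion_counts")
  rp <- metrics_report(cc, zone_id = "frontal", plane = "axial")
  agg1 <- aggregate_zones(list(rp))
  expect_equal(agg1$iou[agg1$statistic == "mean"], rp$iou)
  expect_equal(agg1$f1[agg1$statistic == "max"], rp$f1)

  # mean between min and max for any list
  set.seed(24)
  vals <- runif(7)
  a <- aggregate_zones(vals)
  expect_lte(a$iou[a$statistic == "mean"], a$iou[a$statistic == "max"])
  expect_gte(a$iou[a$statistic == "mean"], a$iou[a$statistic == "min"])
  expect_error(aggregate_zones(list()), "no reports")
})

test_that("metrics CSV writer emits the documented schema", {
  cc <- confusion(random_mask(6), random_mask(6))
  rp <- metrics_report(cc, zone_id = "striatum", plane = "axial")
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(list(rp), path)
  df <- read.csv(path)
  expect_equal(names(df), c("zone", "plane", "iou", "accuracy",
                            "specificity", "sensitivity", "precision",
                            "f1"))
  expect_equal(df$zone, "striatum")
})
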