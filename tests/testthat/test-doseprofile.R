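test_that("creatinine normalization is a homogeneous intensity rescaling", {
  expect_equal(normalize_by_creatinine(1000, 2), 500)
  expect_equal(normalize_by_creatinine(0, 3.7), 0)
  x <- c(100, 250, 0, 80); cr <- c(0.5, 1.2, 2, 0.9)
  expect_equal(normalize_by_creatinine(x, cr * 3),
               normalize_by_creatinine(x, cr) / 3)
  expect_equal(normalize_by_creatinine(x * 7, cr),
               normalize_by_creatinine(x, cr) * 7)
  expect_error(normalize_by_creatinine(10, 0), "positive")
})

test_that("percent of total reproduces the reference composition columns", {
  fixture <- load_fixture("limonene_metabolites")
  pct <- percent_of_total(structure(fixture$hl01_pct, names = fixture$id))
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  # printed column sums to 99.96, so recomputed percents deviate < 0.05
  expect_lt(max(abs(pct - fixture$hl01_pct)), 0.05)
  top3 <- sort(pct, decreasing = TRUE)[1:3]
  expect_equal(unname(round(top3)), c(26, 23, 20))
  expect_equal(names(top3), c("M7-II", "M1", "M12"))

  expect_equal(unname(percent_of_total(c(a = 42))), 100)
  expect_error(percent_of_total(c(a = 0, b = 0)), "zero")

  set.seed(21)
  for (i in 1:10) {
    v <- runif(sample(2:20, 1), 0, 100)
    names(v) <- seq_along(v)
    expect_equal(sum(percent_of_total(v)), 100, tolerance = 1e-9)
  }
})

test_that("fixture percent columns are internally consistent compositions", {
  fixture <- load_fixture("limonene_metabolites")
  expect_true(sum(fixture$hl01_pct) >= 99.9 && sum(fixture$hl01_pct) <= 100.1)
  expect_true(sum(fixture$hl08_pct) >= 99.9 && sum(fixture$hl08_pct) <= 100.1)
})

test_that("two-group comparison routes through Shapiro-Wilk", {
  set.seed(31)
  a <- rnorm(10)
  same <- group_compare(a, a)
  expect_equal(same$test, "t")
  expect_equal(same$p_value, 1, tolerance = 1e-9)

  b <- rnorm(10, mean = 3)          # 3 SD location shift
  shifted <- group_compare(a, b)
  expect_equal(shifted$test, "t")
  expect_lt(shifted$p_value, 0.01)

  heavy <- c(rnorm(17), 40, -35, 60)  # gross outliers fail normality
  expect_lt(stats::shapiro.test(heavy)$p.value, 0.05)
  routed <- group_compare(heavy, rnorm(20))
  expect_equal(routed$test, "wilcoxon")

  expect_error(group_compare(1:2, 1:5), "at least 3")
})

test_that("switching report classifies dose-dependent composition shifts", {
  fixture <- load_fixture("limonene_metabolites")
  lo <- structure(fixture$hl01_pct, names = fixture$id)
  hi <- structure(fixture$hl08_pct, names = fixture$id)
  sw <- switching_report(lo, hi)
  expect_equal(sw$delta[sw$label == "M14"], 6.20 - 3.97, tolerance = 1e-9)
  expect_equal(sw$direction[sw$label == "M14"], "increased")
  expect_equal(sw$direction[sw$label == "M1"], "decreased")
  expect_equal(sw$direction[sw$label == "M15"], "increased") # 3.30 -> 5.77
  expect_equal(sw$direction[sw$label == "M9-I"], "increased") # 3.71 -> 7.44

  # identical profiles are all stable with zero deltas
  same <- switching_report(lo, lo)
  expect_true(all(same$direction == "stable"))
  expect_true(all(same$delta == 0))

  # deltas of two true compositions sum to zero
  sw_norm <- switching_report(percent_of_total(lo), percent_of_total(hi))
  expect_equal(sum(sw_norm$delta), 0, tolerance = 1e-9)

  expect_error(switching_report(lo, hi[-1]), "same metabolite set")
})

test_that("dose arithmetic: percent loss and human-equivalent doses", {
  expect_equal(percent_loss(0.8, 0.67), 16.25)
  expect_equal(percent_loss(0.1, 0.10), 0)
  expect_equal(percent_loss(3.3, 3.3), 0)
  expect_error(percent_loss(0, 1), "positive")

  expect_equal(round(human_equivalent_dose(90), 1), 7.3)
  expect_equal(round(human_equivalent_dose(580), 1), 47.0)
  expect_equal(human_equivalent_dose(0), 0)
  expect_error(human_equivalent_dose(10, km_human = 0), "positive")
})

test_that("profile table summarizes creatinine-normalized groups", {
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     group = rep(c("A", "B"), each = 2), tissue = "urine",
                     creatinine = c(1, 2, 1, 4), stringsAsFactors = FALSE)
  feats <- data.frame(feature_id = c("f1", "f2"), mz = c(300, 310),
                      rt = c(1, 2),
                      s1 = c(100, 300), s2 = c(200, 600),
                      s3 = c(50, 0), s4 = c(200, 0))
  asg <- data.frame(feature_id = c("f1", "f2"), label = c("x", "y"),
                    stringsAsFactors = FALSE)
  prof <- profile_table(feats, meta, asg)
  a_x <- prof[prof$group == "A" & prof$label == "x", ]
  expect_equal(a_x$mean_norm, mean(c(100 / 1, 200 / 2)))
  expect_equal(sum(prof$percent[prof$group == "A"]), 100, tolerance = 1e-9)
  # y is absent in group B: contributes 0 and the composition is all x
  expect_equal(prof$percent[prof$group == "B" & prof$label == "y"], 0)
  expect_equal(prof$percent[prof$group == "B" & prof$label == "x"], 100)
})
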