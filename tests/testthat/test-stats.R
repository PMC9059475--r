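test_that("percent difference matches hand values and its inverse law", {
  expect_equal(percent_difference(27, 18), 50)
  expect_equal(round(percent_difference(0.57, 0.44), 1), 29.5)
  expect_equal(percent_difference(3, 3), 0)
  d1 <- percent_difference(7, 4)
  d2 <- percent_difference(4, 7)
  expect_equal((1 + d1 / 100) * (1 + d2 / 100), 1, tolerance = 1e-12)
  expect_error(percent_difference(1, 0),
               class = "osteomech_undefined_metric")
})

test_that("pooled t-test matches the closed-form oracle", {
  # x = {1,2,3}, y = {4,5,6}: pooled SD 1, SE sqrt(2/3), t = -3/0.8165
  tt <- ttest_unpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(tt$df, 4)
  # symmetry
  ts <- ttest_unpaired(c(4, 5, 6), c(1, 2, 3))
  expect_equal(ts$t, -tt$t)
  expect_equal(ts$p, tt$p)
  # identical groups
  same <- ttest_unpaired(c(2, 2), c(2, 2))
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  deg <- ttest_unpaired(c(2, 2), c(3, 3))
  expect_equal(deg$p, 0)
  expect_error(ttest_unpaired(1, c(1, 2)), class = "osteomech_data_error")
})

test_that("t-test power matches the analytic oracle for a 2-sigma shift", {
  set.seed(12)
  hits <- mean(replicate(200, {
    ttest_unpaired(rnorm(10, 0, 1), rnorm(10, 2, 1))$p < 0.01
  }))
  pw <- stats::power.t.test(n = 10, delta = 2, sd = 1,
                            sig.level = 0.01)$power
  se <- sqrt(pw * (1 - pw) / 200)
  expect_lt(abs(hits - pw), 3 * se + 0.01)
  expect_gte(hits, 0.85)
})

test_that("one-way ANOVA matches t^2 and a brute-force oracle", {
  x <- c(1.2, 1.9, 2.4, 3.1)
  y <- c(2.2, 2.8, 3.9)
  an <- anova_oneway(list(x, y))
  tt <- ttest_unpaired(x, y)
  expect_equal(an$f, tt$t^2, tolerance = 1e-10)

  g <- list(c(1, 2, 3), c(2, 4, 6), c(5, 5, 8))
  an3 <- anova_oneway(g)
  vals <- unlist(g)
  gm <- mean(vals)
  ss_b <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2,
                     numeric(1)))
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  f_oracle <- (ss_b / 2) / (ss_w / 6)
  expect_equal(an3$f, f_oracle, tolerance = 1e-10)

  const <- anova_oneway(list(c(1, 1), c(1, 1)))
  expect_true(const$degenerate)
  expect_error(anova_oneway(list(1:3)), class = "osteomech_data_error")
})

test_that("ddCt fold changes follow 2^(-ddCt) and its invariances", {
  rec <- data.frame(sample_id = c("c1", "s1"),
                    ct_target = c(27, 25),
                    ct_reference = c(20, 20),
                    group = c("calibrator", "test"))
  out <- ddct_fold_change(rec)
  expect_equal(out$ddct[2], -2)
  expect_equal(out$fold_change[2], 4)
  expect_equal(out$fold_change[1], 1)   # calibrator relative to itself
  # adding a constant to every reference Ct changes nothing
  rec2 <- rec
  rec2$ct_reference <- rec$ct_reference + 3
  expect_equal(ddct_fold_change(rec2)$fold_change, out$fold_change)
  rec3 <- rec
  rec3$group <- "test"
  expect_error(ddct_fold_change(rec3), class = "osteomech_config_error")

  set.seed(5)
  tab <- data.frame(sample_id = 1:40,
                    ct_target = c(rnorm(20, 26, 0.2), rnorm(20, 25, 0.2)),
                    ct_reference = rnorm(40, 20, 0.2),
                    group = rep(c("calibrator", "test"), each = 20))
  fc <- ddct_fold_change(tab)
  expect_lt(abs(mean(fc$fold_change[tab$group == "test"]) / 2 - 1), 0.15)
})

test_that("ratio metric and report assembly behave", {
  r <- ratio_metric(c(2, 2, 2), c(1, 1, 1), n_boot = 200, seed = 1)
  expect_equal(r$ratio, 2)
  expect_equal(ratio_metric(c(3, 3), c(3, 3), n_boot = 100)$ratio, 1)
  expect_error(ratio_metric(c(1, 2), c(1, -1)),
               class = "osteomech_undefined_metric")

  morpho <- c("bvtv", "bstv", "tb_n", "tb_th", "tb_sp", "smi", "ct_th")
  metrics <- setNames(lapply(morpho, function(m)
    list(wt = c(1, 1.1, 0.9), ko = c(0.5, 0.45, 0.55))), morpho)
  rep <- build_report(metrics, provenance = list(seed = 1))
  expect_equal(nrow(rep), 7)
  expect_equal(rep$metric, morpho)
  expect_true(all(rep$percent_difference > 0))
  expect_equal(attr(rep, "provenance")$seed, 1)
  expect_error(build_report(list()),
               class = "osteomech_validation_error")
})

test_that("the CLI round-trips a bending analysis", {
  cv <- synth_bending_curve(noise_sd = 0)
  pc <- tempfile(fileext = ".csv")
  write_bending_csv(cv, pc)
  out <- tempfile(fileext = ".json")
  res <- osteomech_cli(c("bend", "--in", pc, "--out", out))
  expect_true(file.exists(out))
  back <- jsonlite::read_json(out)
  expect_lt(abs(back$stiffness / 120 - 1), 0.02)
})
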