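test_that("peak quality scores Gaussian shapes high and noise low", {
  rt <- seq(0, 1, length.out = 25)
  g <- 100 * exp(-(rt - 0.5)^2 / (2 * 0.1^2))
  expect_gte(peak_quality(rt, g), 0.99)
  expect_equal(peak_quality(rt[1:2], g[1:2]), 0)
  set.seed(13)
  low <- sum(vapply(1:100, function(i) {
    peak_quality(rt, runif(25, 0, 100)) < 0.6
  }, logical(1)))
  expect_gte(low, 95)
})

test_that("feature detection infers charge from isotope spacing", {
  run <- blank_run()
  run <- spike_feature(run, 600.0, rt = 1.0, height = 2000, charge = 2)
  f <- detect_features(run, npd_params())
  expect_equal(nrow(f), 1)
  expect_equal(f$charge, 2L)
  expect_equal(f$mz, 600.0, tolerance = 1e-3)
  expect_gt(f$quality, 0.9)
})

test_that("singly charged and sub-threshold features are dropped", {
  run1 <- spike_feature(blank_run(), 700.0, rt = 1.2, height = 2000,
                        charge = 1)
  f1 <- detect_features(run1, npd_params(exclude_charge1 = TRUE))
  expect_equal(nrow(f1), 0)
  f1b <- detect_features(run1, npd_params(exclude_charge1 = FALSE))
  expect_equal(nrow(f1b), 1)
  run2 <- spike_feature(blank_run(), 700.0, rt = 1.2, height = 450,
                        charge = 2)
  expect_equal(nrow(detect_features(run2, npd_params())), 0)
})

test_that("feature matching is greedy on ppm then RT within the gates", {
  a <- data.frame(mz = c(500, 800), rt = c(1, 2), charge = 2,
                  height = 1000, area = 100, quality = 0.9)
  p <- match_features(a, a, npd_params())
  expect_true(all(!is.na(p$test_idx) & !is.na(p$ref_idx)))
  # RT shift beyond 0.2 min breaks the pair
  b <- a
  b$rt <- b$rt + 0.3
  p2 <- match_features(b, a, npd_params())
  expect_true(all(is.na(p2$test_idx) | is.na(p2$ref_idx)))
  # two test candidates for one reference: closer ppm wins
  t2 <- data.frame(mz = c(500.000, 500.004), rt = c(1, 1), charge = 2,
                   height = 1000, area = 100, quality = 0.9)
  r1 <- data.frame(mz = 500.001, rt = 1, charge = 2, height = 1000,
                   area = 100, quality = 0.9)
  p3 <- match_features(t2, r1, npd_params())
  matched <- p3[!is.na(p3$test_idx) & !is.na(p3$ref_idx), ]
  expect_equal(matched$test_idx, 1)
  expect_equal(sum(is.na(p3$ref_idx)), 1)
})

test_that("classification applies the height/quality/fold rules", {
  tf <- data.frame(mz = 600, rt = 1, charge = 2, height = 600, area = 50,
                   quality = 0.8)
  rf <- tf[0, ]
  p <- match_features(tf, rf, npd_params())
  expect_equal(classify_features(p, tf, rf, npd_params())$category, "new")
  # matched pair, targeted fold 5 >= 3 -> changed
  tf2 <- tf
  tf2$area <- 50
  rf2 <- tf
  rf2$area <- 10
  p2 <- match_features(tf2, rf2, npd_params())
  expect_equal(
    classify_features(p2, tf2, rf2, npd_params(), "targeted")$category,
    "changed")
  # untargeted: fold 1.5 < 20 -> unchanged
  tf3 <- tf
  tf3$area <- 15
  expect_equal(
    classify_features(match_features(tf3, rf2, npd_params()), tf3, rf2,
                      npd_params(), "untargeted")$category,
    "unchanged")
})

test_that("classification equals the literal rule-table oracle", {
  set.seed(17)
  params <- npd_params()
  for (i in 1:30) {
    test <- random_features(sample(0:20, 1))
    ref <- random_features(sample(0:20, 1))
    pairs <- match_features(test, ref, params)
    mode <- sample(c("untargeted", "targeted"), 1)
    got <- classify_features(pairs, test, ref, params, mode)
    expect_equal(got$category, oracle_classify(pairs, test, ref, params,
                                               mode))
  }
})

test_that("swapping test and reference maps new to missing exactly", {
  set.seed(19)
  test <- random_features(8)
  test$height <- test$height + 600
  test$quality <- 0.9
  ref <- random_features(5)
  ref$height <- ref$height + 600
  ref$quality <- 0.9
  params <- npd_params()
  fwd <- classify_features(match_features(test, ref, params), test, ref,
                           params)
  rev <- classify_features(match_features(ref, test, params), ref, test,
                           params)
  expect_equal(sum(fwd$category == "new"), sum(rev$category == "missing"))
  expect_equal(sum(fwd$category == "missing"), sum(rev$category == "new"))
})

test_that("a drifting oxidised species reproduces the targeted flag series", {
  base <- blank_run(run_id = "ref")
  mz_ox <- 520.27
  mz_other <- 880.44
  mk <- function(scale, id) {
    r <- blank_run(run_id = id)
    r <- spike_feature(r, mz_other, rt = 2.2, height = 3000, charge = 2)
    spike_feature(r, mz_ox, rt = 1.1, height = 800 * scale, charge = 2)
  }
  ref <- mk(1, "ref")
  flags <- lapply(c(1, 3.5, 4), function(sc)
    npd_compare(mk(sc, "t"), ref, npd_params(), mode = "targeted"))
  ox_flag <- vapply(flags, function(fl)
    fl$category[abs(fl$mz - mz_ox) < 0.1], character(1))
  expect_equal(ox_flag, c("unchanged", "changed", "changed"))
  # the stable species is never flagged
  other_flag <- vapply(flags, function(fl)
    fl$category[abs(fl$mz - mz_other) < 0.1], character(1))
  expect_equal(unique(other_flag), "unchanged")
})
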