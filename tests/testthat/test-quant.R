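fake_measurement <- function(area, detected = TRUE, glycan_name = NULL,
                             id = paste0("sp", area)) {
  glycan <- if (!is.null(glycan_name)) {
    glycan_composition(glycan_name, H = 3, N = 4)
  }
  sp <- structure(list(species_id = id, glycan = glycan,
                       peptide = list(chain_id = "heavy", start = 1,
                                      end = 5, sequence = "GGGGK")),
                  class = "target_species")
  structure(list(species = sp, total_area = area, detected = detected),
            class = "species_measurement")
}

test_that("smoothing preserves identity, constants and total signal", {
  tr <- make_trace(seq(0, 1, length.out = 21), c(rep(0, 10), 100, rep(0, 10)))
  expect_identical(smooth_trace(tr, 0), tr)
  cst <- make_trace(seq(0, 1, length.out = 15), rep(7, 15))
  expect_equal(smooth_trace(cst, 1)$intensity, rep(7, 15), tolerance = 1e-9)
  sm <- smooth_trace(tr, 1)
  expect_lt(max(sm$intensity), 100)  # spike is spread out
  expect_equal(sum(sm$intensity), 100, tolerance = 1e-3)
})

test_that("noise estimate is the mean of the lowest percentage of points", {
  tr <- make_trace(1:10, 1:10)
  expect_equal(estimate_noise(tr, 40), 2.5)
  expect_equal(estimate_noise(make_trace(1:5, rep(0, 5)), 40), 0)
  expect_equal(estimate_noise(make_trace(1:5, rep(3, 5)), 40), 3)
  expect_error(estimate_noise(make_trace(numeric(), numeric())), "empty")
})

test_that("a flat trace yields no peaks and a clean Gaussian is integrated", {
  expect_equal(nrow(detect_and_integrate(make_trace(1:50, rep(0, 50)))), 0)
  rt <- seq(0, 2, by = 0.01)
  set.seed(5)
  h <- 1000
  sig <- 0.05
  y <- h * exp(-(rt - 1)^2 / (2 * sig^2)) + abs(rnorm(length(rt), 0, 1))
  pk <- detect_and_integrate(make_trace(rt, y))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$rt_apex, 1, tolerance = 0.02)
  expect_equal(pk$area, h * sig * sqrt(2 * pi), tolerance = 0.02)
})

test_that("valley splitting separates resolved peaks", {
  rt <- seq(0, 2, by = 0.01)
  y <- 900 * exp(-(rt - 0.7)^2 / (2 * 0.06^2)) +
    900 * exp(-(rt - 1.3)^2 / (2 * 0.06^2))
  # valley is ~1/3 of the apexes: ratio 3 >= splitting 2 -> two peaks
  y <- y + 300 * exp(-(rt - 1)^2 / (2 * 0.25^2))
  pk <- detect_and_integrate(make_trace(rt, y))
  expect_equal(nrow(pk), 2)
})

test_that("integration equals the exhaustive local-extrema oracle", {
  set.seed(6)
  params <- integration_params()
  for (i in 1:15) {
    n <- sample(30:200, 1)
    rt <- seq(0, n - 1) * 0.02
    y <- numeric(n)
    for (p in seq_len(sample(1:4, 1))) {
      y <- y + runif(1, 60, 2000) *
        exp(-(rt - runif(1, 0, max(rt)))^2 / (2 * runif(1, 0.05, 0.2)^2))
    }
    y <- y + abs(rnorm(n, 0, 3))
    got <- detect_and_integrate(make_trace(rt, y), params)
    want <- oracle_integrate(make_trace(rt, y), params)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$rt_apex, want$rt_apex, tolerance = 1e-9)
      expect_equal(got$area, want$area, tolerance = 1e-9)
      expect_equal(got$height, want$height, tolerance = 1e-9)
    }
  }
})

test_that("doubling intensities doubles areas (scale invariance)", {
  rt <- seq(0, 2, by = 0.01)
  set.seed(8)
  y <- 800 * exp(-(rt - 1)^2 / (2 * 0.07^2)) + abs(rnorm(length(rt), 0, 2))
  a1 <- detect_and_integrate(make_trace(rt, y))$area
  a2 <- detect_and_integrate(make_trace(rt, 2 * y))$area
  expect_equal(a2, 2 * a1, tolerance = 1e-9)
})

test_that("relative abundance follows the modified/total-area formula", {
  res <- pqa_relative_abundance(list(fake_measurement(25, id = "m")),
                                list(fake_measurement(25, id = "m"),
                                     fake_measurement(75, id = "u")))
  expect_equal(res$relative_abundance, 25)
  res0 <- pqa_relative_abundance(list(fake_measurement(0, id = "m")),
                                 list(fake_measurement(0, id = "m"),
                                      fake_measurement(100, id = "u")))
  expect_equal(res0$relative_abundance, 0)
  # denominator holds every site form: oxidised 10 over {10, 40, 50}
  res3 <- pqa_relative_abundance(
    list(fake_measurement(10, id = "ox")),
    list(fake_measurement(10, id = "ox"), fake_measurement(40, id = "un"),
         fake_measurement(50, id = "deam")))
  expect_equal(res3$relative_abundance, 10)
  expect_error(pqa_relative_abundance(list(fake_measurement(1, id = "x")),
                                      list(fake_measurement(2, id = "y"))),
               "not contained")
  # zero denominator is flagged, not an error
  rz <- pqa_relative_abundance(list(fake_measurement(0, id = "m")),
                               list(fake_measurement(0, id = "m")))
  expect_equal(rz$status, "not_detected")
  expect_equal(rz$flag, "denominator_zero")
})

test_that("abundances stay in range and statuses follow the thresholds", {
  res <- pqa_relative_abundance(list(fake_measurement(0.4, id = "m")),
                                list(fake_measurement(0.4, id = "m"),
                                     fake_measurement(99.6, id = "u")))
  expect_true(res$relative_abundance >= 0 && res$relative_abundance <= 100)
  expect_equal(res$status, "detected")
})

test_that("glycoform profiles are percentages over detected forms", {
  prof <- glycoform_profile(list(fake_measurement(60, glycan_name = "FA2"),
                                 fake_measurement(40, glycan_name = "FA2G1")))
  expect_equal(unname(prof), c(60, 40))
  expect_equal(sum(prof), 100, tolerance = 1e-6)
  single <- glycoform_profile(list(fake_measurement(5, glycan_name = "M5")))
  expect_equal(unname(single), 100)
  # aglycosylated counts as a form; undetected forms are excluded
  prof2 <- glycoform_profile(list(
    fake_measurement(90, glycan_name = "FA2"),
    fake_measurement(10),                       # aglycosylated
    fake_measurement(33, glycan_name = "M5", detected = FALSE)))
  expect_setequal(names(prof2), c("FA2", "Aglycosylated"))
  expect_equal(sum(prof2), 100, tolerance = 1e-6)
  expect_error(glycoform_profile(list(
    fake_measurement(1, detected = FALSE))), "no glycoform")
})

test_that("MS/MS score is ten times the matched-ion fraction", {
  sp <- target_species(list(chain_id = "heavy", start = 1, end = 5,
                            sequence = "AVGLK"), charges = 2)
  ions <- fragment_ions(sp, 1)
  prec <- mz_from_mass(sp$neutral_mono_mass, 2)
  full <- spectrum_record(2L, 1, ions$mz, rep(100, nrow(ions)),
                          precursor_mz = prec)
  expect_equal(msms_match_score(full, sp)$score, 10)
  empty <- spectrum_record(2L, 1, numeric(), numeric(),
                           precursor_mz = prec)
  expect_equal(msms_match_score(empty, sp)$score, 0)
  half <- spectrum_record(2L, 1, ions$mz[seq(1, nrow(ions), by = 2)],
                          rep(100, ceiling(nrow(ions) / 2)),
                          precursor_mz = prec)
  expect_equal(msms_match_score(half, sp)$score, 5)
  # wrong precursor is rejected
  wrong <- spectrum_record(2L, 1, ions$mz, rep(100, nrow(ions)),
                           precursor_mz = prec + 1)
  expect_error(msms_match_score(wrong, sp), "precursor")
})

test_that("sequence coverage counts residues covered by validated species", {
  ch <- chain_sequence("heavy", paste(rep("AVGLTYSDEK", 1), collapse = ""))
  sp_full <- target_species(list(chain_id = "heavy", start = 1, end = 10,
                                 sequence = ch$residues))
  expect_equal(unname(sequence_coverage(list(sp_full), list(ch))), 100)
  expect_equal(unname(sequence_coverage(list(), list(ch))), 0)
  sp_half <- target_species(list(chain_id = "heavy", start = 1, end = 5,
                                 sequence = "AVGLT"))
  expect_equal(unname(sequence_coverage(list(sp_half), list(ch))), 50)
})

test_that("species below the intensity floor are not detected", {
  run <- blank_run()
  sp <- target_species(list(chain_id = "heavy", start = 1, end = 9,
                            sequence = "AVSGMDELK"), charges = 2,
                       expected_rt = 1.35)
  mz <- mz_from_mass(sp$neutral_mono_mass, 2)
  # absent entirely
  m0 <- measure_species(run, sp)
  expect_equal(m0$total_area, 0)
  expect_false(m0$detected)
  # present but apex height 40 < 50 counts
  low <- spike_feature(run, mz, rt = 1.35, height = 40)
  m40 <- measure_species(low, sp)
  expect_false(m40$detected)
  # present at height 400 -> detected
  hi <- spike_feature(run, mz, rt = 1.35, height = 400)
  m400 <- measure_species(hi, sp)
  expect_true(m400$detected)
  expect_gt(m400$total_area, 0)
})
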