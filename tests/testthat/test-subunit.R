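fake_recon <- function(masses, areas) {
  structure(list(mass_axis = seq(20000, 30000, by = 5),
                 intensity = numeric(2001),
                 peaks = data.frame(mass = masses, height = areas,
                                    area = areas, sn = 100)),
            class = "reconstructed_spectrum")
}

test_that("single-species deconvolution recovers the mass on target", {
  sp <- simulate_subunit_spectrum(23000, 0, seed = 4)
  rec <- deconvolve(sp, deconv_params(mass_range = c(20000, 26000)))
  expect_equal(nrow(rec$peaks), 1)
  expect_lt(abs(rec$peaks$mass - 23000), 1)
})

test_that("an empty spectrum reconstructs to nothing", {
  empty <- spectrum_record(1L, 0, numeric(), numeric())
  rec <- deconvolve(empty, deconv_params(mass_range = c(20000, 26000)))
  expect_equal(nrow(rec$peaks), 0)
  expect_true(all(rec$intensity == 0))
})

test_that("a 95:5 two-species envelope recovers the minor fraction", {
  sp <- simulate_subunit_spectrum(23000, 0.05, seed = 1)
  rec <- deconvolve(sp, deconv_params(mass_range = c(20000, 26000)))
  expect_gte(nrow(rec$peaks), 2)
  m <- match_subunit_species(rec, glycation_species_table(23000))
  expect_setequal(m$name, c("LC", "LC+1gly"))
  frac <- 100 * m$area[m$name == "LC+1gly"] / sum(m$area)
  expect_lt(abs(frac - 5), 0.5)
})

test_that("harmonic artifacts stay below 5% of the true species", {
  sp <- simulate_subunit_spectrum(24000, 0, seed = 9)
  rec <- deconvolve(sp, deconv_params(mass_range = c(10000, 50000)))
  main <- rec$peaks[which.min(abs(rec$peaks$mass - 24000)), ]
  expect_lt(abs(main$mass - 24000), 1)
  for (harm in c(12000, 48000)) {
    near <- rec$peaks[abs(rec$peaks$mass - harm) < 100, ]
    if (nrow(near)) expect_lt(max(near$height), 0.05 * main$height)
  }
})

test_that("reconstructed intensity is conserved against the raw envelope", {
  sp <- simulate_subunit_spectrum(23000, 0.05, seed = 2, noise_sd = 0)
  rec <- deconvolve(sp, deconv_params(mass_range = c(20000, 26000)))
  raw_area <- sum(sp$intensity) * 0.05  # grid step
  expect_lt(abs(sum(rec$peaks$area) - raw_area) / raw_area, 0.1)
})

test_that("species matching respects the +/- 5 Da tolerance", {
  rec <- fake_recon(c(23003), c(100))
  th <- data.frame(name = "LC", avg_mass = 23000)
  m <- match_subunit_species(rec, th, match_tol = 5)
  expect_equal(nrow(m), 1)
  rec2 <- fake_recon(c(23008), c(100))
  expect_equal(nrow(match_subunit_species(rec2, th, match_tol = 5)), 0)
  # two theoretical species claiming one peak: closer wins with a warning
  th2 <- data.frame(name = c("A", "B"), avg_mass = c(23001, 23003.5))
  expect_warning(m2 <- match_subunit_species(rec, th2, match_tol = 5),
                 "multiple species")
  expect_equal(m2$name, "B")
})

test_that("the glycated species table applies the hexose mass increase", {
  th <- glycation_species_table(23000, max_glycations = 2)
  expect_equal(th$avg_mass, c(23000, 23162.0528, 23324.1056))
  expect_equal(th$n_glycations, 0:2)
})

test_that("glycation percent counts all glycated stoichiometries", {
  m <- data.frame(name = c("LC", "LC+1gly"), area = c(95, 5),
                  n_glycations = c(0, 1))
  expect_equal(glycation_percent(m), 5)
  expect_equal(glycation_percent(data.frame(name = "LC", area = 100,
                                            n_glycations = 0)), 0)
  m3 <- data.frame(name = c("LC", "LC+1gly", "LC+2gly"),
                   area = c(90, 8, 2), n_glycations = 0:2)
  expect_equal(glycation_percent(m3), 10)
  expect_error(glycation_percent(m3[0, ]), "no light-chain")
})

test_that("two-species recovery holds across seeds and masses", {
  set.seed(99)
  for (s in 1:5) {
    M <- runif(1, 20000, 30000)
    fr <- runif(1, 0.02, 0.10)
    sp <- simulate_subunit_spectrum(M, fr, seed = s)
    rec <- deconvolve(sp, deconv_params(mass_range = c(M - 3000, M + 3000)))
    m <- match_subunit_species(rec, glycation_species_table(M))
    expect_setequal(m$name, c("LC", "LC+1gly"))
    expect_lt(max(abs(m$measured_mass - m$theoretical_mass)), 1)
    g <- glycation_percent(m)
    expect_lt(abs(g - 100 * fr), 0.5)
  }
})
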