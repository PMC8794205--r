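test_that("chain FASTA parsing tags chains and validates residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">light lc", "DIQ", ">heavy hc", "EVQ"), f)
  chains <- parse_chain_fasta(f)
  expect_length(chains, 2)
  expect_equal(chains[[1]]$chain_id, "light")
  expect_equal(chains[[2]]$chain_id, "heavy")
  expect_equal(chains[[1]]$residues, "DIQ")

  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">heavy", "QVZ"), f2)
  expect_error(parse_chain_fasta(f2), "position 3")

  f3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chainA", "QVQ"), f3)
  expect_error(parse_chain_fasta(f3), "light")
})

test_that("tryptic digestion follows the Keil rule", {
  d <- digest(chain_sequence("heavy", "AKRGCK"), max_missed = 1)
  expect_setequal(d$sequence, c("AK", "R", "GCK", "AKR", "RGCK"))
  expect_equal(d$start[d$sequence == "GCK"], 4)
  expect_equal(d$end[d$sequence == "GCK"], 6)
  # no cleavage before proline
  expect_equal(digest(chain_sequence("heavy", "AKPGR"), 1)$sequence,
               "AKPGR")
  # no cleavage sites at all
  expect_equal(digest(chain_sequence("heavy", "GGG"), 1)$sequence, "GGG")
})

test_that("digestion equals the brute-force substring oracle", {
  set.seed(11)
  for (i in 1:25) {
    seq <- random_chain(sample(5:50, 1))
    mm <- sample(0:2, 1)
    got <- digest(chain_sequence("heavy", seq), mm)
    got <- got[order(got$start, got$end), ]
    want <- oracle_digest(seq, mm)
    expect_equal(got$start, want$start, info = seq)
    expect_equal(got$end, want$end, info = seq)
    expect_equal(got$sequence, want$sequence, info = seq)
    expect_equal(got$missed_cleavages, want$missed_cleavages, info = seq)
  }
})

test_that("panel enumeration covers terminal and internal sites", {
  heavy <- chain_sequence("heavy", "QVQLMGGKTTPGK")
  # the default panel includes PyroGlu from E, which this chain lacks
  expect_warning(panel <- enumerate_pqa_species(list(heavy)),
                 "targets no residue")
  ids <- vapply(panel, function(p) p$pqa_id, character(1))
  # N-terminal pyroGlu on the position-1 Q
  pg <- panel[[grep("PyroGluQ", ids)]]
  expect_equal(pg$site$position, 1)
  # C-terminal lysine loss
  ll <- panel[[grep("LysLoss", ids)]]
  expect_equal(ll$site$position, nchar(heavy$residues))
  # oxidation of the single internal methionine
  ox <- panel[grep("Oxidation", ids)]
  expect_length(ox, 1)
  expect_equal(ox[[1]]$site$position, 5)
})

test_that("a toy chain with one methionine yields exactly one oxidation PQA", {
  ch <- chain_sequence("heavy", "GGMGGK")
  panel <- enumerate_pqa_species(
    list(ch),
    modifications = list(modification_def("Oxidation", "M", 15.994915)))
  expect_length(panel, 1)
  expect_equal(panel[[1]]$site$position, 3)
  # the denominator contains the unmodified and the modified form once each
  expect_length(panel[[1]]$all_species, 2)
  expect_length(panel[[1]]$modified_species, 1)
})

test_that("enumeration on a chain with no eligible residues is empty", {
  ch <- chain_sequence("heavy", "GGAGGL")
  expect_warning(
    panel <- enumerate_pqa_species(
      list(ch),
      modifications = list(modification_def("Oxidation", "M", 15.994915))),
    "skipped")
  expect_length(panel, 0)
})

test_that("glycoform definitions require a valid N-X-S/T sequon", {
  ch <- chain_sequence("heavy", "EEQYNSTYR")
  panel <- enumerate_pqa_species(
    list(ch), modifications = list(), glycans = default_glycan_panel(),
    glyco_sites = list(list(chain_id = "heavy", position = 5)))
  expect_length(panel, 1)
  expect_length(panel[[1]]$all_species, 9)  # 8 glycoforms + aglycosylated
  expect_error(enumerate_pqa_species(
    list(ch), modifications = list(), glycans = default_glycan_panel(),
    glyco_sites = list(list(chain_id = "heavy", position = 2))),
    "sequon")
})

test_that("fragment ions match residue-sum values and counts", {
  sp <- target_species(list(chain_id = "heavy", start = 1, end = 2,
                            sequence = "AG"))
  ions <- fragment_ions(sp, 1)
  expect_equal(ions$mz[ions$series == "b" & ions$index == 1], 72.04439,
               tolerance = 1e-5)
  expect_equal(ions$mz[ions$series == "y" & ions$index == 1], 76.03931,
               tolerance = 1e-5)
  # a peptide of length n has 2(n-1) singly charged ions
  sp2 <- target_species(list(chain_id = "heavy", start = 1, end = 7,
                             sequence = "AVGLTYK"))
  expect_equal(nrow(fragment_ions(sp2, 1)), 12)
})

test_that("site modifications shift only the fragments containing them", {
  pep <- list(chain_id = "heavy", start = 1, end = 4, sequence = "GMGK")
  ox <- modification_def("Oxidation", "M", 15.994915)
  plain <- fragment_ions(target_species(pep), 1)
  modded <- fragment_ions(
    target_species(pep, site_mods = list(list(position = 2, mod = ox))), 1)
  d <- modded$mz - plain$mz
  # b1 excludes the M; b2, b3 include it
  expect_equal(d[modded$series == "b" & modded$index == 1], 0)
  expect_equal(d[modded$series == "b" & modded$index == 2], 15.994915,
               tolerance = 1e-6)
  # y1, y2 exclude the M; y3 includes it
  expect_equal(d[modded$series == "y" & modded$index == 2], 0)
  expect_equal(d[modded$series == "y" & modded$index == 3], 15.994915,
               tolerance = 1e-6)
})
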