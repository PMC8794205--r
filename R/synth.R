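# Seeded generator of ground-truthed peptide-map and subunit LC-MS runs.
# Every simulated quantity is recorded so downstream recovery can be
# checked against known truth.

#' Acquisition settings for simulated runs
#'
#' Defaults emulate a QTOF DDA peptide-map acquisition: 1.35 s scan cycle,
#' survey range 300-1800 m/z.
#'
#' @param scan_interval_s MS1 scan interval in seconds.
#' @param gradient_min Acquisition length in minutes.
#' @param mz_range Survey m/z range.
#' @param include_ms2 Also emit one MS2 spectrum per species at its apex.
#' @param noise_sd SD of the additive intensity noise (counts); noise
#'   magnitudes are drawn as `|N(0, sd)|`.
#' @param n_noise_peaks Random noise centroids added per MS1 spectrum.
#' @return A `sim_config` list.
#' @export
sim_config <- function(scan_interval_s = 1.35, gradient_min = 8,
                       mz_range = c(300, 1800), include_ms2 = FALSE,
                       noise_sd = 5, n_noise_peaks = 40) {
  stopifnot(scan_interval_s > 0, gradient_min > 0, noise_sd >= 0)
  structure(list(scan_interval_s = scan_interval_s,
                 gradient_min = gradient_min, mz_range = mz_range,
                 include_ms2 = include_ms2, noise_sd = noise_sd,
                 n_noise_peaks = n_noise_peaks),
            class = "sim_config")
}

#' Build a ground truth for a PQA panel
#'
#' Assigns every species of the panel a true fractional abundance within
#' its backbone group, a collision-free retention time (minimum spacing
#' 0.5 min), a chromatographic width, a total ion count, and charge-state
#' weights. Deterministic for a given seed.
#'
#' @param panel List of `pqa_definition` objects (see
#'   [enumerate_pqa_species()]). Backbone peptides are assumed distinct
#'   across definitions.
#' @param levels Named vector: `pqa_id` -> true modified fraction in
#'   `[0, 1]`. Definitions without an entry get level 0 (modified species
#'   absent).
#' @param glyco Optional named vector of glycoform fractions (including
#'   `"Aglycosylated"`) for glycoform definitions; must sum to 1.
#' @param seed Integer seed.
#' @param group_counts Total ion count per backbone group (counts x min).
#' @param chrom_sigma Chromatographic Gaussian sigma in minutes.
#' @param rt_range Retention-time interval for species apexes (minutes).
#' @param charge_weights Named or positional weights over each species'
#'   monitored charges.
#' @return A `ground_truth` with a `species` table (`species_id`,
#'   `pqa_id`, `role`, `true_fraction`, `counts`, `rt`, `sigma`) and the
#'   `target_species` objects.
#' @export
build_ground_truth <- function(panel, levels, glyco = NULL, seed = 1,
                               group_counts = 2e5, chrom_sigma = 0.05,
                               rt_range = c(0.8, 7.2),
                               charge_weights = c(0.55, 0.30, 0.15)) {
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  if (!is.null(glyco)) {
    if (abs(sum(glyco) - 1) > 1e-9) {
      stop("glycoform fractions must sum to 1 (got ", sum(glyco), ")")
    }
    if (any(glyco < 0)) stop("glycoform fractions must lie in [0, 1]")
  }
  set.seed(seed)
  species <- list()
  rows <- list()
  for (def in panel) {
    is_glyco <- !is.null(def$glycans)
    if (is_glyco) {
      if (is.null(glyco)) stop("panel holds a glycoform definition but no ",
                               "glyco fractions were given")
      for (sp in def$all_species) {
        nm <- if (!is.null(sp$glycan)) sp$glycan$oxford_name else
          "Aglycosylated"
        frac <- if (nm %in% names(glyco)) glyco[[nm]] else 0
        if (frac == 0) next
        species[[length(species) + 1]] <- sp
        rows[[length(rows) + 1]] <- data.frame(
          species_id = sp$species_id, pqa_id = def$pqa_id, role = nm,
          true_fraction = frac, counts = group_counts * frac)
      }
    } else {
      level <- if (def$pqa_id %in% names(levels)) levels[[def$pqa_id]] else 0
      mod <- def$modified_species[[1]]
      unmod <- Filter(function(sp) length(sp$site_mods) == 0,
                      def$all_species)[[1]]
      if (level > 0) {
        species[[length(species) + 1]] <- mod
        rows[[length(rows) + 1]] <- data.frame(
          species_id = mod$species_id, pqa_id = def$pqa_id,
          role = "modified", true_fraction = level,
          counts = group_counts * level)
      }
      species[[length(species) + 1]] <- unmod
      rows[[length(rows) + 1]] <- data.frame(
        species_id = unmod$species_id, pqa_id = def$pqa_id,
        role = "unmodified", true_fraction = 1 - level,
        counts = group_counts * (1 - level))
    }
  }
  tab <- do.call(rbind, rows)
  # drop duplicate species (same backbone shared across definitions)
  keep <- !duplicated(tab$species_id)
  tab <- tab[keep, , drop = FALSE]
  species <- species[keep]

  # collision-free retention times, minimum spacing 0.5 min: draw sorted
  # uniforms on the slack interval and add the fixed spacings back
  n <- nrow(tab)
  spacing <- 0.5
  slack <- diff(rt_range) - (n - 1) * spacing
  if (slack < 0) {
    stop("cannot place ", n, " species with ", spacing,
         " min spacing in the given rt_range")
  }
  u <- sort(stats::runif(n, 0, slack))
  rt <- rt_range[1] + u + (seq_len(n) - 1) * spacing
  tab$rt <- rt[sample.int(n)]
  tab$sigma <- chrom_sigma
  rownames(tab) <- NULL
  for (i in seq_len(n)) species[[i]]$expected_rt <- tab$rt[i]
  structure(list(species_table = tab, species = species, seed = seed,
                 charge_weights = charge_weights,
                 group_counts = group_counts),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground truth: %d species, seed %d>\n",
              nrow(x$species_table), x$seed))
  invisible(x)
}

#' Simulate a DDA peptide-map run
#'
#' MS1 spectra are emitted every scan interval; each species contributes
#' per monitored charge an averagine-approximated isotope envelope scaled
#' by its Gaussian elution profile, plus additive noise centroids. The
#' injected monoisotopic area per species (summed over charges) is
#' recorded in the returned run's ground-truth attribute.
#'
#' @param truth A [build_ground_truth()] result.
#' @param config A [sim_config()].
#' @param run_id Run identifier.
#' @return An [ms_run()]; `attr(run, "injected")` holds the per-species
#'   injected monoisotopic areas alongside the truth table.
#' @export
simulate_peptide_run <- function(truth, config = sim_config(),
                                 run_id = "sim") {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed(truth$seed + 77)
  times <- seq(0, config$gradient_min, by = config$scan_interval_s / 60)
  tab <- truth$species_table
  n_iso <- 5

  # one row per (species, charge, isotope): m/z and count coefficient
  peak_rows <- list()
  injected <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    sp <- truth$species[[i]]
    zs <- sp$charges
    w <- truth$charge_weights[seq_along(zs)]
    w <- w / sum(w)
    env <- averagine_envelope(sp$neutral_mono_mass, n_iso)
    injected[i] <- tab$counts[i] * env[1]
    for (k in seq_along(zs)) {
      mzs <- (sp$neutral_mono_mass + (0:(n_iso - 1)) * C13_C12_DELTA +
                zs[k] * PROTON_MASS) / zs[k]
      ok <- mzs >= config$mz_range[1] & mzs <= config$mz_range[2]
      if (!any(ok)) next
      peak_rows[[length(peak_rows) + 1]] <- data.frame(
        mz = mzs[ok], coef = tab$counts[i] * w[k] * env[ok],
        rt = tab$rt[i], sigma = tab$sigma[i])
    }
  }
  pk <- do.call(rbind, peak_rows)

  spectra <- vector("list", length(times))
  for (t_idx in seq_along(times)) {
    t <- times[t_idx]
    intens <- pk$coef * stats::dnorm(t, pk$rt, pk$sigma)
    sel <- intens > 1e-3
    mz <- pk$mz[sel]
    intensity <- intens[sel]
    if (config$noise_sd > 0) {
      if (length(intensity)) {
        intensity <- pmax(
          intensity + stats::rnorm(length(intensity), 0, config$noise_sd), 0)
      }
      if (config$n_noise_peaks > 0) {
        mz <- c(mz, stats::runif(config$n_noise_peaks, config$mz_range[1],
                                 config$mz_range[2]))
        intensity <- c(intensity,
                       abs(stats::rnorm(config$n_noise_peaks, 0,
                                        config$noise_sd)))
      }
    }
    spectra[[t_idx]] <- spectrum_record(1L, t, mz, intensity)
  }

  if (config$include_ms2) {
    for (i in seq_len(nrow(tab))) {
      sp <- truth$species[[i]]
      ions <- fragment_ions(sp, max_charge = 1)
      z <- sp$charges[1]
      spectra[[length(spectra) + 1]] <- spectrum_record(
        2L, tab$rt[i] + 1e-4, ions$mz,
        rep(1000, nrow(ions)),
        precursor_mz = mz_from_mass(sp$neutral_mono_mass, z),
        precursor_charge = z)
    }
  }

  run <- ms_run(run_id, spectra,
                metadata = list(simulated = TRUE, seed = truth$seed))
  inj <- truth$species_table
  inj$injected_area <- injected
  attr(run, "injected") <- inj
  run
}

#' Simulate a reduced-subunit multi-charge spectrum
#'
#' Profile spectrum of a light chain with a glycated fraction: Gaussian
#' peaks at `(M + z * 1.0072765)/z` for `M` in `{lc_mass,
#' lc_mass + 162.0528}` with FWHM `m/z / resolution`, log-normal
#' charge-state weights around an apex charge, and additive noise drawn
#' as `|N(0, sd)|`.
#'
#' @param lc_mass Average light-chain mass in Da.
#' @param glycated_fraction Fraction of the glycated species in `[0, 1]`.
#' @param charges Integer charges simulated.
#' @param resolution Resolving power (FWHM).
#' @param seed Integer seed.
#' @param apex_charge Charge state carrying the most intensity.
#' @param peak_height Apex height of the strongest peak (counts).
#' @param noise_sd Noise magnitude SD (counts).
#' @param mz_range Simulated m/z window.
#' @param grid_step Profile grid spacing in m/z.
#' @return A profile [spectrum_record()] (MS1).
#' @export
simulate_subunit_spectrum <- function(lc_mass, glycated_fraction,
                                      charges = 8:35, resolution = 2500,
                                      seed = 1, apex_charge = 15,
                                      peak_height = 5000, noise_sd = 20,
                                      mz_range = c(400, 3000),
                                      grid_step = 0.05) {
  stopifnot(glycated_fraction >= 0, glycated_fraction <= 1, lc_mass > 0)
  set.seed(seed)
  grid <- seq(mz_range[1], mz_range[2], by = grid_step)
  signal <- numeric(length(grid))
  zw <- stats::dlnorm(charges, meanlog = log(apex_charge), sdlog = 0.2)
  zw <- zw / max(zw)
  masses <- c(lc_mass, lc_mass + 162.0528)
  fracs <- c(1 - glycated_fraction, glycated_fraction)
  for (s in seq_along(masses)) {
    if (fracs[s] == 0) next
    for (k in seq_along(charges)) {
      mu <- (masses[s] + charges[k] * PROTON_MASS) / charges[k]
      if (mu < mz_range[1] || mu > mz_range[2]) next
      sig <- mu / resolution / (2 * sqrt(2 * log(2)))
      a <- peak_height * fracs[s] * zw[k]
      win <- abs(grid - mu) <= 6 * sig
      signal[win] <- signal[win] + a * exp(-(grid[win] - mu)^2 / (2 * sig^2))
    }
  }
  if (noise_sd > 0) {
    signal <- signal + abs(stats::rnorm(length(grid), 0, noise_sd))
  }
  spectrum_record(1L, 0, grid, signal, centroided = FALSE)
}

#' Demo oxidation panel
#'
#' A synthetic heavy chain of five tryptic peptides, each carrying one
#' methionine, sized so charge states 2-3 fall inside the survey window.
#' Used as the standard test bed for end-to-end oxidation-recovery
#' studies (no public mAb sequence is attached to the workflow, so the
#' chain is synthetic by construction).
#'
#' @param charges Monitored charge states.
#' @return List with `chain` ([chain_sequence()]) and `panel` (list of
#'   `pqa_definition`, ids `Oxidation_1` .. `Oxidation_5`).
#' @export
demo_oxidation_panel <- function(charges = 2:3) {
  chain <- chain_sequence("heavy", paste0(
    "AVSGMDELK", "TLYMNQAGK", "VFDMSPELR", "GHWMTTESK", "YAAMGDVLK"))
  panel <- enumerate_pqa_species(
    list(chain),
    modifications = list(modification_def("Oxidation", "M", 15.994915)),
    charges = charges)
  list(chain = chain, panel = panel)
}

#' Demo glycoform panel
#'
#' The public Fc glycopeptide backbone `EEQYNSTYR` with the default
#' eight-form glycan panel plus the aglycosylated peptide.
#'
#' @param charges Monitored charge states.
#' @return List with `chain`, `panel` (one glycoform `pqa_definition`)
#'   and `fractions`, a named vector of realistic true glycoform
#'   fractions (dominant form 0.90) summing to 1.
#' @export
demo_glyco_panel <- function(charges = 2:3) {
  chain <- chain_sequence("heavy", "AVLQSGAEVKEEQYNSTYRVVSVLTVLHQDWK")
  panel <- enumerate_pqa_species(
    list(chain), modifications = list(),
    glycans = default_glycan_panel(),
    glyco_sites = list(list(chain_id = "heavy", position = 15)),
    charges = charges)
  raw <- c(FA2 = 89.76, FA2G1 = 5.92, FA2G2 = 0.10, FA1 = 1.56,
           FA3 = 0.56, A2 = 0.47, M5 = 0.29, Aglycosylated = 0.52)
  list(chain = chain, panel = panel, fractions = raw / sum(raw))
}

#' Attach ground-truth retention times to a panel
#'
#' Copies the simulated apex retention times of a [build_ground_truth()]
#' result onto the matching species of a PQA panel, so batch
#' quantification can use the characterization-run expected-RT windows.
#'
#' @param panel List of `pqa_definition` objects.
#' @param truth A [build_ground_truth()] result.
#' @return The panel with `expected_rt` set on every species present in
#'   the truth.
#' @export
attach_expected_rt <- function(panel, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  set_rt <- function(sp) {
    j <- which(truth$species_table$species_id == sp$species_id)
    if (length(j)) sp$expected_rt <- truth$species_table$rt[j[1]]
    sp
  }
  lapply(panel, function(def) {
    def$all_species <- lapply(def$all_species, set_rt)
    def$modified_species <- lapply(def$modified_species, set_rt)
    def
  })
}
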