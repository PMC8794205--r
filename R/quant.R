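# Chromatographic peak detection/integration, species measurement,
# relative-abundance quantification, glycoform profiling, MS/MS scoring.

#' Integration parameters
#'
#' Defaults are the batch-quantification settings of the workflow: Gaussian
#' smooth width 1.0 point, minimum peak width 3 points, minimum peak height
#' 50 counts, S/N integration threshold 3, noise percentage 40, baseline
#' subtraction window 2 points, peak splitting ratio 2, XIC width 0.02 Da.
#'
#' @param gaussian_smooth_width Gaussian kernel sigma in points.
#' @param min_peak_width Minimum peak width in points.
#' @param min_peak_height Minimum apex height in counts.
#' @param sn_threshold Signal-to-noise integration threshold.
#' @param noise_percentage Percentage of lowest trace points averaged for
#'   the noise estimate.
#' @param baseline_window Points averaged at each boundary for the linear
#'   baseline.
#' @param peak_splitting Apex/valley ratio above which adjacent apexes are
#'   split into separate peaks.
#' @param xic_width Full XIC m/z window in Da.
#' @return An `integration_params` list.
#' @export
integration_params <- function(gaussian_smooth_width = 1.0,
                               min_peak_width = 3, min_peak_height = 50,
                               sn_threshold = 3, noise_percentage = 40,
                               baseline_window = 2, peak_splitting = 2,
                               xic_width = 0.02) {
  p <- list(gaussian_smooth_width = gaussian_smooth_width,
            min_peak_width = min_peak_width,
            min_peak_height = min_peak_height, sn_threshold = sn_threshold,
            noise_percentage = noise_percentage,
            baseline_window = baseline_window,
            peak_splitting = peak_splitting, xic_width = xic_width)
  if (any(unlist(p) <= 0)) stop("integration parameters must be positive")
  structure(p, class = "integration_params")
}

#' Gaussian smoothing of an XIC trace
#'
#' Convolution with a Gaussian kernel of sigma `width` points, renormalized
#' at the trace edges so constant traces are preserved exactly.
#'
#' @param trace An `xic_trace`.
#' @param width Kernel sigma in points; 0 is a no-op.
#' @return The smoothed `xic_trace`.
#' @export
smooth_trace <- function(trace, width = 1.0) {
  stopifnot(inherits(trace, "xic_trace"), width >= 0)
  if (width == 0 || length(trace$intensity) < 2) return(trace)
  h <- max(1L, ceiling(4 * width))
  w <- stats::dnorm(seq(-h, h), sd = width)
  w <- w / sum(w)
  n <- length(trace$intensity)
  padded <- c(rep(0, h), trace$intensity, rep(0, h))
  sm <- stats::filter(padded, w, sides = 2)[(h + 1):(h + n)]
  # edge renormalization: divide by the in-range kernel weight
  ones <- stats::filter(c(rep(0, h), rep(1, n), rep(0, h)), w,
                        sides = 2)[(h + 1):(h + n)]
  trace$intensity <- as.numeric(sm / ones)
  trace
}

#' Noise estimate of a trace
#'
#' Mean of the lowest `noise_percentage` percent of trace intensities.
#'
#' @param trace An `xic_trace`.
#' @param noise_percentage Percentage of points treated as noise (default
#'   40).
#' @return Noise level in counts (0 for an all-zero trace).
#' @export
estimate_noise <- function(trace, noise_percentage = 40) {
  x <- trace$intensity
  if (!length(x)) stop("cannot estimate noise of an empty trace")
  if (all(x == 0)) return(0)
  k <- max(1L, ceiling(length(x) * noise_percentage / 100))
  mean(sort(x)[seq_len(k)])
}

#' Detect and integrate chromatographic peaks
#'
#' The integration contract: smooth the trace, estimate noise, find local
#' maxima at or above `max(min_peak_height, sn_threshold * noise)`, take
#' boundaries at the nearest flanking local minima (or trace ends), merge
#' adjacent apexes into one peak unless the ratio of the smaller apex (the
#' group's tallest versus the candidate) to the intervening valley reaches
#' `peak_splitting`,
#' reject peaks narrower than `min_peak_width` points, subtract a linear
#' baseline anchored on `baseline_window`-point means at each boundary, and
#' integrate trapezoidally on the unsmoothed trace.
#'
#' @param trace An `xic_trace`.
#' @param params An [integration_params()].
#' @return data.frame of peaks: `rt_apex`, `rt_start`, `rt_end`, `height`,
#'   `area` (counts x min), `sn`. Empty when nothing passes.
#' @export
detect_and_integrate <- function(trace, params = integration_params()) {
  empty <- data.frame(rt_apex = numeric(), rt_start = numeric(),
                      rt_end = numeric(), height = numeric(),
                      area = numeric(), sn = numeric())
  n <- length(trace$intensity)
  if (n < 3) return(empty)
  sm <- smooth_trace(trace, params$gaussian_smooth_width)
  s <- sm$intensity
  noise <- estimate_noise(sm, params$noise_percentage)
  thr <- max(params$min_peak_height, params$sn_threshold * noise)

  apexes <- which(s >= thr &
                    s >= c(-Inf, s[-n]) & s > c(s[-1], -Inf))
  if (!length(apexes)) return(empty)

  # merge an apex into the previous group unless the ratio of the smaller
  # of (group's tallest apex, candidate apex) to the intervening valley
  # reaches the splitting threshold
  groups <- list(apexes[1])
  if (length(apexes) > 1) {
    for (i in 2:length(apexes)) {
      prev <- groups[[length(groups)]]
      a_top <- prev[which.max(s[prev])]
      a_cur <- apexes[i]
      valley <- min(s[a_top:a_cur])
      ratio <- min(s[a_top], s[a_cur]) / max(valley, .Machine$double.eps)
      if (ratio >= params$peak_splitting) {
        groups[[length(groups) + 1]] <- a_cur
      } else {
        groups[[length(groups)]] <- c(prev, a_cur)
      }
    }
  }

  out <- list()
  for (g in groups) {
    apex <- g[which.max(s[g])]
    # walk to flanking local minima of the smoothed trace
    left <- g[1]
    while (left > 1 && s[left - 1] < s[left]) left <- left - 1
    right <- g[length(g)]
    while (right < n && s[right + 1] < s[right]) right <- right + 1
    if (right - left + 1 < params$min_peak_width) next
    # linear baseline from boundary-window means, on the raw trace
    bw <- params$baseline_window
    y <- trace$intensity
    lb <- mean(y[max(1, left - bw + 1):left])
    rb <- mean(y[right:min(n, right + bw - 1)])
    idx <- left:right
    base <- lb + (rb - lb) * (idx - left) / max(right - left, 1)
    yc <- pmax(y[idx] - base, 0)
    area <- if (length(idx) > 1) {
      sum(diff(trace$rt[idx]) * (yc[-length(yc)] + yc[-1]) / 2)
    } else 0
    height <- max(yc)
    out[[length(out) + 1]] <- data.frame(
      rt_apex = trace$rt[apex], rt_start = trace$rt[left],
      rt_end = trace$rt[right], height = height, area = area,
      sn = if (noise > 0) height / noise else Inf
    )
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Measure one target species in a run
#'
#' Extracts one XIC per monitored charge at the theoretical m/z, integrates
#' it, and keeps the largest peak in the expected retention-time window
#' (`expected_rt` +/- `rt_halfwidth`, or the global maximum when no window
#' is available). A peak is only attributed to the species when the apex
#' MS1 spectrum holds a centroid within `ppm_tol` of the theoretical m/z.
#'
#' @param run An [ms_run()].
#' @param species A [target_species()].
#' @param params An [integration_params()].
#' @param rt_window Optional `c(min, max)` window in minutes; default
#'   derived from `species$expected_rt` +/- `rt_halfwidth`.
#' @param rt_halfwidth Half-width of the default window (minutes).
#' @param ppm_tol Apex-spectrum m/z acceptance in ppm (default 5).
#' @return A `species_measurement`: per-charge peak table, `total_area`,
#'   `detected` (at least one peak with S/N >= threshold and height >=
#'   minimum).
#' @export
measure_species <- function(run, species, params = integration_params(),
                            rt_window = NULL, rt_halfwidth = 1,
                            ppm_tol = 5) {
  stopifnot(inherits(species, "target_species"),
            length(species$charges) >= 1)
  if (is.null(rt_window) && !is.na(species$expected_rt)) {
    rt_window <- species$expected_rt + c(-1, 1) * rt_halfwidth
  }
  per_charge <- list()
  total_area <- 0
  detected <- FALSE
  for (z in species$charges) {
    mz <- mz_from_mass(species$neutral_mono_mass, z)
    trace <- extract_xic(run, mz, params$xic_width)
    peaks <- detect_and_integrate(trace, params)
    pick <- NULL
    if (nrow(peaks)) {
      if (!is.null(rt_window)) {
        inwin <- peaks$rt_apex >= rt_window[1] & peaks$rt_apex <= rt_window[2]
        peaks <- peaks[inwin, , drop = FALSE]
      }
      if (nrow(peaks)) pick <- peaks[which.max(peaks$area), , drop = FALSE]
    }
    if (!is.null(pick) &&
        !apex_spectrum_has_ion(run, pick$rt_apex, mz, ppm_tol)) {
      pick <- NULL
    }
    if (!is.null(pick)) {
      pick$charge <- z
      pick$mz <- mz
      per_charge[[length(per_charge) + 1]] <- pick
      total_area <- total_area + pick$area
      if (pick$sn >= params$sn_threshold &&
          pick$height >= params$min_peak_height) {
        detected <- TRUE
      }
    }
  }
  peaks_df <- if (length(per_charge)) do.call(rbind, per_charge) else
    data.frame(rt_apex = numeric(), rt_start = numeric(),
               rt_end = numeric(), height = numeric(), area = numeric(),
               sn = numeric(), charge = integer(), mz = numeric())
  rownames(peaks_df) <- NULL
  structure(list(species = species, peaks = peaks_df,
                 total_area = total_area, detected = detected),
            class = "species_measurement")
}

apex_spectrum_has_ion <- function(run, rt_apex, mz, ppm_tol) {
  ms1 <- Filter(function(s) s$ms_level == 1L, run$spectra)
  if (!length(ms1)) return(FALSE)
  rts <- vapply(ms1, function(s) s$rt, numeric(1))
  sp <- ms1[[which.min(abs(rts - rt_apex))]]
  any(abs(sp$mz - mz) <= mz * ppm_tol * 1e-6)
}

#' @export
print.species_measurement <- function(x, ...) {
  cat(sprintf("<measurement %s: area %0.1f, %s>\n", x$species$species_id,
              x$total_area, if (x$detected) "detected" else "not detected"))
  invisible(x)
}

#' Relative abundance of a product quality attribute
#'
#' The attribute's relative abundance is the summed peak area of its
#' modified species divided by the summed area of every detected form of
#' the same backbone peptide, times 100.
#'
#' @param modified List of [measure_species()] results for the modified
#'   species.
#' @param all_forms List of measurements covering every form (must contain
#'   the modified species).
#' @param pqa_id Attribute identifier carried into the result.
#' @param thresholds A [qc_thresholds()] used to set the status field.
#' @return A `pqa_result` with `relative_abundance` (%), areas and status.
#' @export
pqa_relative_abundance <- function(modified, all_forms,
                                   pqa_id = NA_character_,
                                   thresholds = qc_thresholds()) {
  if (!length(all_forms)) stop("all_forms must be non-empty")
  ids_all <- vapply(all_forms, function(m) m$species$species_id,
                    character(1))
  ids_mod <- vapply(modified, function(m) m$species$species_id, character(1))
  if (!all(ids_mod %in% ids_all)) {
    stop("modified species not contained in all_forms: ",
         paste(setdiff(ids_mod, ids_all), collapse = ", "))
  }
  mod_area <- sum(vapply(modified, function(m) m$total_area, numeric(1)))
  tot_area <- sum(vapply(all_forms, function(m) m$total_area, numeric(1)))
  if (tot_area == 0) {
    ra <- 0
    status <- "not_detected"
    flag <- "denominator_zero"
  } else {
    ra <- 100 * mod_area / tot_area
    status <- classify_abundance(ra, thresholds)
    flag <- NA_character_
  }
  structure(list(pqa_id = pqa_id, relative_abundance = ra,
                 modified_area = mod_area, total_area = tot_area,
                 status = status, flag = flag),
            class = "pqa_result")
}

#' @export
print.pqa_result <- function(x, ...) {
  cat(sprintf("<PQA %s: %0.3f%% (%s)>\n", x$pqa_id, x$relative_abundance,
              x$status))
  invisible(x)
}

#' Glycoform profile
#'
#' Percentage of each detected glycoform over the summed area of all
#' detected glycoforms; the aglycosylated peptide counts as a form.
#'
#' @param measurements Named list (or list with species glycan names) of
#'   [measure_species()] results, one per glycoform.
#' @return Named numeric vector of percentages summing to 100.
#' @export
glycoform_profile <- function(measurements) {
  det <- Filter(function(m) m$detected, measurements)
  if (!length(det)) stop("no glycoform detected")
  nm <- vapply(det, function(m) {
    if (!is.null(m$species$glycan)) m$species$glycan$oxford_name
    else "Aglycosylated"
  }, character(1))
  areas <- vapply(det, function(m) m$total_area, numeric(1))
  stats::setNames(100 * areas / sum(areas), nm)
}

#' MS/MS fragment match score
#'
#' Counts theoretical b/y ions with an observed peak within `tol` Da and
#' scores 10 x matched/theoretical. Species are auto-validated at score
#' >= 3 (i.e. at least 30% ion coverage).
#'
#' @param spectrum An MS2 [spectrum_record()] whose precursor lies within
#'   `precursor_ppm` of one of the species' charge states.
#' @param species A [target_species()].
#' @param tol Fragment matching tolerance in Da (default 0.03).
#' @param max_charge Fragment charges considered (default 1).
#' @param precursor_ppm Precursor acceptance in ppm (default 5).
#' @return An `msms_match` with `matched`, `theoretical`, `score`,
#'   `validated`.
#' @export
msms_match_score <- function(spectrum, species, tol = 0.03, max_charge = 1,
                             precursor_ppm = 5) {
  stopifnot(inherits(spectrum, "spectrum_record"))
  if (spectrum$ms_level != 2L) stop("MS/MS scoring requires an MS2 spectrum")
  if (!is.na(spectrum$precursor_mz)) {
    prec_ok <- any(vapply(species$charges, function(z) {
      mz <- mz_from_mass(species$neutral_mono_mass, z)
      abs(spectrum$precursor_mz - mz) <= mz * precursor_ppm * 1e-6
    }, logical(1)))
    if (!prec_ok) {
      stop("precursor m/z does not match any monitored charge state")
    }
  }
  ions <- fragment_ions(species, max_charge = max_charge)
  matched <- vapply(ions$mz, function(m)
    length(spectrum$mz) > 0 && any(abs(spectrum$mz - m) <= tol), logical(1))
  score <- 10 * sum(matched) / nrow(ions)
  structure(list(species = species, matched = sum(matched),
                 theoretical = nrow(ions), score = score,
                 validated = score >= 3),
            class = "msms_match")
}

#' Sequence coverage by validated species
#'
#' @param validated List of [target_species()] confirmed by MS/MS or
#'   glycopeptide evidence.
#' @param chains List of [chain_sequence()].
#' @return Named numeric vector: percent of each chain's residues covered
#'   by at least one validated species.
#' @export
sequence_coverage <- function(validated, chains) {
  out <- vapply(chains, function(chain) {
    n <- nchar(chain$residues)
    covered <- logical(n)
    for (sp in validated) {
      if (sp$peptide$chain_id == chain$chain_id) {
        covered[sp$peptide$start:sp$peptide$end] <- TRUE
      }
    }
    100 * sum(covered) / n
  }, numeric(1))
  stats::setNames(out, vapply(chains, function(c) c$chain_id, character(1)))
}
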