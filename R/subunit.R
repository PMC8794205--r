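# Charge-state deconvolution of reduced-subunit spectra and light-chain
# glycation quantification.

#' Deconvolution parameters
#'
#' Defaults follow the intact-protein processing settings: 20 iterations,
#' S/N threshold 20, resolution 2500, Gaussian smoothing of 1 point,
#' matching tolerance +/- 5 Da, m/z acceptance window 400-3000; the
#' default charge range 8-35 is clipped by that window.
#'
#' @param mass_range `c(min, max)` candidate neutral-mass interval in Da.
#' @param mz_range m/z acceptance window.
#' @param iterations Peak-stripping rounds.
#' @param sn_threshold Reconstructed-peak S/N suppression threshold.
#' @param resolution Instrument resolving power (m/dm FWHM).
#' @param smooth_points Gaussian smoothing of the reconstruction (points).
#' @param match_tol Species matching tolerance in Da.
#' @param charge_range Integer charges considered.
#' @return A `deconv_params` list.
#' @export
deconv_params <- function(mass_range, mz_range = c(400, 3000),
                          iterations = 20, sn_threshold = 20,
                          resolution = 2500, smooth_points = 1,
                          match_tol = 5, charge_range = 8:35) {
  stopifnot(length(mass_range) == 2, mass_range[1] > 0,
            mass_range[2] > mass_range[1], iterations >= 1,
            sn_threshold > 0, resolution > 0, match_tol > 0)
  structure(list(mass_range = mass_range, mz_range = mz_range,
                 iterations = iterations, sn_threshold = sn_threshold,
                 resolution = resolution, smooth_points = smooth_points,
                 match_tol = match_tol, charge_range = charge_range),
            class = "deconv_params")
}

#' Charge-state deconvolution of a subunit spectrum
#'
#' Iterative peak-stripping reconstruction: candidate neutral masses on a
#' grid over `mass_range` (step = mass / (2 x resolution)) are scored by
#' the summed spectrum intensity at the predicted m/z of every charge
#' whose m/z falls inside `mz_range`; each round the best-supported
#' candidate is refined by continuous optimisation, its predicted
#' charge-state envelope (Gaussian peaks of width m/z / resolution FWHM)
#' is subtracted from the working spectrum, and the process repeats for up
#' to `iterations` rounds or until the residual support falls below the
#' noise gate. Reconstructed peaks with S/N below `sn_threshold` are
#' suppressed; the reconstruction is smoothed over `smooth_points`.
#'
#' @param spectrum An MS1 [spectrum_record()] of the reduced subunits
#'   (profile or dense centroid data).
#' @param params A [deconv_params()].
#' @return A `reconstructed_spectrum`: `mass_axis`, `intensity`, and a
#'   `peaks` data.frame (`mass`, `height`, `area`, `sn`).
#' @export
deconvolve <- function(spectrum, params) {
  stopifnot(inherits(spectrum, "spectrum_record"),
            inherits(params, "deconv_params"))
  step <- mean(params$mass_range) / (2 * params$resolution)
  mass_axis <- seq(params$mass_range[1], params$mass_range[2], by = step)
  empty <- structure(
    list(mass_axis = mass_axis, intensity = numeric(length(mass_axis)),
         peaks = data.frame(mass = numeric(), height = numeric(),
                            area = numeric(), sn = numeric())),
    class = "reconstructed_spectrum")
  if (!length(spectrum$mz)) return(empty)

  sel <- spectrum$mz >= params$mz_range[1] & spectrum$mz <= params$mz_range[2]
  mz <- spectrum$mz[sel]
  y <- spectrum$intensity[sel]
  if (length(mz) < 3 || sum(y) == 0) return(empty)
  noise <- mean(sort(y)[seq_len(max(1L, ceiling(length(y) * 0.4)))])

  interp <- function(yy) stats::approxfun(mz, yy, yleft = 0, yright = 0)
  charges <- params$charge_range
  score_fn <- function(M, f) {
    pm <- (M + charges * PROTON_MASS) / charges
    ok <- pm >= params$mz_range[1] & pm <= params$mz_range[2]
    if (!any(ok)) return(0)
    sum(f(pm[ok]))
  }

  work <- y
  found <- list()
  for (iter in seq_len(params$iterations)) {
    f <- interp(work)
    scores <- vapply(mass_axis, score_fn, numeric(1), f = f)
    best <- which.max(scores)
    if (scores[best] <= 0) break
    lo <- mass_axis[max(1, best - 1)]
    hi <- mass_axis[min(length(mass_axis), best + 1)]
    opt <- stats::optimize(function(M) -score_fn(M, f), c(lo, hi))
    M <- opt$minimum
    # refine: per-charge parabolic apex positions, amplitude-weighted mean
    # of the implied neutral masses
    ref_pm <- (M + charges * PROTON_MASS) / charges
    ref_sigma <- ref_pm / params$resolution / (2 * sqrt(2 * log(2)))
    est <- vapply(seq_along(charges), function(j) {
      if (ref_pm[j] < params$mz_range[1] || ref_pm[j] > params$mz_range[2]) {
        return(c(NA_real_, 0))
      }
      win <- which(abs(mz - ref_pm[j]) <= 2 * ref_sigma[j])
      if (length(win) < 3) return(c(NA_real_, 0))
      ann <- (abs(mz - ref_pm[j]) > 3 * ref_sigma[j]) &
        (abs(mz - ref_pm[j]) <= 6 * ref_sigma[j])
      base <- if (any(ann)) stats::median(work[ann]) else 0
      w <- pmax(work[win] - base, 0)
      if (sum(w) <= 0) return(c(NA_real_, 0))
      apex_mz <- sum(mz[win] * w) / sum(w)
      c((apex_mz - PROTON_MASS) * charges[j], max(w))
    }, numeric(2))
    wts <- est[2, ]
    good <- !is.na(est[1, ]) & wts > 0 &
      abs(est[1, ] - M) < 3 * mean(params$mass_range) / params$resolution
    if (any(good)) M <- sum(est[1, good] * wts[good]) / sum(wts[good])
    pm <- (M + charges * PROTON_MASS) / charges
    ok <- pm >= params$mz_range[1] & pm <= params$mz_range[2]
    sigma <- pm / params$resolution / (2 * sqrt(2 * log(2)))
    # apex amplitude above the local baseline (median of an annulus
    # 3-6 peak widths from the predicted centre)
    h <- vapply(seq_along(pm), function(j) {
      if (!ok[j]) return(0)
      ann <- (abs(mz - pm[j]) > 3 * sigma[j]) &
        (abs(mz - pm[j]) <= 6 * sigma[j])
      base <- if (any(ann)) stats::median(work[ann]) else 0
      max(f(pm[j]) - base, 0)
    }, numeric(1))
    apex_h <- max(h)
    if (noise > 0 && apex_h < params$sn_threshold * noise) break
    if (apex_h <= 0) break
    area <- sum(h * sigma * sqrt(2 * pi))
    found[[length(found) + 1]] <- data.frame(
      mass = M, height = apex_h, area = area,
      sn = if (noise > 0) apex_h / noise else Inf)
    # strip the predicted envelope from the working spectrum
    for (j in which(ok & h > 0)) {
      affected <- abs(mz - pm[j]) <= 6 * sigma[j]
      work[affected] <- pmax(
        work[affected] -
          h[j] * exp(-(mz[affected] - pm[j])^2 / (2 * sigma[j]^2)), 0)
    }
  }

  if (!length(found)) return(empty)
  peaks <- do.call(rbind, found)
  peaks <- peaks[peaks$sn >= params$sn_threshold, , drop = FALSE]
  rownames(peaks) <- NULL
  intensity <- numeric(length(mass_axis))
  mass_sigma <- mass_axis / params$resolution / (2 * sqrt(2 * log(2)))
  for (k in seq_len(nrow(peaks))) {
    sig <- peaks$mass[k] / params$resolution / (2 * sqrt(2 * log(2)))
    intensity <- intensity + peaks$area[k] *
      stats::dnorm(mass_axis, peaks$mass[k], sig) * step
  }
  if (params$smooth_points > 0 && length(intensity) > 2) {
    tr <- structure(list(target_mz = NA, window = 1, rt = mass_axis,
                         intensity = intensity), class = "xic_trace")
    intensity <- smooth_trace(tr, params$smooth_points)$intensity
  }
  structure(list(mass_axis = mass_axis, intensity = intensity,
                 peaks = peaks),
            class = "reconstructed_spectrum")
}

#' @export
print.reconstructed_spectrum <- function(x, ...) {
  cat(sprintf("<reconstruction: %d grid points, %d peaks>\n",
              length(x$mass_axis), nrow(x$peaks)))
  if (nrow(x$peaks)) {
    print(x$peaks)
  }
  invisible(x)
}

#' Match reconstructed peaks to theoretical subunit species
#'
#' Assigns the nearest reconstructed peak within `match_tol` Da to each
#' theoretical species; when two theoretical species claim the same peak,
#' the closer wins with a warning.
#'
#' @param recon A [deconvolve()] result with at least one peak.
#' @param theoretical data.frame with columns `name`, `avg_mass`, and
#'   optionally `n_glycations` (default 0).
#' @param match_tol Tolerance in Da (default 5).
#' @return data.frame of matched species: `name`, `theoretical_mass`,
#'   `measured_mass`, `area`, `n_glycations`; unmatched species are
#'   absent.
#' @export
match_subunit_species <- function(recon, theoretical, match_tol = 5) {
  stopifnot(inherits(recon, "reconstructed_spectrum"))
  if (!nrow(recon$peaks)) stop("reconstruction holds no peaks")
  if (!"n_glycations" %in% names(theoretical)) theoretical$n_glycations <- 0L
  claims <- list()
  assigned_peak <- rep(NA_integer_, nrow(theoretical))
  dist <- rep(NA_real_, nrow(theoretical))
  for (i in seq_len(nrow(theoretical))) {
    d <- abs(recon$peaks$mass - theoretical$avg_mass[i])
    j <- which.min(d)
    if (d[j] <= match_tol) {
      assigned_peak[i] <- j
      dist[i] <- d[j]
    }
  }
  # resolve conflicts: closer theoretical keeps the peak
  for (j in unique(stats::na.omit(assigned_peak))) {
    claimers <- which(assigned_peak == j)
    if (length(claimers) > 1) {
      keep <- claimers[which.min(dist[claimers])]
      drop <- setdiff(claimers, keep)
      warning("reconstructed peak at ", round(recon$peaks$mass[j], 2),
              " Da claimed by multiple species; keeping ",
              theoretical$name[keep])
      assigned_peak[drop] <- NA_integer_
    }
  }
  keep <- which(!is.na(assigned_peak))
  data.frame(
    name = theoretical$name[keep],
    theoretical_mass = theoretical$avg_mass[keep],
    measured_mass = recon$peaks$mass[assigned_peak[keep]],
    area = recon$peaks$area[assigned_peak[keep]],
    n_glycations = theoretical$n_glycations[keep]
  )
}

#' Total light-chain glycation percentage
#'
#' 100 x summed area of all glycated stoichiometries over the summed area
#' of every matched light-chain species.
#'
#' @param species Output of [match_subunit_species()].
#' @return Glycation percentage.
#' @export
glycation_percent <- function(species) {
  if (!nrow(species)) stop("no light-chain species matched")
  100 * sum(species$area[species$n_glycations > 0]) / sum(species$area)
}

#' Theoretical glycated subunit species table
#'
#' Builds the light-chain species list `LC`, `LC+1gly`, ... using the
#' +162.0528 Da hexose adduct per glycation.
#'
#' @param lc_mass Average mass of the unmodified light chain (Da).
#' @param max_glycations Highest glycation stoichiometry listed.
#' @return data.frame with `name`, `avg_mass`, `n_glycations`.
#' @export
glycation_species_table <- function(lc_mass, max_glycations = 2) {
  k <- 0:max_glycations
  data.frame(
    name = c("LC", paste0("LC+", k[-1], "gly")),
    avg_mass = lc_mass + k * 162.0528,
    n_glycations = k
  )
}
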