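# LC-MS run containers, mzML / peak-list CSV I/O, XIC extraction.
# Internal retention-time unit is minutes throughout.

#' Construct a mass spectrum
#'
#' @param ms_level 1 or 2.
#' @param rt Retention time in minutes.
#' @param mz,intensity Parallel numeric arrays; `mz` is sorted ascending,
#'   intensities must be non-negative.
#' @param precursor_mz,precursor_charge Precursor of an MS2 spectrum.
#' @param centroided Logical flag; profile spectra are accepted but flagged.
#' @return A `spectrum_record` object.
#' @export
spectrum_record <- function(ms_level, rt, mz, intensity,
                            precursor_mz = NA_real_,
                            precursor_charge = NA_integer_,
                            centroided = TRUE) {
  stopifnot(ms_level %in% c(1L, 2L), length(mz) == length(intensity))
  if (any(intensity < 0)) stop("negative intensity in spectrum at rt ", rt)
  if (is.unsorted(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  structure(
    list(ms_level = as.integer(ms_level), rt = rt, mz = as.numeric(mz),
         intensity = as.numeric(intensity), precursor_mz = precursor_mz,
         precursor_charge = precursor_charge, centroided = centroided),
    class = "spectrum_record"
  )
}

#' Construct an LC-MS run
#'
#' @param run_id Run identifier.
#' @param spectra List of [spectrum_record()]; re-ordered by retention time.
#' @param metadata Optional named list (instrument, acquisition length...).
#' @return An `ms_run` object.
#' @export
ms_run <- function(run_id, spectra, metadata = list()) {
  rts <- vapply(spectra, function(s) s$rt, numeric(1))
  spectra <- spectra[order(rts)]
  structure(list(run_id = run_id, spectra = spectra, metadata = metadata),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  lv <- vapply(x$spectra, function(s) s$ms_level, integer(1))
  cat(sprintf("<ms_run '%s': %d spectra (%d MS1 / %d MS2)>\n", x$run_id,
              length(x$spectra), sum(lv == 1), sum(lv == 2)))
  invisible(x)
}

#' Read an LC-MS run
#'
#' Reads mzML (via mzR; retention times converted from seconds to minutes)
#' or the peak-list CSV debug dialect with columns `rt_min`, `ms_level`,
#' `mz`, `intensity` and optional `precursor_mz`, `precursor_z`.
#'
#' @param path Path to a `.mzML` or `.csv` file.
#' @param run_id Run identifier, default the file base name.
#' @return An [ms_run()].
#' @export
read_run <- function(path, run_id = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stop("run file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mzml") {
    read_run_mzml(path, run_id)
  } else if (ext == "csv") {
    read_run_csv(path, run_id)
  } else {
    stop("unsupported run format '.", ext, "' for ", path)
  }
}

read_run_mzml <- function(path, run_id) {
  head_txt <- paste(readLines(path, n = 20, warn = FALSE), collapse = "")
  if (grepl("<spectrumList count=\"0\"", head_txt, fixed = TRUE)) {
    return(ms_run(run_id, list()))
  }
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  if (nrow(hdr) == 0) return(ms_run(run_id, list()))
  spectra <- lapply(seq_len(nrow(hdr)), function(i) {
    pk <- mzR::peaks(h, i)
    if (is.null(dim(pk))) pk <- matrix(pk, ncol = 2)
    lvl <- hdr$msLevel[i]
    if (!lvl %in% c(1L, 2L)) {
      stop("spectrum ", i, " in ", path, " has unsupported MS level ", lvl)
    }
    spectrum_record(
      ms_level = lvl, rt = hdr$retentionTime[i] / 60,
      mz = pk[, 1], intensity = pk[, 2],
      precursor_mz = if (lvl == 2L) hdr$precursorMZ[i] else NA_real_,
      precursor_charge = if (lvl == 2L) hdr$precursorCharge[i]
                         else NA_integer_,
      centroided = isTRUE(hdr$centroided[i])
    )
  })
  ms_run(run_id, spectra)
}

read_run_csv <- function(path, run_id) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("rt_min", "ms_level", "mz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("peak-list CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  key <- paste(df$rt_min, df$ms_level,
               if ("precursor_mz" %in% names(df)) df$precursor_mz else "")
  spectra <- lapply(split(df, factor(key, levels = unique(key))),
                    function(sp) {
    spectrum_record(
      ms_level = sp$ms_level[1], rt = sp$rt_min[1], mz = sp$mz,
      intensity = sp$intensity,
      precursor_mz = if ("precursor_mz" %in% names(sp)) sp$precursor_mz[1]
                     else NA_real_,
      precursor_charge = if ("precursor_z" %in% names(sp))
                           as.integer(sp$precursor_z[1]) else NA_integer_
    )
  })
  ms_run(run_id, unname(spectra))
}

#' Write an LC-MS run
#'
#' Writes standard mzML (via mzR) or the peak-list CSV dialect, chosen by
#' file extension. mzML output is lossless to well below 1e-6 relative on
#' m/z.
#'
#' @param run An [ms_run()].
#' @param path Destination `.mzML` or `.csv` path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "mzml") {
    write_run_mzml(run, path)
  } else if (ext == "csv") {
    write_run_csv(run, path)
  } else {
    stop("unsupported run format '.", ext, "'")
  }
  invisible(path)
}

write_run_mzml <- function(run, path) {
  n <- length(run$spectra)
  if (n == 0) {
    # mzR cannot serialise an empty experiment; emit a minimal valid mzML
    writeLines(c(
      '<?xml version="1.0" encoding="utf-8"?>',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
      sprintf('  <run id="%s">', run$run_id),
      '    <spectrumList count="0" defaultDataProcessingRef="dp"/>',
      '  </run>', '</mzML>'), path)
    return(invisible(path))
  }
  pks <- lapply(run$spectra, function(s)
    cbind(mz = s$mz, intensity = s$intensity))
  na0 <- function(x, repl = 0) ifelse(is.na(x), repl, x)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(run$spectra, function(s) s$ms_level, integer(1)),
    polarity = 1L,
    peaksCount = vapply(run$spectra, function(s) length(s$mz), integer(1)),
    totIonCurrent = vapply(run$spectra, function(s) sum(s$intensity),
                           numeric(1)),
    retentionTime = vapply(run$spectra, function(s) s$rt * 60, numeric(1)),
    basePeakMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(run$spectra, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = vapply(run$spectra, function(s) na0(s$precursor_mz),
                         numeric(1)),
    precursorCharge = vapply(run$spectra, function(s)
      as.integer(na0(s$precursor_charge, 0L)), integer(1)),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0,
    filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = vapply(run$spectra, function(s) isTRUE(s$centroided),
                        logical(1)),
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

write_run_csv <- function(run, path) {
  rows <- lapply(run$spectra, function(s) {
    if (!length(s$mz)) return(NULL)
    data.frame(rt_min = s$rt, ms_level = s$ms_level, mz = s$mz,
               intensity = s$intensity, precursor_mz = s$precursor_mz,
               precursor_z = s$precursor_charge)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Extract an ion chromatogram
#'
#' Per MS1 spectrum, sums intensities within `window/2` of `target_mz`;
#' spectra with no matching point contribute zero.
#'
#' @param run An [ms_run()].
#' @param target_mz Target m/z.
#' @param window Full m/z window width in Da (default 0.025, the
#'   characterization setting; batch quantification uses 0.02).
#' @param rt_range Optional `c(min, max)` retention-time restriction
#'   (minutes).
#' @return An `xic_trace` with fields `target_mz`, `window`, `rt`,
#'   `intensity`.
#' @export
extract_xic <- function(run, target_mz, window = 0.025, rt_range = NULL) {
  stopifnot(inherits(run, "ms_run"), window > 0)
  half <- window / 2
  ms1 <- Filter(function(s) s$ms_level == 1L, run$spectra)
  if (!is.null(rt_range)) {
    ms1 <- Filter(function(s) s$rt >= rt_range[1] && s$rt <= rt_range[2],
                  ms1)
  }
  rt <- vapply(ms1, function(s) s$rt, numeric(1))
  intensity <- vapply(ms1, function(s) {
    sel <- abs(s$mz - target_mz) <= half
    if (any(sel)) sum(s$intensity[sel]) else 0
  }, numeric(1))
  structure(list(target_mz = target_mz, window = window, rt = rt,
                 intensity = intensity),
            class = "xic_trace")
}

#' @export
print.xic_trace <- function(x, ...) {
  cat(sprintf("<XIC m/z %0.4f +/- %0.4f: %d points, max %0.1f>\n",
              x$target_mz, x$window / 2, length(x$rt),
              if (length(x$intensity)) max(x$intensity) else 0))
  invisible(x)
}
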