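# Batch orchestration: quantification over run manifests, NPD comparisons,
# and QC report assembly. The thin command-line wrapper in
# inst/scripts/mam_cli.R calls these functions.

write_report_csv <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# mamtools ", schema), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Quantify a PQA panel over a batch of runs
#'
#' For every run in the manifest, measures every species of every PQA
#' definition, applies the relative-abundance formula, and (when the panel
#' holds a glycoform definition) profiles the glycoforms. Writes one PQA
#' table per run plus a batch summary (runs x PQAs) when `out_dir` is
#' given. Deterministic given its inputs.
#'
#' @param panel List of `pqa_definition` objects.
#' @param runs Named list of [ms_run()] objects, or a character vector of
#'   run file paths (read with [read_run()]).
#' @param params An [integration_params()].
#' @param thresholds A [qc_thresholds()].
#' @param reference_glyco Optional named reference glycoform percentages;
#'   when a measured glycoform deviates more than two-fold from it, an
#'   advisory warning about possible in-source fragmentation is recorded.
#' @param out_dir Optional output directory for CSVs.
#' @return List with `per_run` (list of PQA data.frames), `summary`
#'   (runs x PQAs matrix as data.frame), `glyco` (per-run glycoform
#'   profiles) and `warnings`.
#' @export
run_quantify <- function(panel, runs, params = integration_params(),
                         thresholds = qc_thresholds(),
                         reference_glyco = NULL, out_dir = NULL) {
  if (is.character(runs)) {
    missing <- runs[!file.exists(runs)]
    if (length(missing)) {
      stop(errorCondition(paste("run file not found:", missing[1]),
                          class = c("mam_data_error", "error")))
    }
    runs <- stats::setNames(lapply(runs, read_run),
                            sub("\\.[^.]+$", "", basename(runs)))
  }
  if (is.null(names(runs))) names(runs) <- paste0("run", seq_along(runs))
  validate_panel(panel)
  warnings <- character()
  per_run <- list()
  glyco <- list()
  for (rn in names(runs)) {
    run <- runs[[rn]]
    rows <- list()
    for (def in panel) {
      meas_all <- lapply(def$all_species, function(sp)
        measure_species(run, sp, params))
      if (!is.null(def$glycans)) {
        prof <- tryCatch(glycoform_profile(meas_all), error = function(e) NULL)
        if (!is.null(prof)) {
          glyco[[rn]] <- prof
          if (!is.null(reference_glyco)) {
            for (nm in intersect(names(prof), names(reference_glyco))) {
              if (reference_glyco[[nm]] > 0 &&
                  (prof[[nm]] > 2 * reference_glyco[[nm]] ||
                   prof[[nm]] < reference_glyco[[nm]] / 2)) {
                warnings <- c(warnings, paste0(
                  rn, ": glycoform ", nm, " at ", round(prof[[nm]], 2),
                  "% deviates more than two-fold from the reference (",
                  round(reference_glyco[[nm]], 2),
                  "%) - possible in-source fragmentation; check ",
                  "declustering potential / collision energy"))
              }
            }
          }
        }
      } else {
        names_mod <- vapply(def$modified_species, function(s) s$species_id,
                            character(1))
        meas_mod <- meas_all[vapply(meas_all, function(m)
          m$species$species_id %in% names_mod, logical(1))]
        res <- pqa_relative_abundance(meas_mod, meas_all, def$pqa_id,
                                      thresholds)
        rows[[length(rows) + 1]] <- data.frame(
          pqa_id = res$pqa_id, abundance_pct = res$relative_abundance,
          status = res$status, modified_area = res$modified_area,
          total_area = res$total_area)
      }
    }
    per_run[[rn]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(pqa_id = character(), abundance_pct = numeric(),
                 status = character(), modified_area = numeric(),
                 total_area = numeric())
    rownames(per_run[[rn]]) <- NULL
  }
  pqa_ids <- unique(unlist(lapply(per_run, function(d) d$pqa_id)))
  summary <- data.frame(run_id = names(per_run))
  for (id in pqa_ids) {
    summary[[id]] <- vapply(per_run, function(d) {
      v <- d$abundance_pct[d$pqa_id == id]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (rn in names(per_run)) {
      write_report_csv(per_run[[rn]],
                       file.path(out_dir, paste0("pqa_", rn, ".csv")),
                       "pqa_table v1")
    }
    write_report_csv(summary, file.path(out_dir, "batch_summary.csv"),
                     "batch_summary v1")
    for (rn in names(glyco)) {
      write_report_csv(
        data.frame(glycoform = names(glyco[[rn]]),
                   abundance_pct = as.numeric(glyco[[rn]])),
        file.path(out_dir, paste0("glyco_", rn, ".csv")),
        "glyco_profile v1")
    }
  }
  for (w in warnings) warning(w)
  list(per_run = per_run, summary = summary, glyco = glyco,
       warnings = warnings)
}

validate_panel <- function(panel) {
  if (!length(panel)) {
    stop(errorCondition("empty PQA panel",
                        class = c("mam_validation_error", "error")))
  }
  ok <- vapply(panel, inherits, logical(1), "pqa_definition")
  if (!all(ok)) {
    stop(errorCondition("panel entries must be pqa_definition objects",
                        class = c("mam_validation_error", "error")))
  }
  invisible(TRUE)
}

#' Run new-peak detection for a batch of test runs
#'
#' @param reference An [ms_run()] (or path) used as the control.
#' @param tests Named list of [ms_run()] objects (or paths); must be
#'   non-empty.
#' @param params An [npd_params()].
#' @param mode `"untargeted"` or `"targeted"`.
#' @param out_dir Optional output directory for per-test flag CSVs.
#' @return List with per-test flag tables and a `summary` of category
#'   counts per test run.
#' @export
run_npd <- function(reference, tests, params = npd_params(),
                    mode = "untargeted", out_dir = NULL) {
  if (!length(tests)) {
    stop(errorCondition("empty test-run list",
                        class = c("mam_validation_error", "error")))
  }
  if (is.character(reference)) {
    if (!file.exists(reference)) {
      stop(errorCondition(paste("reference run not found:", reference),
                          class = c("mam_data_error", "error")))
    }
    reference <- read_run(reference)
  }
  if (is.character(tests)) {
    tests <- stats::setNames(lapply(tests, read_run),
                             sub("\\.[^.]+$", "", basename(tests)))
  }
  if (is.null(names(tests))) names(tests) <- paste0("test", seq_along(tests))
  ref_feat <- detect_features(reference, params)
  flags <- list()
  for (tn in names(tests)) {
    tf <- detect_features(tests[[tn]], params)
    flags[[tn]] <- classify_features(match_features(tf, ref_feat, params),
                                     tf, ref_feat, params, mode)
  }
  cats <- c("new", "missing", "changed", "unchanged", "below_threshold")
  summary <- data.frame(test_run = names(flags))
  for (ct in cats) {
    summary[[ct]] <- vapply(flags, function(d) sum(d$category == ct),
                            integer(1))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tn in names(flags)) {
      write_report_csv(flags[[tn]],
                       file.path(out_dir, paste0("npd_", tn, ".csv")),
                       "npd_flags v1")
    }
    write_report_csv(summary, file.path(out_dir, "npd_summary.csv"),
                     "npd_summary v1")
  }
  list(flags = flags, summary = summary)
}

#' Assemble a QC report
#'
#' Computes reference statistics from replicate PQA tables, applies the
#' tiered pass/fail criteria to each sample, reports per-PQA RSD
#' precision, and (when two-site columns are given) a Bland-Altman
#' comparability section.
#'
#' @param samples data.frame of sample measurements: rows = samples,
#'   columns = PQAs, plus a `sample_id` column.
#' @param reference data.frame of reference replicate measurements in the
#'   same layout (>= 2 rows).
#' @param tiers A [tier_criteria()].
#' @param two_site Optional list `list(lab1 =, lab2 =)` of paired numeric
#'   vectors for the Bland-Altman section.
#' @param out_dir Optional output directory.
#' @return List with `verdicts` (long data.frame), `reference_stats`,
#'   `rsd`, and optionally `bland_altman`.
#' @export
run_report <- function(samples, reference, tiers = tier_criteria(),
                       two_site = NULL, out_dir = NULL) {
  if (nrow(reference) < 2) {
    stop(errorCondition("fewer than 2 reference replicates",
                        class = c("mam_validation_error", "error")))
  }
  pqa_cols <- setdiff(names(reference), "sample_id")
  ref_stats <- data.frame(
    pqa_id = pqa_cols,
    mean = vapply(pqa_cols, function(c) mean(reference[[c]]), numeric(1)),
    sd = vapply(pqa_cols, function(c) stats::sd(reference[[c]]), numeric(1)),
    n = nrow(reference))
  rownames(ref_stats) <- NULL
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    for (pc in intersect(pqa_cols, names(samples))) {
      st <- ref_stats[ref_stats$pqa_id == pc, ]
      pf <- pass_fail(samples[[pc]][i], st$mean, st$sd, tiers)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = samples$sample_id[i], pqa_id = pc,
        value = samples[[pc]][i], ref_mean = st$mean, ref_sd = st$sd,
        allowed_low = pf$lower, allowed_high = pf$upper,
        verdict = pf$verdict)
    }
  }
  verdicts <- do.call(rbind, rows)
  rownames(verdicts) <- NULL
  rsd <- suppressWarnings(rsd_report(reference[pqa_cols]))
  out <- list(verdicts = verdicts, reference_stats = ref_stats, rsd = rsd)
  if (!is.null(two_site)) {
    out$bland_altman <- bland_altman(two_site$lab1, two_site$lab2)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_csv(verdicts, file.path(out_dir, "qc_report.csv"),
                     "qc_report v1")
    if (!is.null(out$bland_altman)) {
      ba <- out$bland_altman
      write_report_csv(
        cbind(ba$table, mean_bias = ba$mean_bias, loa_low = ba$loa_low,
              loa_high = ba$loa_high),
        file.path(out_dir, "bland_altman.csv"), "bland_altman v1")
    }
  }
  out
}
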