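# Untargeted new/missing/changed peak detection between a test run and a
# reference run.

#' New-peak-detection parameters
#'
#' Defaults follow the batch-processing flagging rules: peak height > 500
#' counts, peak quality > 0.6, retention-time delta <= 0.2 min, singly
#' charged ions excluded, area fold-change thresholds 20 (untargeted) and
#' 3 (targeted). The cross-run m/z pairing tolerance is 10 ppm.
#'
#' @param min_height Minimum feature apex height in counts.
#' @param min_quality Minimum Gaussian-shape quality in `[0, 1]`.
#' @param rt_delta Maximum retention-time difference for pairing (min).
#' @param mz_tol_ppm m/z pairing tolerance in ppm.
#' @param fold_untargeted,fold_targeted Area fold-change flag thresholds.
#' @param exclude_charge1 Drop singly charged features.
#' @param charge_range Charges considered during deisotoping.
#' @return An `npd_params` list.
#' @export
npd_params <- function(min_height = 500, min_quality = 0.6, rt_delta = 0.2,
                       mz_tol_ppm = 10, fold_untargeted = 20,
                       fold_targeted = 3, exclude_charge1 = TRUE,
                       charge_range = 1:6) {
  stopifnot(min_height > 0, min_quality > 0, rt_delta > 0, mz_tol_ppm > 0,
            fold_untargeted > 0, fold_targeted > 0)
  structure(list(min_height = min_height, min_quality = min_quality,
                 rt_delta = rt_delta, mz_tol_ppm = mz_tol_ppm,
                 fold_untargeted = fold_untargeted,
                 fold_targeted = fold_targeted,
                 exclude_charge1 = exclude_charge1,
                 charge_range = charge_range),
            class = "npd_params")
}

#' Gaussian-shape peak quality
#'
#' Pearson correlation between a chromatographic trace segment and its
#' best-fit Gaussian (moment estimates of centre and width), clipped to
#' `[0, 1]`. Segments with fewer than 3 points score 0.
#'
#' @param rt,intensity Parallel numeric vectors of the segment.
#' @return Quality in `[0, 1]`.
#' @export
peak_quality <- function(rt, intensity) {
  if (length(rt) < 3 || sum(intensity) <= 0) return(0)
  w <- intensity / sum(intensity)
  mu <- sum(w * rt)
  sigma <- sqrt(sum(w * (rt - mu)^2))
  if (sigma <= 0) return(0)
  g <- exp(-(rt - mu)^2 / (2 * sigma^2))
  if (stats::sd(g) == 0 || stats::sd(intensity) == 0) return(0)
  max(0, min(1, stats::cor(intensity, g)))
}

#' Detect untargeted MS1 features
#'
#' Clusters per-spectrum centroids over retention time by m/z, integrates
#' each cluster trace, infers the charge from isotope spacing
#' (delta m/z ~ 1.00335/z, 10 ppm + 0.01 Da tolerance), removes
#' non-monoisotopic cluster members, optionally removes singly charged
#' features, and drops features at or below the minimum height.
#'
#' @param run An [ms_run()] with MS1 spectra.
#' @param params An [npd_params()].
#' @return data.frame of features: `mz`, `rt`, `charge` (0 = unknown),
#'   `height`, `area`, `quality`.
#' @export
detect_features <- function(run, params = npd_params()) {
  empty <- data.frame(mz = numeric(), rt = numeric(), charge = integer(),
                      height = numeric(), area = numeric(),
                      quality = numeric())
  ms1 <- Filter(function(s) s$ms_level == 1L, run$spectra)
  if (!length(ms1)) stop("no MS1 spectra in run ", run$run_id)
  rts <- vapply(ms1, function(s) s$rt, numeric(1))
  cent <- do.call(rbind, lapply(seq_along(ms1), function(i) {
    s <- ms1[[i]]
    if (!length(s$mz)) return(NULL)
    data.frame(scan = i, mz = s$mz, intensity = s$intensity)
  }))
  if (is.null(cent) || !nrow(cent)) return(empty)

  # group centroids by m/z: break where the gap exceeds the tolerance
  o <- order(cent$mz)
  cent <- cent[o, ]
  tol <- pmax(cent$mz * params$mz_tol_ppm * 1e-6, 0.005)
  grp <- cumsum(c(TRUE, diff(cent$mz) > tol[-1]))

  # cheap per-group summaries (weighted m/z, apex scan, apex height)
  wsum <- rowsum(cent$intensity, grp)
  gmz <- rowsum(cent$mz * cent$intensity, grp) / wsum
  ngrp <- nrow(wsum)
  apex_scan <- integer(ngrp)
  apex_h <- numeric(ngrp)
  idx_by_grp <- split(seq_len(nrow(cent)), grp)
  for (g in seq_len(ngrp)) {
    idx <- idx_by_grp[[g]]
    agg <- rowsum(cent$intensity[idx], cent$scan[idx])
    k <- which.max(agg[, 1])
    apex_scan[g] <- as.integer(rownames(agg))[k]
    apex_h[g] <- agg[k, 1]
  }
  feats <- data.frame(mz = as.numeric(gmz), rt = rts[apex_scan],
                      charge = 0L, height = apex_h, area = 0,
                      quality = 0, apex_scan = apex_scan)
  feats <- feats[order(feats$mz), , drop = FALSE]
  rownames(feats) <- NULL
  groups_sorted <- as.integer(names(idx_by_grp))[order(gmz)]

  # deisotope: assign charge to candidate monoisotopic features from the
  # isotope spacing, absorbing the companion isotope features
  seeds <- which(feats$height > params$min_height)
  absorbed <- logical(nrow(feats))
  for (i in seeds[order(-feats$height[seeds])]) {
    if (absorbed[i]) next
    best_z <- 0L
    best_len <- 0L
    best_members <- integer()
    for (z in params$charge_range) {
      members <- integer()
      pos <- i
      repeat {
        target <- feats$mz[pos] + C13_C12_DELTA / z
        tl <- feats$mz[pos] * 10e-6 + 0.01
        lo <- findInterval(target - tl, feats$mz) + 1
        hi <- findInterval(target + tl, feats$mz)
        cand <- if (hi >= lo) lo:hi else integer()
        cand <- cand[!absorbed[cand] &
                       abs(feats$rt[cand] - feats$rt[i]) <= 0.1]
        cand <- setdiff(cand, c(i, members))
        if (!length(cand)) break
        nxt <- cand[which.min(abs(feats$mz[cand] - target))]
        members <- c(members, nxt)
        pos <- nxt
        if (length(members) >= 6) break
      }
      if (length(members) > best_len) {
        best_len <- length(members)
        best_z <- z
        best_members <- members
      }
    }
    if (best_len >= 1) {
      feats$charge[i] <- best_z
      absorbed[best_members] <- TRUE
    }
  }
  keep <- !absorbed & feats$height > params$min_height
  if (params$exclude_charge1) keep <- keep & feats$charge != 1L
  feats <- feats[keep, , drop = FALSE]
  groups_sorted <- groups_sorted[keep]
  if (!nrow(feats)) return(empty)

  # full trace, area and quality for the surviving features only
  for (k in seq_len(nrow(feats))) {
    idx <- idx_by_grp[[as.character(groups_sorted[k])]]
    trace_int <- numeric(length(ms1))
    agg <- rowsum(cent$intensity[idx], cent$scan[idx])
    trace_int[as.integer(rownames(agg))] <- agg[, 1]
    apex <- feats$apex_scan[k]
    left <- apex
    while (left > 1 && trace_int[left - 1] > 0) left <- left - 1
    right <- apex
    while (right < length(trace_int) && trace_int[right + 1] > 0) {
      right <- right + 1
    }
    seg <- left:right
    feats$area[k] <- if (length(seg) > 1) {
      sum(diff(rts[seg]) * (trace_int[seg][-length(seg)] +
                              trace_int[seg][-1]) / 2)
    } else 0
    feats$quality[k] <- peak_quality(rts[seg], trace_int[seg])
  }
  feats$apex_scan <- NULL
  rownames(feats) <- NULL
  feats
}

#' Pair features between a test and a reference run
#'
#' Greedy nearest matching ordered by ppm distance then retention-time
#' distance, requiring `|dRT| <= rt_delta` and `|dm/z| <= mz_tol_ppm`;
#' every feature is matched at most once, unmatched features are paired
#' with `NA`.
#'
#' @param test,ref Feature data.frames from [detect_features()].
#' @param params An [npd_params()].
#' @return data.frame with columns `test_idx`, `ref_idx` (`NA` when
#'   unmatched).
#' @export
match_features <- function(test, ref, params = npd_params()) {
  cand <- expand.grid(test_idx = seq_len(nrow(test)),
                      ref_idx = seq_len(nrow(ref)))
  if (nrow(cand)) {
    dmz <- abs(test$mz[cand$test_idx] - ref$mz[cand$ref_idx])
    ppm <- dmz / ref$mz[cand$ref_idx] * 1e6
    drt <- abs(test$rt[cand$test_idx] - ref$rt[cand$ref_idx])
    cand <- cand[ppm <= params$mz_tol_ppm & drt <= params$rt_delta, ,
                 drop = FALSE]
    ppm <- ppm[as.integer(rownames(cand))]
    drt <- drt[as.integer(rownames(cand))]
    cand <- cand[order(ppm, drt), , drop = FALSE]
  }
  used_t <- logical(nrow(test))
  used_r <- logical(nrow(ref))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    ti <- cand$test_idx[k]
    ri <- cand$ref_idx[k]
    if (used_t[ti] || used_r[ri]) next
    used_t[ti] <- TRUE
    used_r[ri] <- TRUE
    pairs[[length(pairs) + 1]] <- data.frame(test_idx = ti, ref_idx = ri)
  }
  un_t <- which(!used_t)
  un_r <- which(!used_r)
  out <- rbind(
    if (length(pairs)) do.call(rbind, pairs),
    if (length(un_t)) data.frame(test_idx = un_t, ref_idx = NA_integer_),
    if (length(un_r)) data.frame(test_idx = NA_integer_, ref_idx = un_r)
  )
  if (is.null(out)) {
    out <- data.frame(test_idx = integer(), ref_idx = integer())
  }
  rownames(out) <- NULL
  out
}

#' Classify paired features as new / missing / changed / unchanged
#'
#' Test-only features passing the height and quality gates are `new`;
#' reference-only features passing are `missing`; features present in both
#' are `changed` when the area fold change (test/reference) is at or above
#' the mode's threshold, or at or below its inverse (the rule is
#' symmetric; the direction is recorded), else `unchanged`. Gate failures
#' are reported as `below_threshold` with a per-rule record.
#'
#' @param pairs Output of [match_features()].
#' @param test,ref The feature data.frames the pair indices refer to.
#' @param params An [npd_params()].
#' @param mode `"untargeted"` (fold threshold 20) or `"targeted"` (3).
#' @return data.frame of flags: `category`, feature coordinates,
#'   `fold_change`, `direction`, and per-criterion booleans `pass_height`,
#'   `pass_quality`.
#' @export
classify_features <- function(pairs, test, ref, params = npd_params(),
                              mode = c("untargeted", "targeted")) {
  mode <- match.arg(mode)
  fold_thr <- if (mode == "untargeted") params$fold_untargeted else
    params$fold_targeted
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    ti <- pairs$test_idx[k]
    ri <- pairs$ref_idx[k]
    tf <- if (!is.na(ti)) test[ti, ] else NULL
    rf <- if (!is.na(ri)) ref[ri, ] else NULL
    lead <- if (!is.null(tf)) tf else rf
    pass_h <- lead$height > params$min_height
    pass_q <- lead$quality > params$min_quality
    fold <- NA_real_
    direction <- NA_character_
    if (!is.null(tf) && !is.null(rf)) fold <- tf$area / rf$area
    if (!pass_h || !pass_q) {
      category <- "below_threshold"
    } else if (!is.null(tf) && !is.null(rf)) {
      if (fold >= fold_thr) {
        category <- "changed"
        direction <- "up"
      } else if (fold <= 1 / fold_thr) {
        category <- "changed"
        direction <- "down"
      } else {
        category <- "unchanged"
      }
    } else if (!is.null(tf)) {
      category <- "new"
    } else {
      category <- "missing"
    }
    data.frame(category = category, mz = lead$mz, rt = lead$rt,
               charge = lead$charge, height = lead$height,
               quality = lead$quality, fold_change = fold,
               direction = direction, pass_height = pass_h,
               pass_quality = pass_q)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(), mz = numeric(), rt = numeric(),
               charge = integer(), height = numeric(), quality = numeric(),
               fold_change = numeric(), direction = character(),
               pass_height = logical(), pass_quality = logical())
  rownames(out) <- NULL
  out
}

#' Compare a test run against a reference run
#'
#' Convenience wrapper: detect features in both runs, pair them, and
#' classify.
#'
#' @param test_run,ref_run [ms_run()] objects.
#' @param params An [npd_params()].
#' @param mode Fold-change mode, see [classify_features()].
#' @return The flag data.frame of [classify_features()].
#' @export
npd_compare <- function(test_run, ref_run, params = npd_params(),
                        mode = "untargeted") {
  tf <- detect_features(test_run, params)
  rf <- detect_features(ref_run, params)
  classify_features(match_features(tf, rf, params), tf, rf, params, mode)
}
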