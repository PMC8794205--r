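# Independent brute-force oracles and fixture builders used across the
# suite. Each oracle is written naively from the stated rule, not from the
# package's implementation.

# --- digestion oracle: test every substring against the cleavage rule ----
oracle_digest <- function(residues, max_missed) {
  s <- strsplit(residues, "")[[1]]
  n <- length(s)
  is_cut <- function(i) {
    # cleavage between position i and i+1
    i >= 1 && i < n && s[i] %in% c("K", "R") && s[i + 1] != "P"
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      left_ok <- (i == 1) || is_cut(i - 1)
      right_ok <- (j == n) || is_cut(j)
      if (!left_ok || !right_ok) next
      internal <- if (j > i) {
        sum(vapply(i:(j - 1), is_cut, logical(1)))
      } else 0
      if (internal <= max_missed) {
        out[[length(out) + 1]] <- data.frame(
          start = i, end = j,
          sequence = paste(s[i:j], collapse = ""),
          missed_cleavages = internal)
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

random_chain <- function(len) {
  paste(sample(names(mamtools:::AA_MONO), len, replace = TRUE),
        collapse = "")
}

# --- xic trace construction ---------------------------------------------
make_trace <- function(rt, intensity, target_mz = 500, window = 0.02) {
  structure(list(target_mz = target_mz, window = window, rt = rt,
                 intensity = intensity), class = "xic_trace")
}

# --- peak integration oracle: exhaustive local-extrema scan --------------
# Independent naive re-derivation of the integration contract.
oracle_integrate <- function(trace, params) {
  y <- trace$intensity
  n <- length(y)
  if (n < 3) return(NULL)
  # gaussian smoothing by direct kernel sums
  s <- numeric(n)
  if (params$gaussian_smooth_width > 0) {
    h <- max(1, ceiling(4 * params$gaussian_smooth_width))
    k <- dnorm(-h:h, sd = params$gaussian_smooth_width)
    k <- k / sum(k)
    for (i in seq_len(n)) {
      acc <- 0
      wsum <- 0
      for (d in -h:h) {
        j <- i + d
        if (j >= 1 && j <= n) {
          acc <- acc + k[d + h + 1] * y[j]
          wsum <- wsum + k[d + h + 1]
        }
      }
      s[i] <- acc / wsum
    }
  } else {
    s <- y
  }
  srt <- sort(s)
  kk <- max(1, ceiling(n * params$noise_percentage / 100))
  noise <- if (all(s == 0)) 0 else mean(srt[1:kk])
  thr <- max(params$min_peak_height, params$sn_threshold * noise)
  apexes <- c()
  for (i in seq_len(n)) {
    left <- if (i == 1) -Inf else s[i - 1]
    right <- if (i == n) -Inf else s[i + 1]
    if (s[i] >= thr && s[i] >= left && s[i] > right) apexes <- c(apexes, i)
  }
  if (!length(apexes)) return(NULL)
  # merge adjacent apexes whose apex/valley ratio is below the splitting
  groups <- list(apexes[1])
  if (length(apexes) > 1) {
    for (i in 2:length(apexes)) {
      prev <- groups[[length(groups)]]
      a1 <- prev[which.max(s[prev])]
      a2 <- apexes[i]
      valley <- min(s[a1:a2])
      ratio <- min(s[a1], s[a2]) / max(valley, .Machine$double.eps)
      if (ratio >= params$peak_splitting) {
        groups[[length(groups) + 1]] <- a2
      } else {
        groups[[length(groups)]] <- c(prev, a2)
      }
    }
  }
  out <- list()
  for (g in groups) {
    apex <- g[which.max(s[g])]
    left <- g[1]
    while (left > 1 && s[left - 1] < s[left]) left <- left - 1
    right <- g[length(g)]
    while (right < n && s[right + 1] < s[right]) right <- right + 1
    if (right - left + 1 < params$min_peak_width) next
    bw <- params$baseline_window
    lb <- mean(y[max(1, left - bw + 1):left])
    rb <- mean(y[right:min(n, right + bw - 1)])
    area <- 0
    prev_v <- NULL
    for (i in left:right) {
      base <- lb + (rb - lb) * (i - left) / max(right - left, 1)
      v <- max(y[i] - base, 0)
      if (!is.null(prev_v)) {
        area <- area + (trace$rt[i] - trace$rt[i - 1]) * (prev_v + v) / 2
      }
      prev_v <- v
    }
    heights <- sapply(left:right, function(i) {
      base <- lb + (rb - lb) * (i - left) / max(right - left, 1)
      max(y[i] - base, 0)
    })
    out[[length(out) + 1]] <- data.frame(
      rt_apex = trace$rt[apex], rt_start = trace$rt[left],
      rt_end = trace$rt[right], height = max(heights), area = area,
      sn = if (noise > 0) max(heights) / noise else Inf)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# --- NPD classification oracle: literal rule table -----------------------
oracle_classify <- function(pairs, test, ref, params, mode) {
  thr <- if (mode == "untargeted") params$fold_untargeted else
    params$fold_targeted
  cats <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ti <- pairs$test_idx[k]
    ri <- pairs$ref_idx[k]
    lead <- if (!is.na(ti)) test[ti, ] else ref[ri, ]
    gates <- lead$height > params$min_height &&
      lead$quality > params$min_quality
    if (!gates) {
      cats[k] <- "below_threshold"
    } else if (!is.na(ti) && !is.na(ri)) {
      fold <- test$area[ti] / ref$area[ri]
      cats[k] <- if (fold >= thr || fold <= 1 / thr) "changed" else
        "unchanged"
    } else if (!is.na(ti)) {
      cats[k] <- "new"
    } else {
      cats[k] <- "missing"
    }
  }
  cats
}

random_features <- function(n) {
  data.frame(mz = runif(n, 300, 1500), rt = runif(n, 0, 10),
             charge = sample(2:4, n, replace = TRUE),
             height = runif(n, 100, 5000), area = runif(n, 10, 1e4),
             quality = runif(n))
}

# --- run fixtures --------------------------------------------------------
# flat run of empty MS1 spectra
blank_run <- function(n_spectra = 120, dt = 0.0225, run_id = "blank") {
  ms_run(run_id, lapply(seq_len(n_spectra) - 1, function(i)
    spectrum_record(1L, i * dt, numeric(), numeric())))
}

# spike an isotope-resolved chromatographic feature into a run
spike_feature <- function(run, mz, rt, height, sigma = 0.05, charge = 2,
                          n_iso = 3, iso_decay = 0.6) {
  for (i in seq_along(run$spectra)) {
    s <- run$spectra[[i]]
    if (s$ms_level != 1L) next
    amp <- height * exp(-(s$rt - rt)^2 / (2 * sigma^2))
    if (amp < 0.5) next
    mzs <- mz + (0:(n_iso - 1)) * mamtools:::C13_C12_DELTA / charge
    ints <- amp * iso_decay^(0:(n_iso - 1))
    run$spectra[[i]] <- spectrum_record(1L, s$rt, c(s$mz, mzs),
                                        c(s$intensity, ints))
  }
  run
}
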