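#' Per-frequency standard event-related potentials
#'
#' Step 1 of the single-trial MMN estimation: for every tone frequency
#' that occurs as a deviant, average the epochs of its sixth-in-a-row
#' presentations (the "standard" trials) into an electrodes x samples ERP.
#'
#' @param epochs An `epoch_array` (trials x electrodes x samples).
#' @param trials The matching `trial_table`.
#' @return Named list (key: frequency in Hz, as formatted by
#'   `format_freq_key()`) of electrodes x samples matrices.
#' @export
compute_standard_erps <- function(epochs, trials) {
  stopifnot(inherits(epochs, "epoch_array"))
  dev_freqs <- unique(trials$frequency_hz[trials$is_deviant])
  erps <- list()
  missing <- character(0)
  for (f in dev_freqs) {
    idx <- which(trials$is_standard6 & trials$frequency_hz == f)
    if (length(idx) == 0L) {
      missing <- c(missing, format(f))
      next
    }
    sub <- epochs$data[idx, , , drop = FALSE]
    erps[[format_freq_key(f)]] <- apply(sub, c(2L, 3L), mean)
  }
  if (length(missing) > 0L) {
    stop("no sixth-presentation standard trials for deviant frequencies: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  erps
}

format_freq_key <- function(f) sprintf("%.6f", f)

#' Baseline-corrected deviance-specific potentials
#'
#' Steps 1-2 of the estimation: for each deviant trial, subtract the
#' standard ERP of the same tone, then subtract each electrode's mean
#' potential over the 100 ms preceding tone onset (baseline correction,
#' removing any DC offset).
#'
#' @inheritParams compute_standard_erps
#' @param standard_erps Output of [compute_standard_erps()].
#' @return List of class `deviance_potentials`: `data` (deviants x
#'   electrodes x samples), `deviant_trial_indices`, `times_ms`.
#' @export
deviance_potentials <- function(epochs, trials, standard_erps) {
  times <- epochs$times_ms
  base_idx <- which(times >= -100 & times < 0)
  if (length(base_idx) == 0L) {
    stop("baseline window [-100, 0) ms not inside the epoch", call. = FALSE)
  }
  dev_idx <- which(trials$is_deviant)
  n_elec <- dim(epochs$data)[2L]
  out <- array(0, dim = c(length(dev_idx), n_elec, length(times)))
  for (i in seq_along(dev_idx)) {
    t <- dev_idx[i]
    erp <- standard_erps[[format_freq_key(trials$frequency_hz[t])]]
    if (is.null(erp)) {
      stop("missing standard ERP for frequency ", trials$frequency_hz[t],
           call. = FALSE)
    }
    d <- epochs$data[t, , ] - erp
    d <- d - rowMeans(d[, base_idx, drop = FALSE])
    out[i, , ] <- d
  }
  structure(
    list(data = out, deviant_trial_indices = dev_idx, times_ms = times),
    class = "deviance_potentials"
  )
}

#' Estimate the subject's MMN peak latency
#'
#' Step 3: the minimum of the average difference wave (mean over deviants
#' and the given electrodes) between 100 and 200 ms after tone onset. Ties
#' resolve to the earlier sample.
#'
#' @param diffs A `deviance_potentials` object.
#' @param electrodes Electrode indices to average over (default: all).
#' @return Peak latency in ms (a sample time on the epoch grid).
#' @export
estimate_peak_latency <- function(diffs, electrodes = NULL) {
  times <- diffs$times_ms
  win <- which(times >= 100 & times <= 200)
  if (length(win) == 0L) stop("epoch does not cover 100-200 ms", call. = FALSE)
  if (is.null(electrodes)) electrodes <- seq_len(dim(diffs$data)[2L])
  wave <- apply(diffs$data[, electrodes, win, drop = FALSE], 3L, mean)
  times[win][which.min(wave)] # which.min: first (earliest) index on ties
}

#' Extract trial-wise MMN amplitudes
#'
#' Step 4: for each deviant and electrode, average the deviance-specific
#' potential over a window of width `window_ms` centered at the peak
#' latency.
#'
#' @inheritParams estimate_peak_latency
#' @param peak_latency_ms Center of the extraction window (ms).
#' @param window_ms Window width (ms); default 50.
#' @return List of class `amplitude_matrix`: `values` (deviants x
#'   electrodes, microvolts), `deviant_trial_indices`, `peak_latency_ms`,
#'   `window_ms`.
#' @export
extract_amplitudes <- function(diffs, peak_latency_ms, window_ms = 50) {
  times <- diffs$times_ms
  lo <- peak_latency_ms - window_ms / 2
  hi <- peak_latency_ms + window_ms / 2
  if (lo < times[1L] || hi > times[length(times)]) {
    stop("extraction window exceeds the epoch", call. = FALSE)
  }
  win <- which(times >= lo - 1e-9 & times <= hi + 1e-9)
  vals <- apply(diffs$data[, , win, drop = FALSE], c(1L, 2L), mean)
  structure(
    list(values = vals, deviant_trial_indices = diffs$deviant_trial_indices,
         peak_latency_ms = peak_latency_ms, window_ms = window_ms),
    class = "amplitude_matrix"
  )
}

#' Select electrodes showing a reliable MMN
#'
#' For each candidate electrode, the mean potential in the MMN window is
#' compared by paired one-sided t-tests (across deviants) against the
#' mean potentials in the immediately preceding and following windows of
#' equal width. An electrode is retained if both tests show the MMN-window
#' mean to be significantly more negative at the Sidak-corrected per-test
#' level `1 - (1 - fwe_level)^(1/m)`, where `m` is the number of
#' candidates. Degenerate (zero-variance) electrodes are excluded with a
#' warning.
#'
#' @inheritParams extract_amplitudes
#' @param candidate_electrodes Electrode indices to test (default: all).
#' @param fwe_level Family-wise error level (default 0.05).
#' @return Integer vector of retained electrode indices (possibly empty).
#' @export
select_electrodes <- function(diffs, peak_latency_ms, window_ms = 50,
                              candidate_electrodes = NULL, fwe_level = 0.05) {
  if (is.null(candidate_electrodes)) {
    candidate_electrodes <- seq_len(dim(diffs$data)[2L])
  }
  if (dim(diffs$data)[1L] < 2L) {
    stop("electrode selection needs at least 2 deviants", call. = FALSE)
  }
  m <- length(candidate_electrodes)
  alpha <- sidak_alpha(fwe_level, m)
  times <- diffs$times_ms
  half <- window_ms / 2
  w_mmn <- which(times >= peak_latency_ms - half - 1e-9 &
                   times <= peak_latency_ms + half + 1e-9)
  w_pre <- which(times >= peak_latency_ms - 3 * half - 1e-9 &
                   times < peak_latency_ms - half - 1e-9)
  w_post <- which(times > peak_latency_ms + half + 1e-9 &
                    times <= peak_latency_ms + 3 * half + 1e-9)
  if (length(w_pre) == 0L || length(w_post) == 0L) {
    stop("comparison windows fall outside the epoch", call. = FALSE)
  }
  keep <- logical(m)
  for (j in seq_len(m)) {
    k <- candidate_electrodes[j]
    mmn <- apply(diffs$data[, k, w_mmn, drop = FALSE], 1L, mean)
    pre <- apply(diffs$data[, k, w_pre, drop = FALSE], 1L, mean)
    post <- apply(diffs$data[, k, w_post, drop = FALSE], 1L, mean)
    p1 <- tryCatch(
      stats::t.test(mmn, pre, paired = TRUE, alternative = "less")$p.value,
      error = function(e) NA_real_
    )
    p2 <- tryCatch(
      stats::t.test(mmn, post, paired = TRUE, alternative = "less")$p.value,
      error = function(e) NA_real_
    )
    if (is.na(p1) || is.na(p2)) {
      warning("electrode ", k, " excluded: degenerate (zero-variance) data",
              call. = FALSE)
      next
    }
    keep[j] <- p1 < alpha && p2 < alpha
  }
  candidate_electrodes[keep]
}

#' Sidak-corrected per-test significance level
#'
#' @param fwe_level Target family-wise error rate.
#' @param m Number of tests.
#' @return Per-test level `1 - (1 - fwe_level)^(1/m)`.
#' @export
sidak_alpha <- function(fwe_level, m) 1 - (1 - fwe_level)^(1 / m)

#' Full single-trial MMN extraction pipeline
#'
#' Runs the four estimation steps plus electrode selection: standard ERPs,
#' deviance-specific potentials, a provisional peak latency over all
#' candidate electrodes, Sidak electrode selection around that latency,
#' then the final latency and windowed-mean amplitudes over the selected
#' electrodes. Subjects with no surviving electrode are flagged (empty
#' selection; amplitudes restricted to selected electrodes are then
#' empty) rather than silently dropped.
#'
#' @inheritParams compute_standard_erps
#' @param window_ms Extraction window width (ms).
#' @param fwe_level Family-wise error level for electrode selection, or
#'   `NULL` to skip selection and keep all electrodes.
#' @return List of class `mmn_extraction`: `amplitudes` (an
#'   `amplitude_matrix` over the retained electrodes), `selected_electrodes`,
#'   `peak_latency_ms`, `flagged` (`TRUE` if no electrode survived).
#' @export
extract_mmn <- function(epochs, trials, window_ms = 50, fwe_level = 0.05) {
  erps <- compute_standard_erps(epochs, trials)
  diffs <- deviance_potentials(epochs, trials, erps)
  lat0 <- estimate_peak_latency(diffs)
  if (is.null(fwe_level)) {
    selected <- seq_len(dim(diffs$data)[2L])
  } else {
    selected <- select_electrodes(diffs, lat0, window_ms,
                                  fwe_level = fwe_level)
  }
  flagged <- length(selected) == 0L
  lat <- if (flagged) lat0 else estimate_peak_latency(diffs, selected)
  amps <- extract_amplitudes(diffs, lat, window_ms)
  amps$values <- amps$values[, selected, drop = FALSE]
  structure(
    list(amplitudes = amps, selected_electrodes = selected,
         peak_latency_ms = lat, flagged = flagged),
    class = "mmn_extraction"
  )
}
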