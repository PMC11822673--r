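#' Configuration for cystometric landmark extraction
#'
#' @param smooth_width_s zero-phase moving-average width, seconds (the raw
#'   trace is always retained).
#' @param pmax_window_s half-width of the Pmax search window around flow
#'   onset, seconds (the void-associated maximum occurs at flow onset).
#' @param peak_smooth_width_s shorter moving-average width used for the
#'   peak-adjacent landmarks (Pmax, Pend), where heavy smoothing would clip
#'   the narrow void-associated peak.
#' @param pbase_quantile robust low quantile of storage-phase pressure used
#'   for Pbase (default 10th percentile; robust to NVCs).
#' @param k_noise Pthresh must exceed Pbase + k_noise x estimated noise SD.
#' @param slope_fraction the voiding contraction is the final pre-peak run
#'   whose smoothed slope exceeds this fraction of the peak slope; Pthresh is
#'   the pressure where that run starts.
#' @param storage_margin_s seconds trimmed after the previous flow end before
#'   the storage phase is considered established.
#' @param min_storage_s minimum usable storage-phase duration; shorter
#'   storage flags the cycle unusable.
#' @param cv_bound coefficient-of-variation bound on 3 consecutive intervoid
#'   intervals defining an established regular fill/void pattern.
#' @export
cmg_config <- function(smooth_width_s = 0.5,
                       pmax_window_s = 5,
                       peak_smooth_width_s = 0.2,
                       pbase_quantile = 0.1,
                       k_noise = 3,
                       slope_fraction = 0.1,
                       storage_margin_s = 5,
                       min_storage_s = 15,
                       cv_bound = 0.5) {
  structure(list(smooth_width_s = smooth_width_s, pmax_window_s = pmax_window_s,
                 peak_smooth_width_s = peak_smooth_width_s,
                 pbase_quantile = pbase_quantile, k_noise = k_noise,
                 slope_fraction = slope_fraction, storage_margin_s = storage_margin_s,
                 min_storage_s = min_storage_s, cv_bound = cv_bound),
            class = "cmg_config")
}

# zero-phase (centred) moving average
smooth_ma <- function(x, width_samples) {
  w <- max(1L, as.integer(round(width_samples)))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  k <- rep(1 / w, w)
  n <- length(x)
  xp <- c(rep(x[1L], w), x, rep(x[n], w))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(w + 1L):(w + n)])
}

#' Detect voids in a cystometry trace
#'
#' A void is a sustained rise of the collected-volume channel of at least
#' `min_void_volume`; onset/end are where the smoothed volume derivative
#' crosses its noise floor. Nonvoiding contractions live in the pressure
#' channel only and can never be detected here.
#'
#' @param trace a [cmg_trace()].
#' @param min_void_volume mL; smaller rises are ignored.
#' @param min_separation s; onsets closer than this are merged (largest rise
#'   kept).
#' @param config a [cmg_config()].
#' @return data.frame with `flow_onset_time`, `flow_end_time`,
#'   `voided_volume` (one row per void; zero rows if none).
#' @export
detect_voids <- function(trace, min_void_volume = 0.02, min_separation = 20,
                         config = cmg_config()) {
  dt <- 1 / trace$sample_rate
  v <- smooth_ma(trace$volume, 0.3 * trace$sample_rate)
  dv <- c(diff(v), 0) / dt
  # noise floor of the derivative: robust scale + absolute floor from the
  # requested minimum void size spread over a generous 30 s
  floor_abs <- min_void_volume / 30
  thr <- max(4 * mad(dv, center = 0), floor_abs)
  above <- dv > thr
  if (!any(above)) {
    return(data.frame(flow_onset_time = numeric(0), flow_end_time = numeric(0),
                      voided_volume = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < 1 s
  if (nrow(runs) > 1L) {
    gap <- (runs$start[-1L] - runs$end[-nrow(runs)]) * dt
    grp <- cumsum(c(TRUE, gap >= 1))
    runs <- data.frame(start = tapply(runs$start, grp, min),
                       end = tapply(runs$end, grp, max))
  }
  # refine onset/end to the half-plateau crossings of the derivative, which
  # locates the edges of the (smoothing-trapezoided) flow plateau; the
  # plateau level is the run median of a re-smoothed derivative so a single
  # noise-inflated sample can neither set nor break the edge walk
  n <- length(v)
  dv2 <- smooth_ma(dv, 0.2 * trace$sample_rate)
  for (i in seq_len(nrow(runs))) {
    seg <- runs$start[i]:runs$end[i]
    half <- median(dv2[seg]) / 2
    pk <- seg[which.max(dv2[seg])]
    s0 <- pk
    while (s0 > 1L && dv2[s0 - 1L] >= half) s0 <- s0 - 1L
    e0 <- pk
    while (e0 < n && dv2[e0 + 1L] >= half) e0 <- e0 + 1L
    runs$start[i] <- s0; runs$end[i] <- e0
  }
  # volume rise across each run, measured clear of the smoothing spread
  marg <- as.integer(round(0.5 * trace$sample_rate))
  lo <- pmax(1L, runs$start - marg); hi <- pmin(n, runs$end + marg)
  rise <- v[hi] - v[lo]
  runs <- runs[rise >= min_void_volume, , drop = FALSE]
  rise <- rise[rise >= min_void_volume]
  if (nrow(runs) > 1L) {
    keep <- rep(TRUE, nrow(runs))
    for (i in 2:nrow(runs)) {
      prev <- max(which(keep[1:(i - 1)]))
      if ((runs$start[i] - runs$start[prev]) * dt < min_separation) {
        if (rise[i] > rise[prev]) keep[prev] <- FALSE else keep[i] <- FALSE
      }
    }
    runs <- runs[keep, , drop = FALSE]; rise <- rise[keep]
  }
  data.frame(flow_onset_time = trace$time[runs$start],
             flow_end_time = trace$time[runs$end],
             voided_volume = rise)
}

#' Extract per-cycle cystometric landmarks around one detected void
#'
#' Pmax is the maximum smoothed pressure in a window centred on flow onset
#' (the void-associated peak occurs at flow onset). Pbase is a robust low
#' quantile of storage-phase pressure, which makes it insensitive to
#' nonvoiding contractions. Pthresh is the pressure at the start of the
#' final voiding contraction: the last pre-peak run whose smoothed slope
#' exceeds `slope_fraction` of the peak slope, floored at
#' `Pbase + k_noise x sigma` so noise wiggles never qualify. Pend is the
#' (smoothed) pressure at flow end. A storage phase shorter than
#' `min_storage_s` flags the cycle unusable.
#'
#' @param trace a [cmg_trace()].
#' @param void one row of [detect_voids()] output.
#' @param prev_end flow end time of the previous void (or `NULL` for the
#'   first cycle; the trace start is used).
#' @param config a [cmg_config()].
#' @return one-row data.frame (class-free): Pbase, Pthresh, Pmax, Pend, their
#'   times, flow onset/end, voided volume, mean flow rate, `usable` flag and
#'   `reason`.
#' @export
extract_landmarks <- function(trace, void, prev_end = NULL, config = cmg_config()) {
  extract_landmarks_presmoothed(trace, cmg_smoothed(trace, config), void,
                                prev_end, config)
}

# internal: the smoothed signals used by the extractor, computed once per trace
cmg_smoothed <- function(trace, config) {
  dt <- 1 / trace$sample_rate
  ps <- smooth_ma(trace$pressure, config$smooth_width_s * trace$sample_rate)
  list(ps = ps,
       ps_short = smooth_ma(trace$pressure,
                            config$peak_smooth_width_s * trace$sample_rate),
       dp = smooth_ma(c(0, diff(ps)) / dt,
                      config$smooth_width_s * trace$sample_rate))
}

# internal: landmark extraction with the smoothed signals precomputed once
extract_landmarks_presmoothed <- function(trace, sm, void, prev_end, config) {
  ps <- sm$ps
  dt <- 1 / trace$sample_rate
  n <- length(ps)
  onset_i <- which.min(abs(trace$time - void$flow_onset_time))
  end_i <- which.min(abs(trace$time - void$flow_end_time))
  bad <- function(reason) data.frame(
    Pbase = NA_real_, Pthresh = NA_real_, Pmax = NA_real_, Pend = NA_real_,
    t_pbase = NA_real_, t_pthresh = NA_real_, t_pmax = NA_real_,
    flow_onset_time = void$flow_onset_time, flow_end_time = void$flow_end_time,
    voided_volume = void$voided_volume,
    mean_flow_rate = void$voided_volume / (void$flow_end_time - void$flow_onset_time),
    usable = FALSE, reason = reason)
  st0 <- if (is.null(prev_end)) 1L
         else min(n, which.min(abs(trace$time - prev_end)) +
                    round(config$storage_margin_s / dt))
  st1 <- onset_i - 1L
  if (st1 <= st0 || (st1 - st0) * dt < config$min_storage_s)
    return(bad("storage_too_short"))
  storage <- ps[st0:st1]
  Pbase <- as.numeric(quantile(storage, config$pbase_quantile))
  t_pbase <- trace$time[st0 + which.min(abs(storage - Pbase)) - 1L]
  sigma <- mad(diff(trace$pressure[st0:st1])) / sqrt(2)
  # Pmax in a window centred on flow onset
  w0 <- max(1L, onset_i - round(config$pmax_window_s / dt))
  w1 <- min(n, onset_i + round(config$pmax_window_s / dt))
  pk_rel <- which.max(sm$ps_short[w0:w1])
  pk <- w0 + pk_rel - 1L
  Pmax <- sm$ps_short[pk]
  # voiding contraction: last pre-peak run of steep positive slope
  dp <- sm$dp
  look0 <- max(st0, pk - round(3 * config$pmax_window_s / dt))
  seg <- dp[look0:pk]
  peak_slope <- max(seg)
  if (!is.finite(peak_slope) || peak_slope <= 0) return(bad("no_pressure_rise"))
  steep <- seg > config$slope_fraction * peak_slope
  if (!steep[length(steep)]) {
    last_true <- max(which(steep), -Inf)
    if (!is.finite(last_true)) return(bad("no_pressure_rise"))
  } else last_true <- length(steep)
  run_start <- last_true
  while (run_start > 1L && steep[run_start - 1L]) run_start <- run_start - 1L
  thr_i <- look0 + run_start - 1L
  Pthresh <- ps[thr_i]
  floor_p <- Pbase + config$k_noise * max(sigma, 1e-9)
  if (Pthresh < floor_p) {
    # walk forward to the floor crossing within the contraction
    j <- thr_i
    while (j < pk && ps[j] < floor_p) j <- j + 1L
    thr_i <- j; Pthresh <- ps[j]
  }
  if (Pthresh >= Pmax) return(bad("no_threshold_crossing"))
  # Pend: the voiding decay / relaxation slope break near flow end carries a
  # sharper timing signature in the pressure channel than the volume edge
  end_ref <- end_i
  w_in0 <- onset_i + round(0.4 / dt); w_in1 <- end_i - round(0.4 / dt)
  w_out0 <- end_i + round(0.4 / dt); w_out1 <- min(n, end_i + round(1.2 / dt))
  if (w_in1 > w_in0 + 2L && w_out1 > w_out0 + 2L) {
    s_in <- median(dp[w_in0:w_in1]); s_out <- median(dp[w_out0:w_out1])
    if (is.finite(s_in) && is.finite(s_out) && abs(s_in - s_out) > 1e-6) {
      win <- max(1L, end_i - round(0.7 / dt)):min(n, end_i + round(0.7 / dt))
      end_ref <- win[which.min(abs(dp[win] - (s_in + s_out) / 2))]
    }
  }
  Pend <- sm$ps_short[end_ref]
  data.frame(Pbase = Pbase, Pthresh = Pthresh, Pmax = Pmax, Pend = Pend,
             t_pbase = t_pbase, t_pthresh = trace$time[thr_i],
             t_pmax = trace$time[pk],
             flow_onset_time = void$flow_onset_time,
             flow_end_time = void$flow_end_time,
             voided_volume = void$voided_volume,
             mean_flow_rate = void$voided_volume /
               (void$flow_end_time - void$flow_onset_time),
             usable = TRUE, reason = "")
}

#' Analyze a full cystometry trace into per-cycle landmark records
#'
#' Runs [detect_voids()] then [extract_landmarks()] per cycle and computes
#' the intervoid interval (IVI) onset-to-onset between sequential voids (the
#' last cycle has no following void, hence `NA`).
#'
#' @param trace a [cmg_trace()].
#' @param min_void_volume,min_separation passed to [detect_voids()].
#' @param config a [cmg_config()].
#' @return data.frame, one row per detected void cycle.
#' @export
cmg_cycles <- function(trace, min_void_volume = 0.02, min_separation = 20,
                       config = cmg_config()) {
  voids <- detect_voids(trace, min_void_volume, min_separation, config)
  if (nrow(voids) == 0L) {
    out <- extract_landmarks(trace,
      data.frame(flow_onset_time = NA, flow_end_time = NA, voided_volume = NA),
      config = config)[0, ]
    out$cycle <- integer(0); out$ivi <- numeric(0)
    return(out)
  }
  sm <- cmg_smoothed(trace, config)
  rows <- vector("list", nrow(voids))
  for (k in seq_len(nrow(voids))) {
    prev_end <- if (k == 1L) NULL else voids$flow_end_time[k - 1L]
    rows[[k]] <- extract_landmarks_presmoothed(trace, sm, voids[k, ], prev_end, config)
  }
  out <- do.call(rbind, rows)
  out$cycle <- seq_len(nrow(out))
  out$ivi <- c(diff(voids$flow_onset_time), NA_real_)
  out
}

#' Summarize per-cycle cystometry for one mouse
#'
#' Finds the first run of 3 consecutive usable cycles whose intervoid
#' intervals have a coefficient of variation below `config$cv_bound` (the
#' "established regular fill/void pattern" rule) and averages every variable
#' over those 3 cycles. Fewer than 3 usable cycles, or no regular triple,
#' excludes the mouse with code `no_cycling`. Operator-supplied exclusions
#' (leak, death, bad catheter placement) pass through as machine-readable
#' codes.
#'
#' @param cycles data.frame from [cmg_cycles()].
#' @param config a [cmg_config()].
#' @param exclude optional operator exclusion code (e.g. `"leak"`,
#'   `"death"`, `"bad_catheter"`); returned as-is.
#' @return list of class `mouse_cmg_summary`: `means` (named numeric:
#'   Pbase, Pthresh, Pmax, Pend, IVI, voided_volume, mean_flow_rate),
#'   `cycles_used` (indices), `excluded` (logical), `exclusion_code`.
#' @export
summarize_mouse <- function(cycles, config = cmg_config(), exclude = NULL) {
  if (!is.null(exclude))
    return(structure(list(means = NULL, cycles_used = integer(0),
                          excluded = TRUE, exclusion_code = exclude),
                     class = "mouse_cmg_summary"))
  usable <- which(cycles$usable & !is.na(cycles$ivi))
  pick <- NULL
  for (i in usable) {
    if (!all(c(i + 1L, i + 2L) %in% usable)) next
    iv <- cycles$ivi[i:(i + 2L)]
    if (sd(iv) / mean(iv) < config$cv_bound) { pick <- i:(i + 2L); break }
  }
  if (is.null(pick))
    return(structure(list(means = NULL, cycles_used = integer(0),
                          excluded = TRUE, exclusion_code = "no_cycling"),
                     class = "mouse_cmg_summary"))
  sub <- cycles[pick, ]
  means <- c(Pbase = mean(sub$Pbase), Pthresh = mean(sub$Pthresh),
             Pmax = mean(sub$Pmax), Pend = mean(sub$Pend),
             IVI = mean(sub$ivi), voided_volume = mean(sub$voided_volume),
             mean_flow_rate = mean(sub$mean_flow_rate))
  structure(list(means = means, cycles_used = pick, excluded = FALSE,
                 exclusion_code = NA_character_),
            class = "mouse_cmg_summary")
}

#' @export
print.mouse_cmg_summary <- function(x, ...) {
  if (x$excluded) cat(sprintf("<mouse_cmg_summary> excluded (%s)\n", x$exclusion_code))
  else {
    cat(sprintf("<mouse_cmg_summary> cycles %s\n",
                paste(x$cycles_used, collapse = ", ")))
    print(round(x$means, 3))
  }
  invisible(x)
}
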