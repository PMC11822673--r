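#' Cystometry trace container
#'
#' @param time seconds, uniform strictly increasing grid.
#' @param pressure intravesical pressure, cm H2O.
#' @param volume cumulative collected voided volume, mL (non-decreasing up to
#'   measurement noise).
#' @param sample_rate Hz.
#' @param infusion_rate mL/h.
#' @return object of class `cmg_trace`.
#' @export
cmg_trace <- function(time, pressure, volume, sample_rate, infusion_rate) {
  if (length(time) != length(pressure) || length(time) != length(volume))
    stopf("time, pressure, volume must have equal length")
  if (any(diff(time) <= 0)) stopf("time must be strictly increasing")
  if (sample_rate <= 0) stopf("sample_rate must be positive")
  structure(list(time = time, pressure = pressure, volume = volume,
                 sample_rate = sample_rate, infusion_rate = infusion_rate),
            class = "cmg_trace")
}

#' @export
print.cmg_trace <- function(x, ...) {
  cat(sprintf("<cmg_trace> %.1f s at %g Hz, infusion %g mL/h, %d samples\n",
              max(x$time), x$sample_rate, x$infusion_rate, length(x$time)))
  invisible(x)
}

#' Generate a synthetic cystometrogram (pressure/volume trace)
#'
#' Emulates urethane-anaesthetised continuous-infusion cystometry: per cycle,
#' a storage plateau at baseline pressure (Pbase), a slow filling ramp to the
#' threshold pressure (Pthresh), a rapid voiding contraction peaking at Pmax
#' coincident with flow onset, pressure decline through Pend while the
#' collected-volume channel steps up by exactly `infusion_rate x IVI`
#' (conservation), then relaxation back to baseline. Nonvoiding contractions
#' (NVCs) are sub-threshold pressure transients with no volume step.
#' Defaults mirror a middle-aged animal recorded at 30 Hz under 1.5 mL/h
#' infusion (Pbase 7, Pthresh 16.5, Pmax 53, Pend 25.3 cm H2O, IVI 172.86 s).
#'
#' @param n_cycles number of fill/void cycles.
#' @param landmarks named vector `c(Pbase, Pthresh, Pmax, Pend)` (cm H2O), or
#'   an `n_cycles` x 4 matrix for per-cycle values. Must satisfy
#'   Pbase < Pthresh < Pmax and Pbase <= Pend <= Pmax.
#' @param ivi intervoid interval(s), seconds (scalar or per-cycle).
#' @param infusion_rate mL/h.
#' @param sample_rate Hz.
#' @param nvc_rate nonvoiding contractions per minute of storage.
#' @param nvc_amplitude NVC amplitude, cm H2O (kept sub-threshold).
#' @param noise_sd pressure noise SD, cm H2O.
#' @param volume_noise_sd volume measurement noise SD, mL.
#' @param ramp_s,rise_s,flow_s,relax_s phase durations, seconds: slow filling
#'   ramp, voiding contraction rise, flow (void), relaxation.
#' @param lead_in_s baseline recording before the first cycle, seconds.
#' @param seed integer seed.
#' @return list with `trace` (a [cmg_trace()]) and `truth`: per-cycle
#'   data.frame of programmed landmark values and times (`t_pthresh`,
#'   `flow_onset` = time of Pmax, `flow_end`), voided volume, IVI; NVC times;
#'   parameters; seed.
#' @export
gen_cmg_trace <- function(n_cycles = 5,
                          landmarks = c(Pbase = 7.03, Pthresh = 16.51,
                                        Pmax = 53.01, Pend = 25.32),
                          ivi = 172.86,
                          infusion_rate = 1.5,
                          sample_rate = 30,
                          nvc_rate = 0,
                          nvc_amplitude = 5,
                          noise_sd = 0.5,
                          volume_noise_sd = 0.001,
                          ramp_s = 15, rise_s = 2, flow_s = 2.5, relax_s = 3,
                          lead_in_s = 15,
                          seed = 1L) {
  lm <- landmarks
  if (is.null(dim(lm))) lm <- matrix(rep(as.numeric(lm), each = n_cycles), n_cycles, 4,
                                     dimnames = list(NULL, c("Pbase", "Pthresh", "Pmax", "Pend")))
  lm <- as.matrix(lm)
  if (ncol(lm) != 4L || nrow(lm) != n_cycles) stopf("landmarks must give 4 values per cycle")
  colnames(lm) <- c("Pbase", "Pthresh", "Pmax", "Pend")
  if (any(!(lm[, "Pbase"] < lm[, "Pthresh"] & lm[, "Pthresh"] < lm[, "Pmax"])))
    stopf("infeasible landmark ordering: need Pbase < Pthresh < Pmax")
  if (any(lm[, "Pend"] > lm[, "Pmax"]) || any(lm[, "Pend"] < lm[, "Pbase"]))
    stopf("infeasible landmark ordering: need Pbase <= Pend <= Pmax")
  ivi <- rep(ivi, length.out = n_cycles)
  if (any(ivi <= ramp_s + rise_s + flow_s + relax_s + 5))
    stopf("ivi too short for the phase durations")
  if (sample_rate <= 0) stopf("sample_rate must be positive")

  with_seed(seed, {
    dt <- 1 / sample_rate
    total_s <- lead_in_s + sum(ivi) + relax_s + 5
    n <- ceiling(total_s / dt) + 1L
    tm <- (seq_len(n) - 1L) * dt
    pressure <- numeric(n); volume <- numeric(n)
    seg <- function(t0, t1) which(tm >= t0 & tm < t1)
    pressure[] <- lm[1, "Pbase"]
    truth <- vector("list", n_cycles)
    nvc_times <- numeric(0)
    onset_prev <- NA_real_
    t_cursor <- lead_in_s
    vol_cum <- 0
    for (k in seq_len(n_cycles)) {
      Pb <- lm[k, "Pbase"]; Pt <- lm[k, "Pthresh"]
      Pm <- lm[k, "Pmax"]; Pe <- lm[k, "Pend"]
      plateau_s <- ivi[k] - ramp_s - rise_s - flow_s - relax_s
      t_pl0 <- t_cursor
      t_ramp0 <- t_pl0 + plateau_s
      t_rise0 <- t_ramp0 + ramp_s          # Pthresh time
      t_onset <- t_rise0 + rise_s          # flow onset = Pmax time
      t_end <- t_onset + flow_s            # flow end = Pend time
      t_next <- t_end + relax_s
      i <- seg(t_pl0, t_ramp0); pressure[i] <- Pb
      i <- seg(t_ramp0, t_rise0)
      pressure[i] <- Pb + (Pt - Pb) * (tm[i] - t_ramp0) / ramp_s
      i <- seg(t_rise0, t_onset)
      pressure[i] <- Pt + (Pm - Pt) * (1 - cos(pi * (tm[i] - t_rise0) / rise_s)) / 2
      i <- seg(t_onset, t_end)
      pressure[i] <- Pm + (Pe - Pm) * (tm[i] - t_onset) / flow_s
      i <- seg(t_end, t_next)
      pressure[i] <- Pe + (Pb - Pe) * (tm[i] - t_end) / relax_s
      if (k == n_cycles) pressure[tm >= t_next] <- Pb
      # volume: linear step of infusion_rate * ivi during flow
      vstep <- infusion_rate / 3600 * ivi[k]
      i <- seg(t_onset, t_end)
      volume[i] <- vol_cum + vstep * (tm[i] - t_onset) / flow_s
      volume[tm >= t_end] <- vol_cum + vstep
      vol_cum <- vol_cum + vstep
      # NVCs during plateau and the first 60% of the ramp
      if (nvc_rate > 0) {
        storage_win <- c(t_pl0 + 2, t_ramp0 + 0.6 * ramp_s)
        n_nvc <- rpois(1, nvc_rate / 60 * diff(storage_win))
        if (n_nvc > 0) {
          tt <- sort(runif(n_nvc, storage_win[1], storage_win[2]))
          for (tv in tt)
            pressure <- pressure + nvc_amplitude * exp(-((tm - tv)^2) / (2 * 0.8^2))
          nvc_times <- c(nvc_times, tt)
        }
      }
      truth[[k]] <- data.frame(cycle = k, Pbase = Pb, Pthresh = Pt, Pmax = Pm, Pend = Pe,
                               t_pthresh = t_rise0, flow_onset = t_onset,
                               flow_end = t_end, voided_volume = vstep,
                               ivi = ivi[k])
      t_cursor <- t_cursor + ivi[k]
    }
    if (noise_sd > 0) pressure <- pressure + rnorm(n, 0, noise_sd)
    if (volume_noise_sd > 0) volume <- volume + rnorm(n, 0, volume_noise_sd)
    trace <- cmg_trace(tm, pressure, volume, sample_rate, infusion_rate)
    list(trace = trace,
         truth = list(cycles = do.call(rbind, truth), nvc_times = nvc_times,
                      seed = seed,
                      params = list(n_cycles = n_cycles, landmarks = lm, ivi = ivi,
                                    infusion_rate = infusion_rate,
                                    sample_rate = sample_rate, nvc_rate = nvc_rate,
                                    nvc_amplitude = nvc_amplitude, noise_sd = noise_sd,
                                    ramp_s = ramp_s, rise_s = rise_s, flow_s = flow_s,
                                    relax_s = relax_s, lead_in_s = lead_in_s)))
  })
}

#' Write / read a cystometry trace as CSV + JSON header
#'
#' The CSV has columns `time_s`, `pressure_cmH2O`, `volume_mL`; sample rate
#' and infusion rate travel in `<path>.json`.
#' @param trace a [cmg_trace()].
#' @param path CSV path.
#' @export
write_cmg_trace <- function(trace, path) {
  write.csv(data.frame(time_s = trace$time, pressure_cmH2O = trace$pressure,
                       volume_mL = trace$volume), path, row.names = FALSE)
  jsonlite::write_json(list(sample_rate = trace$sample_rate,
                            infusion_rate = trace$infusion_rate),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cmg_trace
#' @export
read_cmg_trace <- function(path) {
  df <- read.csv(path)
  hd <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cmg_trace(df$time_s, df$pressure_cmH2O, df$volume_mL,
            hd$sample_rate, hd$infusion_rate)
}
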