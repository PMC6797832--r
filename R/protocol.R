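## Pacing protocol, beat-resolved simulation, and derived-feature extraction
## (qNet, APD, calcium-transient features).

#' Pacing protocol
#'
#' @param cycle_length Pacing cycle length (ms); the default 2000 ms
#'   emulates bradycardia.
#' @param n_beats Number of paced beats to quasi-steady state.  Full-scale
#'   runs use 1000; the desk-scale default is 100.
#' @param stim_amplitude Stimulus current (uA/uF, negative = depolarizing).
#' @param stim_duration Stimulus pulse width (ms).
#' @param rtol,atol Solver relative/absolute tolerances.
#' @param retained_beats Number of final beats kept for analysis.
#' @param dt Output time step for retained beats (ms).
#' @return List of class `pacing_protocol`.
#' @export
pacing_protocol <- function(cycle_length = 2000, n_beats = 100,
                            stim_amplitude = -80, stim_duration = 0.5,
                            rtol = 1e-6, atol = 1e-6, retained_beats = 5,
                            dt = 1) {
  stopifnot(retained_beats <= n_beats, rtol > 0, atol > 0,
            cycle_length > stim_duration)
  p <- list(cycle_length = cycle_length, n_beats = n_beats,
            stim_amplitude = stim_amplitude, stim_duration = stim_duration,
            rtol = rtol, atol = atol, retained_beats = retained_beats,
            dt = dt)
  class(p) <- "pacing_protocol"
  p
}

#' Copy a protocol with fields changed
#' @param protocol A [pacing_protocol()].
#' @param ... Fields to override.
#' @export
modify_protocol <- function(protocol, ...) {
  mods <- list(...)
  protocol[names(mods)] <- mods
  stopifnot(protocol$retained_beats <= protocol$n_beats)
  protocol
}

## apply a block vector to model parameters (conductance scaling + hERG
## binding parameters + optional additional IKr reduction)
.blocked_params <- function(model, blocks, extra_herg_block = 0) {
  p <- model$params
  b <- as.numeric(blocks)
  names(b) <- names(blocks)
  for (cur in names(model$conductances)) {
    g <- model$conductances[[cur]]
    p[[g]] <- scale_conductance(p[[g]], b[[paste0("b", cur)]])
  }
  p["sbIKr"] <- b[["sbIKr"]]
  p["Ku"] <- b[["Ku"]]
  p["Vhalf"] <- b[["Vhalf"]]
  p["extraKr"] <- extra_herg_block / 100
  p
}

.integrate_segment <- function(y, times, p, protocol, solver) {
  out <- deSolve::lsoda(y, times, func = solver$func, parms = p,
                        dllname = solver$dllname,
                        initfunc = solver$initfunc, nout = solver$nout,
                        outnames = solver$outnames,
                        rtol = protocol$rtol, atol = protocol$atol)
  if (any(!is.finite(out))) stop("solver produced non-finite output")
  out
}

#' Pace a cell model under a drug-action block vector
#'
#' Integrates the model beat by beat from the control resting steady state
#' (or a supplied state), applying the stimulus at the start of every cycle,
#' and returns the retained final beats with all named currents recorded.
#' Conductances are scaled by the percent blocks; the dynamic hERG binding
#' is parameterized by (`sbIKr`, `Ku`, `Vhalf`); `extra_herg_block` applies
#' a further multiplicative IKr conductance reduction (the EAD-protocol
#' perturbation) after dynamic binding.
#'
#' @param model Cell model (see [get_cell_model()]).
#' @param blocks A [block_vector()].
#' @param protocol A [pacing_protocol()].
#' @param extra_herg_block Additional percent IKr conductance reduction.
#' @param init_state Optional initial state (defaults to the model's
#'   packaged control resting state).
#' @return Object of class `beat_trace`: time grid `t` (ms), `V` (mV),
#'   `Cai` (nM), `currents` (matrix, uA/uF), `beat_starts` (stimulus onset
#'   times of retained beats), per-beat pre-stimulus diastolic values
#'   `dia_V`/`dia_Ca`, the cycle length `cl`, and the final state.
#' @export
run_pacing <- function(model, blocks = block_vector(),
                       protocol = pacing_protocol(), extra_herg_block = 0,
                       init_state = NULL) {
  p <- .blocked_params(model, blocks, extra_herg_block)
  solver <- model$solver
  y <- if (is.null(init_state)) model$init_state() else init_state
  cl <- protocol$cycle_length
  sd <- protocol$stim_duration
  keep_from <- protocol$n_beats - protocol$retained_beats + 1

  t_list <- list(); x_list <- list()
  beat_starts <- numeric(0); dia_V <- numeric(0); dia_Ca <- numeric(0)
  for (i in seq_len(protocol$n_beats)) {
    keep <- i >= keep_from
    t0 <- (i - 1) * cl
    if (keep) {
      beat_starts <- c(beat_starts, t0)
      dia_V <- c(dia_V, y[["V"]]); dia_Ca <- c(dia_Ca, y[["Cai"]])
    }
    ## stimulus segment, finely resolved so the upstroke is captured
    p["stim_on"] <- if (protocol$stim_amplitude != 0) 1 else 0
    p["stim_amp"] <- protocol$stim_amplitude
    times1 <- if (keep) seq(0, sd, by = min(0.05, sd)) else c(0, sd)
    o1 <- .integrate_segment(y, times1, p, protocol, solver)
    y <- stats::setNames(as.numeric(o1[nrow(o1), 1 + seq_along(y)]),
                         names(y))
    ## free-running remainder of the cycle
    p["stim_on"] <- 0
    times2 <- if (keep) {
      c(seq(sd, min(sd + 10, cl), by = 0.1),
        seq(ceiling(sd + 10), cl, by = protocol$dt))
    } else c(sd, cl)
    times2 <- unique(times2)
    o2 <- .integrate_segment(y, times2, p, protocol, solver)
    y <- stats::setNames(as.numeric(o2[nrow(o2), 1 + seq_along(y)]),
                         names(y))
    if (keep) {
      oo <- rbind(o1, o2[-1, , drop = FALSE])
      oo[, 1] <- oo[, 1] + t0
      t_list[[length(t_list) + 1]] <- oo
    }
  }
  out <- do.call(rbind, t_list)
  cur <- out[, 1 + length(model$state_names) + seq_along(model$current_names),
             drop = FALSE]
  colnames(cur) <- model$current_names
  trace <- list(t = out[, 1], V = out[, "V"], Cai = out[, "Cai"],
                currents = cur, beat_starts = beat_starts,
                dia_V = dia_V, dia_Ca = dia_Ca, cl = cl,
                stim_duration = sd, final_state = y, blocks = blocks)
  class(trace) <- "beat_trace"
  trace
}

## index range of one retained beat (beat counted within retained set;
## default = last)
.beat_idx <- function(trace, beat = length(trace$beat_starts)) {
  t0 <- trace$beat_starts[beat]
  which(trace$t >= t0 & trace$t <= t0 + trace$cl)
}

#' Action-potential duration at a repolarization fraction
#'
#' Duration from the maximum-dV/dt upstroke time to the linearly
#' interpolated downward crossing of `peak - fraction * amplitude`, where
#' the amplitude references the pre-stimulus diastolic voltage of the same
#' beat.
#'
#' @param t,V Time (ms) and voltage (mV) samples of one beat window
#'   containing a single upstroke.
#' @param fraction Repolarization fraction (0.9 for APD90, 0.5 for APD50).
#' @param dia Pre-stimulus diastolic voltage; defaults to `V[1]`.
#' @return Duration in ms, or `NA` (flagged unresolved) when the trace
#'   never crosses the threshold before the window ends.
#' @export
compute_apd <- function(t, V, fraction = 0.9, dia = V[1]) {
  dvdt <- diff(V) / diff(t)
  i_up <- which.max(dvdt)
  t_up <- t[i_up]
  i_pk <- which.max(V)
  peak <- V[i_pk]
  thr <- peak - fraction * (peak - dia)
  post <- seq(i_pk, length(V))
  below <- post[which(V[post] <= thr)]
  if (!length(below)) {
    res <- NA_real_
    attr(res, "unresolved") <- TRUE
    return(res)
  }
  j <- below[1]
  if (j == 1) return(0)
  tc <- t[j - 1] + (thr - V[j - 1]) * (t[j] - t[j - 1]) / (V[j] - V[j - 1])
  tc - t_up
}

#' Net charge carried by the repolarization-relevant currents (qNet)
#'
#' Trapezoidal integral of `Inet = ICaL + INaL + IKr + IKs + IK1 + Ito` over
#' one full beat (stimulus onset to next onset).  With currents in uA/uF and
#' time in ms the integral is in nC/uF.
#'
#' @param trace A `beat_trace`.
#' @param beat Retained-beat index (default: last).
#' @return qNet in nC/uF.
#' @export
compute_qnet <- function(trace, beat = length(trace$beat_starts)) {
  need <- c("ICaL", "INaL", "IKr", "IKs", "IK1", "Ito")
  missing <- setdiff(need, colnames(trace$currents))
  if (length(missing))
    stop("missing current series: ", paste(missing, collapse = ", "))
  idx <- .beat_idx(trace, beat)
  tt <- trace$t[idx]
  inet <- rowSums(trace$currents[idx, need, drop = FALSE])
  sum(diff(tt) * (inet[-length(inet)] + inet[-1]) / 2)
}

#' Calcium-transient features of one beat
#'
#' Baseline is the pre-stimulus calcium; durations run from the
#' maximum-upslope time of the transient to the linearly interpolated
#' 50%/90% return toward baseline.
#'
#' @param t,Cai Time (ms) and intracellular calcium (nM) of one beat window.
#' @param dia Pre-stimulus (baseline) calcium; defaults to `Cai[1]`.
#' @return List with `peakCa`, `diastolicCa`, `CaTD50`, `CaTD90`.
#' @export
compute_ca_metrics <- function(t, Cai, dia = Cai[1]) {
  peak <- max(Cai)
  if (peak - dia < .Machine$double.eps^0.5 * max(1, abs(peak))) {
    return(list(peakCa = peak, diastolicCa = dia, CaTD50 = 0, CaTD90 = 0))
  }
  dca <- diff(Cai) / diff(t)
  t_up <- t[which.max(dca)]
  i_pk <- which.max(Cai)
  dur <- function(fraction) {
    thr <- peak - fraction * (peak - dia)
    post <- seq(i_pk, length(Cai))
    below <- post[which(Cai[post] <= thr)]
    if (!length(below)) return(NA_real_)
    j <- below[1]
    if (j == 1) return(0)
    tc <- t[j - 1] +
      (thr - Cai[j - 1]) * (t[j] - t[j - 1]) / (Cai[j] - Cai[j - 1])
    tc - t_up
  }
  list(peakCa = peak, diastolicCa = dia, CaTD50 = dur(0.5),
       CaTD90 = dur(0.9))
}

#' All derived metrics of a paced trace
#'
#' Extracts the full feature set from the last retained beat: qNet, APD90,
#' APD50, peakVm, diastolicCa, peakCa, CaTD50, CaTD90.
#'
#' @param trace A `beat_trace`.
#' @return One-row data.frame.
#' @export
derive_all <- function(trace) {
  beat <- length(trace$beat_starts)
  idx <- .beat_idx(trace, beat)
  tt <- trace$t[idx]; vv <- trace$V[idx]; ca <- trace$Cai[idx]
  dia_v <- trace$dia_V[beat]; dia_ca <- trace$dia_Ca[beat]
  cam <- compute_ca_metrics(tt, ca, dia = dia_ca)
  data.frame(qNet = compute_qnet(trace, beat),
             APD90 = as.numeric(compute_apd(tt, vv, 0.9, dia = dia_v)),
             APD50 = as.numeric(compute_apd(tt, vv, 0.5, dia = dia_v)),
             peakVm = max(vv),
             diastolicCa = cam$diastolicCa, peakCa = cam$peakCa,
             CaTD50 = cam$CaTD50, CaTD90 = cam$CaTD90)
}

#' Peak-IKr reduction versus static hERG binding strength
#'
#' For each (`Ku`, `Vhalf`) corner, the percent reduction of the peak IKr
#' current of the last retained beat relative to control, as a function of
#' `sbIKr`.  Trapped-drug corners (`Vhalf` near -1 mV with fast binding)
#' give the largest reduction; free-unbinding corners (`Vhalf = -200` mV
#' with negligible `Ku`) the smallest.
#'
#' @param model Cell model.
#' @param sbikr_grid Values of `sbIKr` to scan.
#' @param corners List of `c(Ku, Vhalf)` pairs.
#' @param cycle_length Pacing cycle length (ms).
#' @param n_beats Beats per run.
#' @return data.frame with columns `Ku`, `Vhalf`, `sbIKr`, `reduction`
#'   (percent).
#' @export
peak_ikr_scan <- function(model, sbikr_grid = c(0, 0.5, 1, 2, 4),
                          corners = list(c(1e-5, -200), c(1, -1)),
                          cycle_length = 2000, n_beats = 30) {
  proto <- pacing_protocol(cycle_length = cycle_length, n_beats = n_beats,
                           retained_beats = 1)
  peak_ikr <- function(blocks) {
    tr <- run_pacing(model, blocks, proto)
    max(abs(tr$currents[, "IKr"]))
  }
  ctrl <- peak_ikr(block_vector())
  res <- list()
  for (corner in corners) {
    for (s in sbikr_grid) {
      pk <- if (s == 0) ctrl else
        peak_ikr(block_vector(sbIKr = s, Ku = corner[1], Vhalf = corner[2]))
      res[[length(res) + 1]] <- data.frame(
        Ku = corner[1], Vhalf = corner[2], sbIKr = s,
        reduction = 100 * (1 - pk / ctrl))
    }
  }
  do.call(rbind, res)
}

#' Synthetic action-potential trace with closed-form metrics
#'
#' Piecewise-analytic AP and calcium waveforms for testing the metric
#' extractors: a triangular or square AP of given amplitude and duration, an
#' optional secondary depolarization (EAD bump) on the plateau, an
#' instantaneous-rise exponential-decay calcium transient, and optional
#' constant current profiles.
#'
#' @param shape `"triangle"` (linear repolarization over `repol_ms`) or
#'   `"square"` (flat plateau of width `repol_ms`, instant repolarization).
#' @param cl Cycle length (ms).
#' @param v_rest,v_peak Resting and peak voltage (mV).
#' @param repol_ms Repolarization span (triangle) or plateau width (square).
#' @param ead_bump Optional list `(amp, at, width)`: adds a triangular bump
#'   of `amp` mV centred `at` ms after the upstroke.
#' @param ca Optional list `(base, amp, lambda)`: calcium transient
#'   `base + amp * exp(-lambda * (t - t_up))` after the upstroke; closed
#'   form gives `CaTD90 - CaTD50 = log(5)/lambda`.
#' @param currents Optional named numeric vector of constant currents
#'   (uA/uF); missing names are zero.
#' @param dt Sample step (ms).
#' @return A `beat_trace`.
#' @export
synth_ap_trace <- function(shape = c("triangle", "square"), cl = 1000,
                           v_rest = -85, v_peak = 35, repol_ms = 300,
                           ead_bump = NULL, ca = NULL, currents = NULL,
                           dt = 0.5) {
  shape <- match.arg(shape)
  t <- seq(0, cl, by = dt)
  t_up <- 1
  V <- rep(v_rest, length(t))
  rise <- t > 0 & t <= t_up
  V[rise] <- v_rest + (v_peak - v_rest) * t[rise] / t_up
  after <- t > t_up
  if (shape == "triangle") {
    V[after] <- pmax(v_rest,
                     v_peak - (v_peak - v_rest) * (t[after] - t_up) / repol_ms)
  } else {
    V[after] <- ifelse(t[after] <= t_up + repol_ms, v_peak, v_rest)
  }
  if (!is.null(ead_bump)) {
    tb <- t_up + ead_bump$at
    w <- ead_bump$width
    bump <- pmax(0, 1 - abs(t - tb) / w) * ead_bump$amp
    V <- V + ifelse(V > v_rest + 1, bump, 0)
  }
  Cai <- rep(if (is.null(ca)) 100 else ca$base, length(t))
  if (!is.null(ca)) {
    Cai[after] <- ca$base + ca$amp * exp(-ca$lambda * (t[after] - t_up))
  }
  cur_names <- c("INa", "INaL", "Ito", "IKs", "IKr", "IK1", "ICaL")
  cur <- matrix(0, length(t), length(cur_names),
                dimnames = list(NULL, cur_names))
  if (!is.null(currents)) {
    for (nm in names(currents)) cur[, nm] <- currents[[nm]]
  }
  trace <- list(t = t, V = V, Cai = Cai, currents = cur, beat_starts = 0,
                dia_V = v_rest, dia_Ca = Cai[1], cl = cl,
                stim_duration = 0.5, final_state = NULL,
                blocks = block_vector())
  class(trace) <- "beat_trace"
  trace
}
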