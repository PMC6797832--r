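## Early-afterdepolarization detection and the additional-hERG-block
## threshold protocol (Th_EAD,hERG).

#' Detect early afterdepolarizations in a paced trace
#'
#' A retained beat carries an EAD when its voltage derivative exceeds `eps`
#' for at least `min_dur` ms inside the plateau window.  The plateau window
#' runs from `t_guard` ms after the upstroke peak (excluding the stimulus
#' artifact and the phase-1 notch-dome rebound) to the first time the
#' voltage falls below `v_floor`; if the
#' beat never repolarizes below the floor the window is capped at the beat
#' end and detection still runs.
#'
#' @param trace A `beat_trace` holding the retained final beats.
#' @param eps Positive-dV/dt threshold (mV/ms).
#' @param min_dur Minimum sustained duration (ms).
#' @param t_guard Guard interval after the peak (ms).
#' @param v_floor Plateau floor voltage (mV).
#' @return `TRUE` if any retained beat shows an EAD.
#' @export
detect_ead <- function(trace, eps = 0.01, min_dur = 2, t_guard = 100,
                       v_floor = -60) {
  for (beat in seq_along(trace$beat_starts)) {
    idx <- .beat_idx(trace, beat)
    tt <- trace$t[idx]; vv <- trace$V[idx]
    ## anchor on the primary upstroke peak (max V within 60 ms of the
    ## maximum-dV/dt time) so that a secondary depolarization larger than
    ## the plateau cannot displace the window
    i_up <- which.max(diff(vv) / diff(tt))
    i_end <- max(which(tt <= tt[i_up] + 60))
    i_pk <- i_up - 1 + which.max(vv[i_up:i_end])
    t_start <- tt[i_pk] + t_guard
    post <- seq(i_pk, length(vv))
    under <- post[which(vv[post] < v_floor)]
    t_end <- if (length(under)) tt[under[1]] else tt[length(tt)]
    if (t_end <= t_start) next
    dvdt <- diff(vv) / diff(tt)
    tm <- tt[-length(tt)]
    in_win <- tm >= t_start & tm < t_end
    pos <- in_win & dvdt > eps
    if (!any(pos)) next
    ## sustained run length in time
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      if (tm[ends[k]] - tm[starts[k]] + mean(diff(tt)) >= min_dur)
        return(TRUE)
    }
  }
  FALSE
}

#' EAD threshold: minimal additional hERG block that elicits an EAD
#'
#' Applies increasing additional IKr conductance reduction (multiplicative,
#' on top of all drug-induced effects and after dynamic binding) on the grid
#' `{0, grid_step, ..., 100}` percent and returns the smallest level at
#' which [detect_ead()] fires.  `method = "sweep"` evaluates every level in
#' ascending order; `method = "search"` (default) uses a coarse ascending
#' scan followed by a fine ascending sweep inside the bracketing interval,
#' which returns the same level whenever the EAD response is monotone in
#' the additional block near onset (the case for the bundled model; the
#' equivalence is exercised in the test suite).
#'
#' Each level is simulated from the drug steady state reached after
#' `protocol$n_beats` paced beats, continuing for `level_beats` further
#' beats under the perturbation (set `warm_start = FALSE` to restart every
#' level from the control resting state for the full beat count).
#'
#' @param model Cell model.
#' @param blocks Drug-action [block_vector()].
#' @param protocol A [pacing_protocol()].
#' @param grid_step Grid resolution in percent; must divide 100.
#' @param method `"search"` or `"sweep"`.
#' @param warm_start Reuse the drug steady state across levels.
#' @param level_beats Beats simulated per level when warm-starting.
#' @param coarse_step Stride of the coarse scan (percent), `"search"` only.
#' @param multiple Concentration multiple annotation carried in the result.
#' @param ... Passed to [detect_ead()].
#' @return List of class `ead_result` with `threshold` (percent, or `NA`
#'   for no EAD up to 100%), `flags` (named per-level detections),
#'   `failed_levels`, and `multiple`.
#' @export
ead_threshold <- function(model, blocks, protocol = pacing_protocol(),
                          grid_step = 0.5, method = c("search", "sweep"),
                          warm_start = TRUE, level_beats = 10,
                          coarse_step = NULL, multiple = NA, ...) {
  method <- match.arg(method)
  if (abs(100 / grid_step - round(100 / grid_step)) > 1e-9)
    stop("grid_step must divide 100")
  flags <- c(); failed <- numeric(0)

  base <- run_pacing(model, blocks, protocol)
  level_proto <- if (warm_start) {
    modify_protocol(protocol,
                    n_beats = max(level_beats, protocol$retained_beats))
  } else protocol
  init <- if (warm_start) base$final_state else NULL

  eval_level <- function(level) {
    if (level == 0) return(detect_ead(base, ...))
    ok <- tryCatch({
      tr <- run_pacing(model, blocks, level_proto,
                       extra_herg_block = level, init_state = init)
      detect_ead(tr, ...)
    }, error = function(e) {
      failed <<- c(failed, level)
      warning("solver failure at additional block ", level,
              "%; treated as non-EAD: ", conditionMessage(e))
      FALSE
    })
    flags[as.character(level)] <<- ok
    ok
  }

  result <- function(th) {
    structure(list(threshold = th, flags = flags, failed_levels = failed,
                   multiple = multiple, grid_step = grid_step),
              class = "ead_result")
  }

  if (eval_level(0)) return(result(0))
  grid <- seq(grid_step, 100, by = grid_step)
  if (method == "sweep") {
    for (level in grid) if (eval_level(level)) return(result(level))
    return(result(NA_real_))
  }
  ## coarse ascending scan, then fine ascending sweep inside the bracket
  ## between the last coarse non-EAD level and the first coarse EAD level
  if (is.null(coarse_step))
    coarse_step <- grid_step * max(1, ceiling(4 / grid_step))
  stopifnot(abs(coarse_step / grid_step - round(coarse_step / grid_step))
            < 1e-9)
  coarse <- unique(c(seq(coarse_step, 100, by = coarse_step), 100))
  hit <- NA_real_
  last_false <- 0
  for (level in coarse) {
    if (eval_level(level)) { hit <- level; break }
    last_false <- level
  }
  if (is.na(hit)) return(result(NA_real_))
  fine <- grid[grid > last_false & grid < hit]
  for (level in fine) if (eval_level(level)) return(result(level))
  result(hit)
}

#' Average a metric over concentration multiples
#'
#' Arithmetic mean of the per-multiple metric values (the reference protocol
#' uses multiples 1-4 of the effective free therapeutic plasma
#' concentration).  `NA` entries represent the no-EAD sentinel; the default
#' policy replaces them by 100 (the top of the additional-block scale) and
#' flags the mean.
#'
#' @param values Numeric vector, `NA` = no EAD up to 100%.
#' @param noead_policy `"treat_as_100"` or `"omit"`.
#' @return Mean value with attribute `flagged = TRUE` when the policy was
#'   applied; `NA` if every multiple was no-EAD.
#' @export
mean_over_concentrations <- function(values,
                                     noead_policy = c("treat_as_100",
                                                      "omit")) {
  noead_policy <- match.arg(noead_policy)
  if (all(is.na(values))) {
    res <- NA_real_
    attr(res, "flagged") <- TRUE
    return(res)
  }
  flagged <- any(is.na(values))
  if (flagged && noead_policy == "treat_as_100") values[is.na(values)] <- 100
  res <- mean(values, na.rm = TRUE)
  if (flagged) attr(res, "flagged") <- TRUE
  res
}
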