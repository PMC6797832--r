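## MinCell: the bundled minimal paced-myocyte model and the cell-model
## registry.  The model equations themselves live in src/mincell.c; this file
## holds the R-side contract (parameter/state layout, resting state, the
## behavioural validation gate) and the dynamic hERG-binding kinetics.

.mincell_state_names <- c("V", "m", "h", "hL", "r", "xs", "xr", "d", "f",
                          "Cai", "b")
.mincell_current_names <- c("INa", "INaL", "Ito", "IKs", "IKr", "IK1", "ICaL")
.mincell_par_names <- c("gNa", "gNaL", "gto", "gKs", "gKr", "gK1", "gCaL",
                        "ENa", "EK", "ECa",
                        "sbIKr", "Ku", "Vhalf", "kT", "extraKr",
                        "kCaL", "tauCa", "Ca0", "stim_amp", "stim_on",
                        "gpump", "gbg")

#' Default MinCell parameters
#'
#' Maximum conductances (mS/uF), reversal potentials (mV), calcium-pool
#' constants and hERG-binding constants of the bundled minimal ventricular
#' model.  The conductances are the frozen control values; drug block scales
#' them via [scale_conductance()].
#'
#' @return Named numeric vector of model parameters.
#' @export
mincell_params <- function() {
  c(gNa = 11, gNaL = 0.08, gto = 0.08, gKs = 0.05, gKr = 0.075, gK1 = 0.5,
    gCaL = 0.12,
    ENa = 70, EK = -88, ECa = 60,
    sbIKr = 0, Ku = 0, Vhalf = -100, kT = 6.8, extraKr = 0,
    kCaL = 6, tauCa = 70, Ca0 = 100,
    stim_amp = -80, stim_on = 0,
    gpump = 0.15, gbg = 2e-4)
}

## registry for pluggable cell models
.model_registry <- new.env(parent = emptyenv())

#' Register a cell model
#'
#' A cell model is a list with elements: `name`; `state_names`; `params`
#' (named numeric defaults, conductances first); `conductances` (names of the
#' scalable conductance parameters, one per blockable current); `init_state`
#' (function returning the packaged resting steady state, see
#' [mincell_rest_state()]); `rhs` (function `(t, state, params)` returning
#' `list(deriv, currents)`); and `solver` (list with `func`, `initfunc`,
#' `dllname`, `nout`, `outnames` for compiled integration, or `NULL` to use
#' the R-level `rhs`).
#'
#' @param model Cell-model list as described above.
#' @export
register_cell_model <- function(model) {
  stopifnot(is.list(model), is.character(model$name))
  assign(model$name, model, envir = .model_registry)
  invisible(model)
}

#' Look up a registered cell model by name
#' @param name Model name, e.g. `"mincell"`.
#' @return The model list.
#' @export
get_cell_model <- function(name) {
  if (!exists(name, envir = .model_registry))
    stop("unknown cell model: ", name)
  get(name, envir = .model_registry)
}

#' MinCell right-hand side
#'
#' Evaluates the time derivative of the MinCell state together with the seven
#' named membrane currents (uA/uF).
#'
#' @param t Time (ms); the model is autonomous apart from the stimulus flag.
#' @param state Named or unnamed numeric state vector (V, gates, Cai, b).
#' @param params Named parameter vector as from [mincell_params()].
#' @param stim Applied stimulus (uA/uF); non-zero values override the
#'   `stim_amp`/`stim_on` entries of `params`.
#' @return List with `deriv` (named derivative) and `currents` (named, uA/uF).
#' @export
mincell_rhs <- function(t, state, params = mincell_params(), stim = 0) {
  state <- as.numeric(state)
  if (any(!is.finite(state))) {
    bad <- .mincell_state_names[which(!is.finite(state))]
    stop("non-finite state component(s): ", paste(bad, collapse = ", "))
  }
  p <- mincell_params()
  p[names(params)] <- params
  if (stim != 0) {
    p["stim_amp"] <- stim
    p["stim_on"] <- 1
  }
  if (any(p[1:7] < 0)) stop("conductances must be non-negative")
  ans <- .Call(C_mincell_rhs, as.numeric(t), state, as.numeric(p))
  list(deriv = stats::setNames(ans[[1]], .mincell_state_names),
       currents = stats::setNames(ans[[2]], .mincell_current_names))
}

#' Dynamic hERG drug-binding kinetics
#'
#' Single-ODE bound-fraction model of drug interaction with the hERG channel:
#' \deqn{db/dt = Ku\, sbIKr\, o\,(1-b) - Ku\, T(V)\, b,}
#' with the release gate \eqn{T(V) = 1/(1+\exp(-(V - Vhalf)/k_T))}.  At fixed
#' voltage with the open proxy and \eqn{T} both 1 the equilibrium bound
#' fraction is \eqn{sbIKr/(1+sbIKr)}; `Vhalf` near -1 mV traps drug at
#' diastolic potentials while `Vhalf = -200` mV permits unbinding at all
#' voltages.  IKr is scaled by \eqn{(1-b)}.
#'
#' @param b Bound fraction in `[0, 1]`.
#' @param V Membrane voltage (mV).
#' @param sbIKr Static binding strength (dimensionless, >= 0).
#' @param Ku Unbinding rate (1/ms).
#' @param Vhalf Trapping half-voltage (mV).
#' @param open_proxy Open-channel fraction gating the binding drive.
#' @param kT Trapping sigmoid slope (mV), default 6.8.
#' @return db/dt (1/ms).
#' @export
herg_binding_rhs <- function(b, V, sbIKr, Ku, Vhalf, open_proxy = 1,
                             kT = 6.8) {
  T_rel <- 1 / (1 + exp(-(V - Vhalf) / kT))
  Ku * sbIKr * open_proxy * (1 - b) - Ku * T_rel * b
}

## resting steady state, computed once per session by 200 stimulus-free
## seconds of pre-integration and cached (the packaged state is code, not a
## stored binary)
.mincell_cache <- new.env(parent = emptyenv())

#' MinCell resting steady state
#'
#' The packaged control resting state, obtained by 200 s of stimulus-free
#' integration from a nominal diastolic guess and cached for the session.
#'
#' @return Named numeric state vector.
#' @export
mincell_rest_state <- function() {
  if (!is.null(.mincell_cache$rest)) return(.mincell_cache$rest)
  y0 <- stats::setNames(c(-88, 0, 1, 1, 1, 0, 0, 0, 1, 100, 0),
                        .mincell_state_names)
  p <- mincell_params()
  out <- deSolve::lsoda(y0, c(0, 200000), func = "mincell_derivs",
                        parms = p, dllname = "proarisk",
                        initfunc = "mincell_init", nout = 7,
                        outnames = .mincell_current_names,
                        rtol = 1e-8, atol = 1e-8)
  rest <- stats::setNames(as.numeric(out[nrow(out), 2:12]),
                          .mincell_state_names)
  .mincell_cache$rest <- rest
  rest
}

.mincell_model <- function() {
  list(name = "mincell",
       state_names = .mincell_state_names,
       current_names = .mincell_current_names,
       params = mincell_params(),
       conductances = c(INa = "gNa", INaL = "gNaL", Ito = "gto", IKs = "gKs",
                        ICaL = "gCaL", IK1 = "gK1"),
       init_state = mincell_rest_state,
       rhs = mincell_rhs,
       solver = list(func = "mincell_derivs", initfunc = "mincell_init",
                     dllname = "proarisk", nout = 7,
                     outnames = .mincell_current_names))
}

.onLoad <- function(libname, pkgname) {
  register_cell_model(.mincell_model())
}

#' Behavioural validation of a cell model
#'
#' Runs the bundled behavioural contract: resting stability and voltage
#' range, action-potential amplitude, the control APD90 band, monotone APD90
#' prolongation under static IKr block, monotone peak-calcium suppression
#' under ICaL block, monotone qNet increase under INaL block, and the
#' existence of an EAD-producing additional IKr-block level below 100%.
#'
#' @param model Cell model (list, see [register_cell_model()]).
#' @param protocol Pacing protocol from [pacing_protocol()]; the default uses
#'   a reduced beat count adequate for quasi-steady behaviour checks.
#' @param apd90_band Acceptable control APD90 range (ms) at cycle length
#'   2000 ms.
#' @return List with `pass` (logical), `violations` (character), and the
#'   measured quantities.
#' @export
validate_model <- function(model = get_cell_model("mincell"),
                           protocol = pacing_protocol(n_beats = 30),
                           apd90_band = c(200, 330)) {
  violations <- character()
  note <- function(msg) violations <<- c(violations, msg)

  rest <- model$init_state()
  v_rest <- rest[["V"]]
  if (v_rest < -92 || v_rest > -78)
    note(sprintf("resting V %.1f mV outside [-92, -78]", v_rest))

  ## resting drift over one cycle length without stimulus
  drift <- run_pacing(model, block_vector(), protocol = modify_protocol(
    protocol, n_beats = 1, retained_beats = 1, stim_amplitude = 0))
  dv <- max(abs(drift$V - v_rest))
  if (dv > 1) note(sprintf("resting drift %.2f mV over one cycle", dv))

  ctrl <- run_pacing(model, block_vector(), protocol)
  mx <- derive_all(ctrl)
  amp <- mx$peakVm - min(ctrl$V)
  if (amp <= 90) note(sprintf("AP amplitude %.1f mV <= 90", amp))
  if (mx$APD90 < apd90_band[1] || mx$APD90 > apd90_band[2])
    note(sprintf("control APD90 %.1f ms outside [%g, %g]",
                 mx$APD90, apd90_band[1], apd90_band[2]))

  apd_grid <- vapply(c(0, 20, 40, 60), function(ex) {
    tr <- run_pacing(model, block_vector(), protocol, extra_herg_block = ex)
    derive_all(tr)$APD90
  }, numeric(1))
  if (any(diff(apd_grid) < 0))
    note("APD90 not non-decreasing across static IKr block grid")

  ca_grid <- vapply(c(0, 25, 50, 75), function(bl) {
    tr <- run_pacing(model, block_vector(bICaL = bl), protocol)
    derive_all(tr)$peakCa
  }, numeric(1))
  if (any(diff(ca_grid) > 0))
    note("peakCa not non-increasing across bICaL grid")

  qnet_grid <- vapply(c(0, 40, 80), function(bl) {
    tr <- run_pacing(model, block_vector(bINaL = bl), protocol)
    derive_all(tr)$qNet
  }, numeric(1))
  if (any(diff(qnet_grid) <= 0))
    note("qNet not increasing across bINaL grid")

  ## EAD capability: a drug-like strong-block combination must show an EAD
  ## below 100% additional IKr reduction
  ead <- ead_threshold(model, block_vector(sbIKr = 2, Ku = 1e-2,
                                           Vhalf = -60),
                       protocol, grid_step = 5)
  if (is.na(ead$threshold))
    note("no EAD-producing additional IKr-block level below 100%")

  list(pass = length(violations) == 0, violations = violations,
       resting_V = v_rest, resting_drift = dv, amplitude = amp,
       APD90_control = mx$APD90, APD90_ikr_grid = apd_grid,
       peakCa_bICaL_grid = ca_grid, qNet_bINaL_grid = qnet_grid,
       ead_threshold = ead$threshold)
}
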