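# Right-hand side of the RGC model: membrane equation, intrinsic and synaptic
# currents, synaptic gating, Mg2+ block, calcium dynamics. These pure-R
# functions define the model; the compiled integrator mirrors them exactly
# (asserted in the test suite).

.state_names <- c("V", "m", "h", "n", "a", "b", "sCaL", "sAMPA", "sNMDA", "Ca")

#' Resting initial state
#'
#' Membrane potential at `Vrest`, gating variables at their voltage-dependent
#' steady states at `Vrest`, synaptic gates closed, calcium at `Ca_rest`.
#' With default parameters and kinetics this is (to numerical precision) a
#' fixed point of the model, so an unstimulated simulation stays flat.
#'
#' @param params model parameters, see [rgc_params()].
#' @param kinetics gating kinetics, see [default_kinetics()].
#' @return Named state vector `(V, m, h, n, a, b, sCaL, sAMPA, sNMDA, Ca)`.
#' @export
resting_state <- function(params = rgc_params(), kinetics = default_kinetics()) {
  params <- as_rgc_params(params)
  g <- steady_gates(params$Vrest, kinetics)
  c(V = params$Vrest, g[c("m", "h", "n", "a", "b", "sCaL")],
    sAMPA = 0, sNMDA = 0, Ca = params$Ca_rest)
}

#' Voltage-dependent Mg2+ block of the NMDA receptor
#'
#' Fraction of NMDA conductance left unblocked by extracellular Mg2+, in the
#' Jahr-Stevens form `B(V, Mg) = 1 / (1 + eta * Mg * exp(-gamma * V))`.
#' `B` is 1 when `Mg = 0`, strictly decreasing in `Mg` and strictly
#' increasing in `V` (depolarisation relieves the block).
#'
#' @param V membrane potential (mV). Vectorised.
#' @param Mg extracellular Mg2+ concentration (mM), must be `>= 0`. Vectorised.
#' @param params model parameters (uses `eta`, `gamma`).
#' @return Fraction unblocked in `(0, 1]`.
#' @examples
#' mg_block(-65, c(0.2, 1, 2))   # ~24%, 6%, 3% unblocked at rest
#' mg_block(0, 1)                # 1/1.28
#' @export
mg_block <- function(V, Mg, params = rgc_params()) {
  params <- as_rgc_params(params)
  if (any(!is.finite(Mg)) || any(Mg < 0))
    stop("'Mg' must be finite and >= 0", call. = FALSE)
  1 / (1 + params$eta * Mg * exp(-params$gamma * V))
}

#' Intrinsic membrane currents
#'
#' Evaluates the six intrinsic currents at a given state:
#' `INa = gNa m^3 h (V - ENa)`, `IKdr = gKdr n^4 (V - EK)`,
#' `IKA = gKA a^3 b (V - EK)`, `ICaL = gCaL sCaL^2 (V - ECa)`,
#' `IKCa = gKCa * Ca^2/(Ca^2 + Kd^2) * (V - EK)` and `IL = gL (V - EL)`.
#' Positive values are outward.
#'
#' @param state named state vector (see [resting_state()]).
#' @param params model parameters.
#' @return Named list of currents (uA/cm^2): `INa`, `IKdr`, `IKA`, `ICaL`,
#'   `IKCa`, `IL`.
#' @export
intrinsic_currents <- function(state, params = rgc_params()) {
  params <- as_rgc_params(params)
  s <- as.list(state)
  kca_act <- s$Ca^2 / (s$Ca^2 + params$Kd_KCa^2)
  list(
    INa  = params$gNa  * s$m^3 * s$h * (s$V - params$ENa),
    IKdr = params$gKdr * s$n^4        * (s$V - params$EK),
    IKA  = params$gKA  * s$a^3 * s$b  * (s$V - params$EK),
    ICaL = params$gCaL * s$sCaL^2     * (s$V - params$ECa),
    IKCa = params$gKCa * kca_act      * (s$V - params$EK),
    IL   = params$gL                  * (s$V - params$EL)
  )
}

#' Synaptic currents
#'
#' `IAMPA = gAMPA * sAMPA * (V - Eexc)` and
#' `INMDA = gNMDA * sNMDA * B(V, Mg) * (V - Eexc)` with `B` the Jahr-Stevens
#' Mg2+ block factor ([mg_block()]). For `V < Eexc` with open gates both are
#' inward (negative).
#'
#' @param state named state vector.
#' @param Mg extracellular Mg2+ (mM), `>= 0`.
#' @param params model parameters.
#' @return Named list `IAMPA`, `INMDA` (uA/cm^2) and the block factor `B`.
#' @export
synaptic_currents <- function(state, Mg, params = rgc_params()) {
  params <- as_rgc_params(params)
  s <- as.list(state)
  B <- mg_block(s$V, Mg, params)
  list(
    IAMPA = params$gAMPA * s$sAMPA * (s$V - params$Eexc),
    INMDA = params$gNMDA * s$sNMDA * B * (s$V - params$Eexc),
    B = B
  )
}

#' Synaptic gate kinetics
#'
#' First-order receptor gating with glutamate-dependent activation:
#' `ds/dt = Glu/(Glu + EC50) * (1 - s)/tau_rise - s/tau_decay`. At `Glu = 0`
#' the gate decays to 0; at `Glu = EC50` the activation term is half-maximal.
#'
#' @param s gate value in `[0, 1]`. Vectorised.
#' @param Glu glutamate concentration (mM), `>= 0`.
#' @param EC50 half-activation glutamate concentration (mM).
#' @param tau_rise,tau_decay rise and decay time constants (ms).
#' @return `ds/dt` in 1/ms.
#' @examples
#' syn_gate_deriv(0, 0, 0.5, 0.3, 3)       # resting fixed point
#' syn_gate_deriv(0, 1, 0.002, 5, 80) * 5  # NMDA activation ~ saturated
#' @export
syn_gate_deriv <- function(s, Glu, EC50, tau_rise, tau_decay) {
  act <- Glu / (Glu + EC50)
  act * (1 - s) / tau_rise - s / tau_decay
}

#' Calcium dynamics
#'
#' Single-pool intracellular calcium:
#' `dCa/dt = -kCa_NMDA * fCa * INMDA - kCa_CaL * ICaL - (Ca - Ca_rest)/tau_Ca`.
#' Inward (negative) NMDA and L-type currents produce positive influx terms;
#' the scaling factors absorb the conversion from current density (uA/cm^2)
#' to concentration rate (uM/ms). Without influx, Ca relaxes to `Ca_rest`
#' with time constant `tau_Ca`.
#'
#' @param Ca intracellular calcium (uM).
#' @param INMDA,ICaL calcium-carrying currents (uA/cm^2, negative = inward).
#' @param params model parameters.
#' @return `dCa/dt` in uM/ms.
#' @export
ca_deriv <- function(Ca, INMDA, ICaL, params = rgc_params()) {
  params <- as_rgc_params(params)
  -params$kCa_NMDA * params$fCa * INMDA - params$kCa_CaL * ICaL -
    (Ca - params$Ca_rest) / params$tau_Ca
}

#' Full right-hand side of the RGC model
#'
#' Assembles the time derivative of the complete state: the membrane equation
#' `Cm dV/dt = -(INa + IKdr + IKA + ICaL + IKCa + IL + IAMPA + INMDA)`,
#' first-order gating relaxation for the six intrinsic gates, glutamate-driven
#' synaptic gate kinetics, and single-pool calcium dynamics.
#'
#' This reference implementation is pure R and is mirrored by the compiled
#' integrator; it is the natural entry point for inspecting the model or
#' integrating with custom kinetics.
#'
#' @param t time (ms).
#' @param state named state vector.
#' @param protocol stimulus description, see [stim_protocol()]; supplies
#'   glutamate and Mg2+ at time `t`.
#' @param params model parameters.
#' @param kinetics gating kinetics set.
#' @return Named vector of time derivatives (same layout as `state`).
#' @export
rgc_rhs <- function(t, state, protocol, params = rgc_params(),
                    kinetics = default_kinetics()) {
  if (any(!is.finite(state)))
    stop("non-finite state at t = ", t, " ms", call. = FALSE)
  params <- as_rgc_params(params)
  s <- as.list(state)
  glu <- glutamate_at(protocol, t)
  mg <- mg_at(protocol, t)

  ii <- intrinsic_currents(state, params)
  si <- synaptic_currents(state, mg, params)
  itot <- ii$INa + ii$IKdr + ii$IKA + ii$ICaL + ii$IKCa + ii$IL +
    si$IAMPA + si$INMDA

  gate_d <- function(name, x) (kinetics[[name]]$inf(s$V) - x) /
    kinetics[[name]]$tau(s$V)

  c(V = -itot / params$Cm,
    m = gate_d("m", s$m), h = gate_d("h", s$h), n = gate_d("n", s$n),
    a = gate_d("a", s$a), b = gate_d("b", s$b),
    sCaL = gate_d("sCaL", s$sCaL),
    sAMPA = syn_gate_deriv(s$sAMPA, glu, params$EC50_AMPA,
                           params$tau_AMPA_rise, params$tau_AMPA_decay),
    sNMDA = syn_gate_deriv(s$sNMDA, glu, params$EC50_NMDA,
                           params$tau_NMDA_rise, params$tau_NMDA_decay),
    Ca = ca_deriv(s$Ca, si$INMDA, ii$ICaL, params))
}
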