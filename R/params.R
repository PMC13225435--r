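# Biophysical parameter set: membrane, intrinsic conductances, synaptic
# receptors, Mg2+ block, calcium handling. Units follow the conventions of
# single-compartment conductance-based models: conductances mS/cm^2,
# potentials mV, time ms, concentrations mM (glutamate, Mg2+) or uM (Ca2+).

.rgc_defaults <- list(
  # membrane
  Cm    = 1.0,    # uF/cm^2
  Vrest = -65,    # mV
  # maximal conductances (mS/cm^2)
  gNa  = 120, gKdr = 36, gKA = 8, gCaL = 0.3, gKCa = 0.3, gL = 0.35,
  # reversal potentials (mV)
  ENa = 50, EK = -77, ECa = 120, EL = -54.4, Eexc = 0,
  # synaptic conductances (mS/cm^2)
  gAMPA = 0.25, gNMDA = 1.2,
  # half-activation glutamate concentrations, both stored in mM
  # (the NMDA value is commonly quoted as 2 uM)
  EC50_AMPA = 0.5, EC50_NMDA = 0.002,
  # synaptic gate time constants (ms)
  tau_AMPA_rise = 0.3, tau_AMPA_decay = 3,
  tau_NMDA_rise = 5,   tau_NMDA_decay = 80,
  # Jahr-Stevens Mg2+ block constants
  eta = 0.28,     # 1/mM
  gamma = 0.062,  # 1/mV
  # calcium dynamics
  fCa = 0.15,        # fractional Ca2+ current through NMDA receptors
  kCa_NMDA = 0.012,  # current-density -> uM/ms scaling (absorbs geometry)
  kCa_CaL  = 0.003,
  Ca_rest = 0.05,    # uM
  tau_Ca  = 200,     # ms
  Kd_KCa  = 0.5      # uM, half-activation of the KCa conductance
)

#' Model parameters for the RGC excitotoxicity model
#'
#' Builds the full parameter record of the single-compartment retinal ganglion
#' cell model: membrane capacitance, maximal conductances and reversal
#' potentials of the intrinsic currents (Na, delayed-rectifier K, A-type K,
#' L-type Ca, Ca-activated K, leak), AMPA/NMDA synaptic conductances and
#' kinetics, Jahr-Stevens Mg2+-block constants, and single-pool calcium
#' dynamics. Defaults are the model's reference values; any subset can be
#' overridden by name.
#'
#' Units: `Cm` uF/cm^2; conductances `g*` mS/cm^2; potentials `E*`, `Vrest` mV;
#' `EC50_*` mM (the NMDA value 0.002 mM = 2 uM); time constants ms; `eta` 1/mM;
#' `gamma` 1/mV; `Ca_rest`, `Kd_KCa` uM; `fCa`, `kCa_*` dimensionless.
#'
#' @param ... named overrides of default values, e.g. `gNMDA = 0`.
#' @return A named list of class `"rgc_params"`.
#' @examples
#' p <- rgc_params()
#' p$gNa
#' rgc_params(gNMDA = 0)$gNMDA
#' @export
rgc_params <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  p <- .rgc_defaults
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(over)] <- over
  }
  validate_params(p)
  structure(p, class = "rgc_params")
}

# stop() with the offending field name on any violated constraint
validate_params <- function(p) {
  num1 <- function(field) {
    x <- p[[field]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", field, "' must be a single finite number",
           call. = FALSE)
    x
  }
  for (f in names(.rgc_defaults)) num1(f)
  nonneg <- c("gNa", "gKdr", "gKA", "gCaL", "gKCa", "gL", "gAMPA", "gNMDA",
              "eta", "gamma", "kCa_NMDA", "kCa_CaL")
  for (f in nonneg)
    if (p[[f]] < 0) stop("parameter '", f, "' must be >= 0", call. = FALSE)
  pos <- c("Cm", "EC50_AMPA", "EC50_NMDA", "tau_AMPA_rise", "tau_AMPA_decay",
           "tau_NMDA_rise", "tau_NMDA_decay", "Ca_rest", "tau_Ca", "Kd_KCa")
  for (f in pos)
    if (p[[f]] <= 0) stop("parameter '", f, "' must be > 0", call. = FALSE)
  if (p$fCa < 0 || p$fCa > 1)
    stop("parameter 'fCa' must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' @export
print.rgc_params <- function(x, ...) {
  cat("RGC model parameters\n")
  cat("  membrane : Cm =", x$Cm, "uF/cm^2, Vrest =", x$Vrest, "mV\n")
  cat("  intrinsic: gNa =", x$gNa, " gKdr =", x$gKdr, " gKA =", x$gKA,
      " gCaL =", x$gCaL, " gKCa =", x$gKCa, " gL =", x$gL, "(mS/cm^2)\n")
  cat("  synaptic : gAMPA =", x$gAMPA, " gNMDA =", x$gNMDA,
      " (tau decay", x$tau_AMPA_decay, "/", x$tau_NMDA_decay, "ms)\n")
  cat("  Mg block : eta =", x$eta, "/mM, gamma =", x$gamma, "/mV\n")
  cat("  calcium  : fCa =", x$fCa, " kCa_NMDA =", x$kCa_NMDA,
      " kCa_CaL =", x$kCa_CaL, " Ca_rest =", x$Ca_rest,
      "uM, tau_Ca =", x$tau_Ca, "ms\n")
  invisible(x)
}

# coerce arbitrary list/params input to validated rgc_params
as_rgc_params <- function(p) {
  if (inherits(p, "rgc_params")) return(p)
  if (is.list(p)) return(rgc_params(p))
  stop("'params' must be an rgc_params object or a named list", call. = FALSE)
}
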