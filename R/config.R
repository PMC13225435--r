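# Configuration files (YAML) and run manifests. The model runs with zero
# configuration: every key defaults to the built-in parameter tables.

.config_sections <- c("parameters", "protocol", "criteria", "integration")

.config_defaults <- function() {
  list(parameters = .rgc_defaults,
       protocol = list(freq = 80, pulse_width = 2, pulse_amp = 1,
                       stim_start = 0, stim_end = 3000, t_end = 3000,
                       mg = 0.2),
       criteria = list(ca_toxicity_threshold = 1.0, max_spike_loss_pct = 20,
                       baseline_mg = 0.2),
       integration = list(dt = 0.02, method = "euler", record_stride = 1))
}

#' Load and validate a model configuration
#'
#' Reads a YAML configuration with any subset of the sections `parameters`,
#' `protocol`, `criteria` and `integration`. Missing keys default to the
#' built-in values (so an empty file yields the full default model); unknown
#' sections or keys are rejected with an error naming them. Parameter values
#' are validated (e.g. negative conductances are refused).
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return A list with elements `parameters` (an [rgc_params()] object),
#'   `protocol`, `criteria` (a [therapeutic_criteria()] object) and
#'   `integration`, of class `"rgc_config"`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    out <- yaml::read_yaml(path)
    if (is.null(out)) list() else out
  }
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  bad <- setdiff(names(raw), .config_sections)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  def <- .config_defaults()
  for (sec in names(raw)) {
    unknown <- setdiff(names(raw[[sec]]), names(def[[sec]]))
    if (length(unknown))
      stop("unknown key(s) in section '", sec, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    def[[sec]] <- modifyList(def[[sec]], raw[[sec]])
  }
  cfg <- list(
    parameters = rgc_params(def$parameters),
    protocol = def$protocol,
    criteria = therapeutic_criteria(def$criteria$ca_toxicity_threshold,
                                    def$criteria$max_spike_loss_pct,
                                    def$criteria$baseline_mg),
    integration = def$integration)
  if (!cfg$integration$dt > 0) stop("integration dt must be > 0",
                                    call. = FALSE)
  if (!cfg$integration$method %in% c("euler", "rk4"))
    stop("integration method must be 'euler' or 'rk4'", call. = FALSE)
  structure(cfg, class = "rgc_config")
}

#' Write a configuration to YAML
#'
#' The written file is normalised (all keys present, default-filled), so
#' `dump_config(load_config(x))` followed by [load_config()] round-trips.
#'
#' @param config an `"rgc_config"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "rgc_config"))
  out <- list(parameters = unclass(config$parameters),
              protocol = config$protocol,
              criteria = unclass(config$criteria),
              integration = config$integration)
  yaml::write_yaml(out, path)
  invisible(path)
}

# stable 31-bit string hash (djb2 variant, exact in double arithmetic)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run manifest for reproducibility
#'
#' Collects everything needed to re-run a simulation bit-identically:
#' package version, the full parameter set, the protocol, the integrator
#' settings, and a stable hash of all of them.
#'
#' @param params model parameters.
#' @param protocol an [stim_protocol()] object (optional).
#' @param integration list with `dt`, `method`, `record_stride`.
#' @return A list of class `"rgc_manifest"` with a `hash` field.
#' @export
run_manifest <- function(params = rgc_params(), protocol = NULL,
                         integration = list(dt = 0.02, method = "euler",
                                            record_stride = 1)) {
  core <- list(package = "rgcmg",
               version = as.character(utils::packageVersion("rgcmg")),
               parameters = unclass(as_rgc_params(params)),
               protocol = if (is.null(protocol)) NULL else
                 list(freq = protocol$freq, pulse_width = protocol$pulse_width,
                      pulse_amp = protocol$pulse_amp,
                      stim_start = protocol$stim_start,
                      stim_end = protocol$stim_end, t_end = protocol$t_end,
                      mg_schedule = protocol$mg_schedule),
               integration = integration)
  core$hash <- config_hash(core[setdiff(names(core), "version")])
  structure(core, class = "rgc_manifest")
}

#' Write a trace to CSV with a JSON manifest sidecar
#'
#' @param trace an `rgc_trace`.
#' @param path CSV output path; the manifest is written next to it with a
#'   `.manifest.json` suffix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "rgc_trace"))
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  man <- run_manifest(attr(trace, "params"), attr(trace, "protocol"),
                      list(dt = attr(trace, "dt"),
                           method = attr(trace, "method"),
                           record_stride = attr(trace, "record_stride")))
  mpath <- sub("\\.csv$", "", path)
  mpath <- paste0(mpath, ".manifest.json")
  jsonlite::write_json(unclass(man), mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(csv = path, manifest = mpath))
}
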