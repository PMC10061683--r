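# Run configuration: plain-text (YAML) round trip, validation, and the
# shipped presets corresponding to the two model landscapes.

config_schema <- list(
  model = c("name", "params"),
  thermostat = c("temperature", "friction", "dt", "substeps", "decoherence",
                 "seed_noise", "seed_hop"),
  regions = c("cv", "a_op", "a_threshold", "a_states",
              "b_op", "b_threshold", "b_states"),
  interfaces = c("levels", "states"),
  run = c("mode", "n_steps", "flux_steps", "flux_method", "shots",
          "max_steps", "stride", "equil_steps", "out"))

#' Shipped run presets
#'
#' Complete run configurations for the two model landscapes with their
#' standard parameter sets: the avoided crossing (dt = 0.0539, T = 0.64/3,
#' gamma = 1.4133, s = 25, C = 0.1) in two region variants, and the conical
#' intersection (dt = 0.1348, T = 0.6370, gamma = 0.7995, s = 25, C = 0.1).
#'
#' @param name `"avoided_crossing"`, `"avoided_crossing_sweep"` (regions at
#'   x = -1/+1 instead of -0.5/+0.5), or `"conical_intersection"`.
#' @return A validated config list (see [load_config()]).
#' @export
preset_config <- function(name = c("avoided_crossing",
                                   "avoided_crossing_sweep",
                                   "conical_intersection")) {
  name <- match.arg(name)
  base_ac <- list(
    model = list(name = "avoided_crossing",
                 params = list(coupling = 0.4, well_offset = 1,
                               barrier_scale = 1,
                               transverse_stiffness = 12.8)),
    thermostat = list(temperature = 0.64 / 3, friction = 1.4133,
                      dt = 0.0539, substeps = 25L, decoherence = 0.1,
                      seed_noise = 1L, seed_hop = 2L),
    run = list(mode = "tsh", n_steps = 5e6, flux_steps = 1e6,
               flux_method = "reset", shots = 2000L, stride = 1L,
               equil_steps = 2000L))
  cfg <- switch(
    name,
    avoided_crossing = modifyList(base_ac, list(
      regions = list(cv = "x", a_op = "<", a_threshold = -0.5, a_states = 1L,
                     b_op = ">", b_threshold = 0.5, b_states = 1L),
      interfaces = list(levels = c(-0.5, -0.3, -0.1, 0.1, 0.3, 0.5),
                        states = c(1L, 2L)))),
    avoided_crossing_sweep = modifyList(base_ac, list(
      regions = list(cv = "x", a_op = "<", a_threshold = -1, a_states = 1L,
                     b_op = ">", b_threshold = 1, b_states = 1L),
      interfaces = list(levels = c(-1, -0.6, -0.2, 0.2, 0.6, 1),
                        states = c(1L, 2L)))),
    conical_intersection = list(
      model = list(name = "conical_intersection",
                   params = list(a = 0.512, b = 0.128, c = 0.5, d = 3.0,
                                 e = 12.8, k = 0.0128, f = 2.3)),
      thermostat = list(temperature = 0.6370, friction = 0.7995,
                        dt = 0.1348, substeps = 25L, decoherence = 0.1,
                        seed_noise = 1L, seed_hop = 2L),
      regions = list(cv = "x-y", a_op = ">=", a_threshold = 2.5,
                     a_states = 1L, b_op = "<=", b_threshold = -2.5,
                     b_states = 1L),
      interfaces = list(levels = c(2.5, 1.5, 0.5, -0.5, -1.5, -2.5),
                        states = c(1L, 2L)),
      run = list(mode = "tsh", n_steps = 5e6, flux_steps = 1e6,
                 flux_method = "no_reset", shots = 2000L, stride = 1L,
                 equil_steps = 2000L)))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  unknown_sections <- setdiff(names(cfg), names(config_schema))
  if (length(unknown_sections))
    abort(paste0("unknown config section(s): ",
                 paste(unknown_sections, collapse = ", ")))
  for (sec in names(cfg)) {
    unknown <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(unknown))
      abort(paste0("unknown key(s) in section `", sec, "`: ",
                   paste(unknown, collapse = ", ")))
  }
  for (sec in c("model", "thermostat"))
    if (is.null(cfg[[sec]]))
      abort(paste0("missing required config section `", sec, "`"))
  need_th <- c("temperature", "friction", "dt")
  miss <- setdiff(need_th, names(cfg$thermostat))
  if (length(miss))
    abort(paste0("missing thermostat key(s): ", paste(miss, collapse = ", ")))
  mp <- cfg$model$params
  if (identical(cfg$model$name, "avoided_crossing")) {
    if (is.null(mp$transverse_stiffness))
      abort("missing required model parameter: transverse_stiffness")
  } else if (identical(cfg$model$name, "conical_intersection")) {
    miss <- setdiff(c("a", "b", "c", "d", "e", "k", "f"), names(mp))
    if (length(miss))
      abort(paste0("missing model parameter(s): ",
                   paste(miss, collapse = ", ")))
  } else {
    abort(paste0("unknown model name `", cfg$model$name, "`"))
  }
  cfg
}

#' Load and validate a run configuration file
#'
#' Plain-text YAML with sections `model`, `thermostat`, `regions`,
#' `interfaces`, and `run`.  Unknown sections or keys and missing required
#' parameters produce errors naming the offending keys.  The configuration
#' round-trips losslessly through [save_config()].
#'
#' @param path Path to a YAML file.
#' @return Validated config list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg A config list.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Instantiate model, thermostat, regions, and interfaces from a config
#'
#' @param cfg A validated config list.
#' @return List with `model`, `thermo`, `A`, `B`, `interfaces`, `run`.
#' @export
config_objects <- function(cfg) {
  cfg <- validate_config(cfg)
  model <- if (cfg$model$name == "avoided_crossing")
    do.call(model_avoided_crossing, cfg$model$params)
  else do.call(model_conical_intersection, cfg$model$params)
  th <- cfg$thermostat
  thermo <- thermostat(th$temperature, th$friction, th$dt,
                       th$substeps %||% 25L, th$decoherence %||% 0.1,
                       th$seed_noise %||% 1L, th$seed_hop %||% 2L)
  A <- B <- interfaces <- NULL
  if (!is.null(cfg$regions)) {
    rg <- cfg$regions
    A <- region_spec(rg$cv, rg$a_op, rg$a_threshold, rg$a_states)
    B <- region_spec(rg$cv, rg$b_op, rg$b_threshold, rg$b_states)
  }
  if (!is.null(cfg$interfaces))
    interfaces <- interface_set(cfg$regions$cv, cfg$interfaces$levels,
                                states = cfg$interfaces$states)
  list(model = model, thermo = thermo, A = A, B = B,
       interfaces = interfaces, run = cfg$run)
}

#' Default initial snapshot for a config (lower-state minimum inside A)
#'
#' @param cfg A validated config list.
#' @return A `fh_snapshot`.
#' @export
config_init <- function(cfg) {
  a_side <- (cfg$regions$a_op %||% "<") %in% c("<", "<=")
  if (cfg$model$name == "avoided_crossing") {
    x0 <- cfg$model$params$well_offset %||% 1
    snapshot(c(if (a_side) -0.98 * x0 else 0.98 * x0, 0, 0))
  } else {
    d <- cfg$model$params$d %||% 3
    snapshot(c(if (a_side) -d else d, 0, 0))
  }
}
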