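#' Load a run configuration from a YAML file
#'
#' Parses and validates a YAML configuration describing one atomization case.
#' Quantities may be bare numbers (taken as SI) or `"value unit"` strings
#' (mL/min, kHz, mN/m, cP, um, ... see [to_si()]); everything is converted to
#' SI on load and the resolved values are kept in the returned object. Unknown
#' keys are rejected so typos cannot silently change a run.
#'
#' Schema (blocks; `*` = mandatory):
#' \describe{
#'   \item{fluid*}{`density`*, `surface_tension`*, and a viscosity model:
#'     `viscosity` and/or `K` + `n`, or `concentration` alone (alginate fits
#'     supply K and n).}
#'   \item{ultrasonic*}{`frequency`*, `power`*, `sound_speed`*, `area` or
#'     `geometry` (D_i_nozzle, D_f_nozzle, D_tip, D_o, L_act, H_tip),
#'     `coupling_density` (defaults to the fluid density).}
#'   \item{flow*}{`core` and/or `shell`, `policy` (shell/core/total).}
#'   \item{correlations}{`select`, `base_exponent`, `viscosity_policy`,
#'     `shear_rate`, `a_rp`, optional `envelope` overrides.}
#'   \item{particles}{list of `{label, fresh, dried}` diameter records.}
#'   \item{output}{`digits` for the text report.}
#' }
#'
#' @param path Path to the YAML file.
#' @return An object of class `run_config`: the validated blocks plus
#'   constructed `fluid`, `setup` and `flow` objects.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known_blocks <- c("fluid", "ultrasonic", "flow", "correlations",
                    "particles", "output")
  extra <- setdiff(names(raw), known_blocks)
  if (length(extra)) {
    stop_config("unknown config block(s): ", paste(extra, collapse = ", "))
  }
  need <- function(block, field, blockname) {
    if (is.null(block[[field]])) {
      stop_config("missing mandatory field `", blockname, ".", field, "`")
    }
    block[[field]]
  }
  reject_extras <- function(block, allowed, blockname) {
    extra <- setdiff(names(block), allowed)
    if (length(extra)) {
      stop_config("unknown field(s) in `", blockname, "`: ",
                  paste(extra, collapse = ", "))
    }
  }

  # fluid ---------------------------------------------------------------
  fb <- raw$fluid
  if (is.null(fb)) stop_config("missing mandatory block `fluid`")
  # YAML 1.1 reads a bare key `n` as boolean FALSE; map it back
  names(fb)[names(fb) %in% c("FALSE", "no")] <- "n"
  reject_extras(fb, c("density", "surface_tension", "viscosity", "K", "n",
                      "concentration"), "fluid")
  conc <- if (!is.null(fb$concentration)) to_si(fb$concentration, "percent",
                                                "fluid.concentration")
  K <- if (!is.null(fb$K)) to_si(fb$K, "viscosity", "fluid.K")
  n <- if (!is.null(fb$n)) as.numeric(fb$n)
  if (is.null(K) && !is.null(conc)) {
    K <- consistency_index_from_concentration(conc)
    n <- flow_index_from_concentration(conc)
  }
  fluid <- fluid_properties(
    density = to_si(need(fb, "density", "fluid"), "density", "fluid.density"),
    surface_tension = to_si(need(fb, "surface_tension", "fluid"),
                            "surface_tension", "fluid.surface_tension"),
    viscosity = if (!is.null(fb$viscosity)) to_si(fb$viscosity, "viscosity",
                                                  "fluid.viscosity"),
    K = K, n = n, concentration = conc
  )

  # ultrasonic ----------------------------------------------------------
  ub <- raw$ultrasonic
  if (is.null(ub)) stop_config("missing mandatory block `ultrasonic`")
  reject_extras(ub, c("frequency", "power", "area", "geometry", "sound_speed",
                      "coupling_density"), "ultrasonic")
  geometry <- NULL
  if (!is.null(ub$geometry)) {
    g <- ub$geometry
    gf <- c("D_i_nozzle", "D_f_nozzle", "D_tip", "D_o", "L_act", "H_tip")
    reject_extras(g, gf, "ultrasonic.geometry")
    args <- lapply(gf, function(nm) to_si(need(g, nm, "ultrasonic.geometry"),
                                          "length",
                                          paste0("ultrasonic.geometry.", nm)))
    names(args) <- gf
    geometry <- do.call(nozzle_geometry, args)
  }
  setup <- ultrasonic_setup(
    frequency = to_si(need(ub, "frequency", "ultrasonic"), "frequency",
                      "ultrasonic.frequency"),
    power = to_si(need(ub, "power", "ultrasonic"), "power", "ultrasonic.power"),
    area = if (!is.null(ub$area)) to_si(ub$area, "area", "ultrasonic.area"),
    geometry = geometry,
    sound_speed = to_si(need(ub, "sound_speed", "ultrasonic"), "velocity",
                        "ultrasonic.sound_speed"),
    coupling_density = if (!is.null(ub$coupling_density)) {
      to_si(ub$coupling_density, "density", "ultrasonic.coupling_density")
    } else fluid$density
  )

  # flow ----------------------------------------------------------------
  wb <- raw$flow
  if (is.null(wb)) stop_config("missing mandatory block `flow`")
  reject_extras(wb, c("core", "shell", "policy"), "flow")
  flow <- flow_config(
    Q_core = if (!is.null(wb$core)) to_si(wb$core, "flow", "flow.core") else 0,
    Q_shell = if (!is.null(wb$shell)) to_si(wb$shell, "flow", "flow.shell") else 0,
    policy = if (!is.null(wb$policy)) wb$policy else "shell"
  )

  # correlations --------------------------------------------------------
  cb <- raw$correlations
  reject_extras(cb, c("select", "base_exponent", "avvaru_exponent",
                      "viscosity_policy", "shear_rate", "a_rp", "envelope"),
                "correlations")
  corr <- list(
    select = if (!is.null(cb$select)) unlist(cb$select)
             else c("lang", "ramisetty", "avvaru", "barba"),
    base_exponent = if (!is.null(cb$base_exponent)) {
      if (identical(cb$base_exponent, "1/3")) 1 / 3 else as.numeric(cb$base_exponent)
    } else 0.33,
    avvaru_exponent = if (!is.null(cb$avvaru_exponent)) {
      if (identical(cb$avvaru_exponent, "1/3")) 1 / 3
      else as.numeric(cb$avvaru_exponent)
    } else 1 / 3,
    viscosity_policy = if (!is.null(cb$viscosity_policy)) cb$viscosity_policy
                       else "apparent",
    shear_rate = if (!is.null(cb$shear_rate)) to_si(cb$shear_rate, "shear_rate",
                                                    "correlations.shear_rate"),
    a_rp = if (!is.null(cb$a_rp)) as.numeric(cb$a_rp),
    envelope = if (!is.null(cb$envelope)) do.call(ramisetty_envelope, cb$envelope)
               else ramisetty_envelope()
  )

  # particles -----------------------------------------------------------
  particles <- NULL
  if (!is.null(raw$particles)) {
    particles <- do.call(rbind, lapply(raw$particles, function(p) {
      reject_extras(p, c("label", "fresh", "dried"), "particles")
      data.frame(label = if (!is.null(p$label)) p$label else "",
                 fresh = to_si(need(p, "fresh", "particles"), "length",
                               "particles.fresh") * 1e6,
                 dried = to_si(need(p, "dried", "particles"), "length",
                               "particles.dried") * 1e6,
                 stringsAsFactors = FALSE)
    }))
  }

  out_digits <- if (!is.null(raw$output$digits)) as.integer(raw$output$digits) else 4L

  structure(list(fluid = fluid, setup = setup, flow = flow,
                 correlations = corr, particles = particles,
                 output = list(digits = out_digits), source = path),
            class = "run_config")
}

#' Run a configuration and write report files
#'
#' Builds the [atomization_report()] for a loaded (or path-given)
#' configuration and writes the machine-readable JSON and the human-readable
#' text table. Output is deterministic: identical configs give byte-identical
#' JSON.
#'
#' @param config A `run_config` from [load_config()], or a path to a YAML file.
#' @param json Path for the JSON report (NULL to skip).
#' @param text Path for the text report (NULL to skip).
#' @return The `atomization_report`, invisibly.
#' @export
run_report <- function(config, json = NULL, text = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  co <- config$correlations
  rep <- atomization_report(
    fluid = config$fluid, setup = config$setup, flow = config$flow,
    correlations = co$select,
    viscosity_policy = co$viscosity_policy,
    shear_rate = co$shear_rate,
    base_exponent = co$base_exponent,
    avvaru_exponent = co$avvaru_exponent,
    a_rp = co$a_rp,
    particles = config$particles,
    envelope = co$envelope
  )
  if (!is.null(json)) report_json(rep, json)
  if (!is.null(text)) {
    writeLines(utils::capture.output(print(rep, digits = config$output$digits)),
               text)
  }
  invisible(rep)
}

#' Path to (or copy of) the bundled reference-case configuration
#'
#' The built-in worked case (see [reference_case()]) as a ready-to-edit YAML
#' config. With `copy_to` the file is copied there and that path returned.
#'
#' @param copy_to Optional destination path.
#' @return Path to the YAML file.
#' @export
reference_config <- function(copy_to = NULL) {
  src <- system.file("extdata", "reference_case.yaml", package = "sonodrop",
                     mustWork = TRUE)
  if (is.null(copy_to)) return(src)
  file.copy(src, copy_to, overwrite = TRUE)
  copy_to
}
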