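#' Full atomization prediction report
#'
#' Runs the whole prediction chain for one fluid / ultrasonic setup / feed
#' configuration: vibration amplitude and surface intensity, ultrasonic
#' dimensionless numbers, the critical/maximum flow-rate operating window, the
#' selected droplet-size correlations with validity flags, and (optionally)
#' volumetric shrinkage of measured fresh/dried particle sizes. The report is
#' deterministic: the same inputs give the same object.
#'
#' When the apparent-viscosity and zero-shear policies give Ohnesorge numbers
#' differing by more than 1%, correlations that depend on Oh are evaluated and
#' reported under both policies; `viscosity_policy` selects which one fills
#' the headline `diameter` column.
#'
#' @param fluid A [fluid_properties()].
#' @param setup An [ultrasonic_setup()].
#' @param flow A [flow_config()] or a single flow rate in m^3/s.
#' @param correlations Character vector choosing among `"lang"`,
#'   `"rajan_pandit"`, `"ramisetty"`, `"avvaru"`, `"barba"`. Empty selection
#'   yields a report with dimensionless numbers and operating window only.
#' @param viscosity_policy `"apparent"` (power-law viscosity at `shear_rate`,
#'   the default) or `"zero_shear"`.
#' @param shear_rate Wall shear rate for the apparent policy, 1/s.
#' @param base_exponent Base-term exponent for the bracketed/product
#'   correlations (Rajan-Pandit, Ramisetty, Barba): 0.33 as printed (default)
#'   or exact 1/3.
#' @param avvaru_exponent Base-term exponent for the additive Avvaru
#'   correlation; defaults to exact 1/3, which reproduces the published
#'   alginate prediction.
#' @param a_rp Rajan-Pandit prefactor; required only when that correlation is
#'   selected.
#' @param particles Optional named list or data frame with `label`, `fresh`
#'   and `dried` diameters (any consistent unit) for shrinkage reporting.
#' @param envelope Validity envelope used for the Ramisetty flags.
#' @return An object of class `atomization_report`.
#' @examples
#' rep <- atomization_report(
#'   fluid = fluid_properties(1004, 0.07, viscosity = 0.13, K = 0.205, n = 0.854),
#'   setup = ultrasonic_setup(25000, 10, area = 1.38e-3, sound_speed = 1497,
#'                            coupling_density = 1004),
#'   flow = flow_config(Q_core = 1.83e-8, Q_shell = 7e-8),
#'   shear_rate = 333)
#' print(rep)
#' @export
atomization_report <- function(fluid, setup, flow,
                               correlations = c("lang", "ramisetty",
                                                "avvaru", "barba"),
                               viscosity_policy = c("apparent", "zero_shear"),
                               shear_rate = NULL,
                               base_exponent = 0.33,
                               avvaru_exponent = 1 / 3,
                               a_rp = NULL,
                               particles = NULL,
                               envelope = ramisetty_envelope()) {
  viscosity_policy <- match.arg(viscosity_policy)
  known <- c("lang", "rajan_pandit", "ramisetty", "avvaru", "barba")
  if (length(correlations)) {
    correlations <- match.arg(correlations, known, several.ok = TRUE)
  }
  if (is.numeric(flow)) flow <- flow_config(Q_shell = flow)

  dims <- dimensionless_set(fluid, setup, flow, viscosity_policy, shear_rate)

  # both viscosity policies, where resolvable, for the dual-policy columns
  dims_both <- list()
  for (pol in c("apparent", "zero_shear")) {
    dims_both[[pol]] <- tryCatch(
      dimensionless_set(fluid, setup, flow, pol, shear_rate),
      error = function(e) NULL)
  }
  dims_both <- Filter(Negate(is.null), dims_both)

  Q_c <- critical_flow_rate(fluid$surface_tension, fluid$density,
                            setup$frequency)
  Q_max <- max_flow_rate(setup$frequency, setup$amplitude, setup$area)
  window <- operating_window(dims$provenance$Q, Q_c, Q_max)

  sigma <- fluid$surface_tension; rho <- fluid$density; f <- setup$frequency

  eval_one <- function(name, d) {
    vio <- if (name == "ramisetty") {
      check_validity(list(f = f, rho = rho, sigma = sigma,
                          Oh = d$Oh, We = d$We, I_N = d$I_N), envelope)
    } else {
      check_validity(list(), envelope)
    }
    diameter <- switch(
      name,
      lang = lang_diameter(sigma, rho, f),
      rajan_pandit = rajan_pandit_diameter(sigma, rho, f, d$We, d$Oh, d$I_N,
                                           a_rp = a_rp,
                                           exponent = base_exponent),
      ramisetty = ramisetty_diameter(sigma, rho, f, d$We, d$Oh, d$I_N,
                                     exponent = base_exponent),
      avvaru = {
        if (is.null(fluid$n)) {
          stop_config("the Avvaru correlation needs the power-law flow index `n`")
        }
        avvaru_diameter(sigma, rho, f, d$We, d$Oh, d$I_N, n = fluid$n,
                        exponent = avvaru_exponent)
      },
      barba = barba_diameter(sigma, rho, f, d$We, d$Oh, d$I_N,
                             exponent = base_exponent)
    )
    list(diameter = diameter, violations = vio)
  }

  preds <- list()
  for (nm in correlations) {
    main <- eval_one(nm, dims)
    alt <- NULL
    if (nm != "lang" && length(dims_both) == 2L) {
      oh_gap <- abs(dims_both$apparent$Oh - dims_both$zero_shear$Oh) /
        dims_both$zero_shear$Oh
      if (oh_gap > 0.01) {
        other <- setdiff(names(dims_both), viscosity_policy)
        alt <- list(policy = other,
                    diameter = eval_one(nm, dims_both[[other]])$diameter)
      }
    }
    preds[[nm]] <- list(
      correlation = nm,
      diameter = main$diameter,
      validity_violations = main$violations,
      alternative = alt,
      inputs_used = list(viscosity_policy = viscosity_policy,
                         base_exponent = if (nm == "avvaru") avvaru_exponent
                                         else base_exponent,
                         Q = dims$provenance$Q,
                         mu = dims$provenance$mu)
    )
  }

  shrink <- NULL
  if (!is.null(particles)) {
    p <- as.data.frame(particles, stringsAsFactors = FALSE)
    shrink <- data.frame(
      label = if ("label" %in% names(p)) p$label else paste0("set", seq_len(nrow(p))),
      fresh = p$fresh, dried = p$dried,
      shrinkage_pct = volumetric_shrinkage(p$fresh, p$dried),
      stringsAsFactors = FALSE
    )
  }

  structure(
    list(fluid = fluid, setup = setup, flow = flow,
         dimensionless = dims, dimensionless_by_policy = dims_both,
         operating_window = window, predictions = preds,
         shrinkage = shrink,
         policies = list(viscosity = viscosity_policy,
                         flow = flow$policy,
                         base_exponent = base_exponent,
                         avvaru_exponent = avvaru_exponent,
                         shear_rate = shear_rate)),
    class = "atomization_report"
  )
}

#' @export
print.atomization_report <- function(x, digits = 4, ...) {
  cat("Ultrasonic atomization prediction report\n")
  cat("-----------------------------------------\n")
  d <- x$dimensionless
  cat(sprintf("We = %.*g   Oh = %.*g   I_N = %.*g\n",
              digits, d$We, digits, d$Oh, digits, d$I_N))
  cat(sprintf("policies: viscosity '%s' (mu = %.3g Pa s), flow '%s' (Q = %.3g m^3/s)\n",
              x$policies$viscosity, d$provenance$mu, x$policies$flow,
              d$provenance$Q))
  w <- x$operating_window
  cat(sprintf("operating window: Q_c = %.3g, Q = %.3g, Q_max = %.3g m^3/s -> %s\n",
              w$Q_c, w$Q, w$Q_max, w$verdict))
  if (length(x$predictions)) {
    cat("\npredicted droplet diameters:\n")
    for (p in x$predictions) {
      flag <- if (nrow(p$validity_violations)) {
        paste0("  [outside validity: ",
               paste(p$validity_violations$quantity, collapse = ", "), "]")
      } else ""
      alt <- if (!is.null(p$alternative)) {
        sprintf("  (%.1f um under '%s' policy)",
                p$alternative$diameter * 1e6, p$alternative$policy)
      } else ""
      cat(sprintf("  %-13s %6.1f um%s%s\n", p$correlation,
                  p$diameter * 1e6, alt, flag))
    }
  }
  if (!is.null(x$shrinkage)) {
    cat("\nvolumetric shrinkage on drying:\n")
    for (i in seq_len(nrow(x$shrinkage))) {
      r <- x$shrinkage[i, ]
      cat(sprintf("  %-25s %g -> %g: %.0f%%\n", r$label, r$fresh, r$dried,
                  round(r$shrinkage_pct)))
    }
  }
  invisible(x)
}

#' @export
summary.atomization_report <- function(object, ...) {
  df <- as.data.frame(object)
  cat("Atomization report summary\n")
  print(df, row.names = FALSE)
  invisible(df)
}

#' Tabulate an atomization report
#'
#' @param x An `atomization_report`.
#' @param row.names,optional,... Passed through for S3 consistency; unused.
#' @return A data frame with one row per correlation: predicted diameter (m
#'   and um), validity status, and the viscosity policy used.
#' @export
as.data.frame.atomization_report <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  if (!length(x$predictions)) {
    return(data.frame(correlation = character(), diameter_m = numeric(),
                      diameter_um = numeric(), valid = logical(),
                      viscosity_policy = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$predictions, function(p) {
    data.frame(correlation = p$correlation,
               diameter_m = p$diameter,
               diameter_um = p$diameter * 1e6,
               valid = nrow(p$validity_violations) == 0L,
               viscosity_policy = p$inputs_used$viscosity_policy,
               stringsAsFactors = FALSE)
  }))
}

#' Serialize an atomization report to JSON
#'
#' Full-precision, deterministic JSON rendering of a report; identical inputs
#' produce byte-identical output. The schema is versioned under `$schema`.
#'
#' @param x An `atomization_report`.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "atomization_report"))
  d <- x$dimensionless
  payload <- list(
    schema = "sonodrop-report/1",
    inputs = list(
      fluid = x$fluid[!vapply(x$fluid, is.null, logical(1))],
      ultrasonic = list(frequency = x$setup$frequency, power = x$setup$power,
                        area = x$setup$area, sound_speed = x$setup$sound_speed,
                        coupling_density = x$setup$coupling_density,
                        intensity = x$setup$intensity,
                        amplitude = x$setup$amplitude),
      flow = unclass(x$flow),
      policies = x$policies
    ),
    dimensionless = list(We = d$We, Oh = d$Oh, I_N = d$I_N,
                         provenance = d$provenance),
    operating_window = x$operating_window,
    predictions = lapply(x$predictions, function(p) {
      list(diameter_m = p$diameter, diameter_um = p$diameter * 1e6,
           valid = nrow(p$validity_violations) == 0L,
           validity_violations = p$validity_violations,
           alternative_policy = p$alternative,
           inputs_used = p$inputs_used)
    }),
    shrinkage = x$shrinkage
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
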