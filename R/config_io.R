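#' Serialise a testbed scenario to a YAML config file
#'
#' Writes every component of a [testbed_config] (artery, tube law,
#' Windkessel, inlet shape, stations, solver controls) as a structured
#' key-value file, and reads it back into an identical config.
#'
#' @param config A [testbed_config].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "testbed_config"))
  x <- list(
    artery = unclass(config$artery),
    tube_law = list(kind = config$law$kind, A_ref = config$law$A_ref,
                    P_ref = config$law$P_ref, params = config$law$params),
    windkessel = unclass(config$wk)[c("Rp", "Rd", "C")],
    inlet = unclass(config$inlet),
    stations = list(x1 = config$stations$x1, x2 = config$stations$x2),
    solver = list(n_nodes = config$n_nodes, dt = config$dt,
                  n_cycles = config$n_cycles,
                  friction_coefficient = config$friction_coefficient,
                  P_init = config$P_init,
                  P_max_expected = config$P_max_expected))
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_scenario_config
#' @return For `read_scenario_config`, a [testbed_config].
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  art <- do.call(artery_spec, x$artery)
  law <- do.call(tube_law, c(list(kind = x$tube_law$kind,
                                  A_ref = x$tube_law$A_ref,
                                  P_ref = x$tube_law$P_ref),
                             x$tube_law$params))
  wk <- do.call(wk3_params, x$windkessel)
  inlet <- do.call(inlet_flow_spec, x$inlet)
  stations <- measurement_plan(x$stations$x1, x$stations$x2,
                               L_total = art$L_total)
  testbed_config(art, law, wk, inlet, stations = stations,
                 n_nodes = x$solver$n_nodes, dt = x$solver$dt,
                 n_cycles = x$solver$n_cycles,
                 friction_coefficient = x$solver$friction_coefficient,
                 P_init = x$solver$P_init,
                 P_max_expected = x$solver$P_max_expected)
}
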