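#' Read and validate a material parameter file
#'
#' Material files are YAML or JSON mappings in strict SI units with a
#' \code{model} key naming one of \code{network}, \code{kelvin_voigt},
#' \code{zener}, \code{fractional_kv}, \code{fractional_zener},
#' \code{biot}, \code{bicsqs}, the model's own parameter keys, and the
#' optional keys \code{rho} (density for dispersion, kg/m^3; the Biot
#' model computes its own aggregate density) and \code{frequency_grid}
#' (\code{min_hz}, \code{max_hz}, \code{n}, \code{spacing} =
#' \code{"log"} or \code{"linear"}).  Frequencies are plain Hz at this
#' boundary and converted to angular frequency internally.  Unknown
#' keys are an error, not a warning.
#'
#' @param path file path (\code{.yaml}, \code{.yml} or \code{.json}).
#' @return list of class \code{"material_file"} with elements
#'   \code{model} (string), \code{object} (the constructed parameter
#'   object), \code{rho} (density or \code{NULL}), \code{grid}
#'   (angular frequencies, rad/s) and \code{raw} (the echoed input).
#' @export
read_material_file <- function(path) {
  if (!file.exists(path))
    validation_stop("material file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  # keep YAML 1.1 boolean-like scalars (`n`, `no`, `y`, ...) literal:
  # the schema has no boolean fields and `n` is a frequency_grid key
  literal <- function(x) x
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path, handlers = list("bool#no" = literal,
                                                "bool#yes" = literal)),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    validation_stop("unsupported material file extension: .", ext))
  if (!is.list(raw) || is.null(raw$model))
    validation_stop("material file must be a mapping with a `model` key")
  model <- raw$model
  spec <- material_keys[[model]]
  if (is.null(spec))
    validation_stop("unknown model name: ", model)
  keys <- setdiff(names(raw), "model")
  unknown <- setdiff(keys, c(spec$required, spec$optional,
                             "rho", "frequency_grid"))
  if (length(unknown))
    validation_stop("unknown key(s) for model `", model, "`: ",
                    paste(unknown, collapse = ", "))
  missing <- setdiff(spec$required, keys)
  if (length(missing))
    validation_stop("missing key(s) for model `", model, "`: ",
                    paste(missing, collapse = ", "))
  object <- tryCatch(material_build(model, raw),
                     error = function(e) validation_stop(conditionMessage(e)))
  grid <- parse_frequency_grid(raw$frequency_grid)
  if (!is.null(raw$rho) && (!is.numeric(raw$rho) || raw$rho <= 0))
    validation_stop("`rho` must be a positive density in kg/m^3")
  structure(list(model = model, object = object, rho = raw$rho,
                 grid = grid, raw = raw),
            class = "material_file")
}

material_keys <- list(
  network = list(required = c("topology", "units"), optional = "E_e"),
  kelvin_voigt = list(required = c("E_e", "eta"), optional = character()),
  zener = list(required = c("E_e", "tau_eps", "tau_sig"),
               optional = character()),
  fractional_kv = list(required = c("E_e", "tau_eps", "alpha"),
                       optional = character()),
  fractional_zener = list(required = c("E_e", "tau_eps", "tau_sig", "alpha"),
                          optional = character()),
  biot = list(required = c("phi", "rho_s", "rho_f", "K_s", "K_f", "eta_f",
                           "B", "tortuosity", "K_r", "mu_r"),
              optional = character()),
  bicsqs = list(required = c("mu", "omega_mu", "omega_eps", "omega_sig"),
                optional = character())
)

material_build <- function(model, raw) {
  switch(model,
    network = {
      units <- raw$units
      if (is.data.frame(units)) units <- split(units, seq_len(nrow(units)))
      E <- vapply(units, function(u) as.numeric(u$E), numeric(1))
      eta <- vapply(units, function(u) as.numeric(u$eta), numeric(1))
      sdnet(raw$topology, E = E, eta = eta,
            E_e = if (is.null(raw$E_e)) 0 else raw$E_e)
    },
    kelvin_voigt = kelvin_voigt(raw$E_e, raw$eta),
    zener = zener(raw$E_e, raw$tau_eps, raw$tau_sig),
    fractional_kv = fractional_kv(raw$E_e, raw$tau_eps, raw$alpha),
    fractional_zener = fractional_zener(raw$E_e, raw$tau_eps, raw$tau_sig,
                                        raw$alpha),
    biot = biot_medium(raw$phi, raw$rho_s, raw$rho_f, raw$K_s, raw$K_f,
                       raw$eta_f, raw$B, raw$tortuosity, raw$K_r, raw$mu_r),
    bicsqs = four_param_model(raw$mu, raw$omega_mu, raw$omega_eps,
                              raw$omega_sig)
  )
}

parse_frequency_grid <- function(fg) {
  if (is.null(fg)) fg <- list()
  defaults <- list(min_hz = 1, max_hz = 1000, n = 200, spacing = "log")
  unknown <- setdiff(names(fg), names(defaults))
  if (length(unknown))
    validation_stop("unknown frequency_grid key(s): ",
                    paste(unknown, collapse = ", "))
  fg <- utils::modifyList(defaults, fg)
  if (!fg$spacing %in% c("log", "linear"))
    validation_stop("frequency_grid spacing must be `log` or `linear`")
  if (fg$min_hz <= 0 || fg$max_hz <= fg$min_hz || fg$n < 2)
    validation_stop("frequency_grid needs 0 < min_hz < max_hz and n >= 2")
  f <- if (fg$spacing == "log") {
    10^seq(log10(fg$min_hz), log10(fg$max_hz), length.out = fg$n)
  } else {
    seq(fg$min_hz, fg$max_hz, length.out = fg$n)
  }
  2 * pi * f
}

validation_stop <- function(...) {
  stop(structure(class = c("rw_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Dynamic modulus of any material description
#'
#' Evaluates the complex dynamic modulus of a validated
#' [read_material_file()] object (or constructs the right call for the
#' parameter object it holds) on an angular frequency grid.
#'
#' @param mat a \code{"material_file"}.
#' @param omega angular frequencies [rad/s].
#' @return complex vector.
#' @export
material_modulus <- function(mat, omega) {
  stopifnot(inherits(mat, "material_file"))
  switch(mat$model,
    network = network_modulus(mat$object, omega),
    kelvin_voigt = ,
    zener = zener_modulus(mat$object, omega),
    fractional_kv = ,
    fractional_zener = frac_modulus(mat$object, omega),
    biot = biot_shear_stoll(mat$object, omega)$E,
    bicsqs = bicsqs_modulus(mat$object, omega)
  )
}

#' Write a dispersion curve as CSV
#'
#' Fixed header
#' \code{freq_hz,re_E_pa,im_E_pa,re_k_per_m,im_k_per_m,phase_velocity_m_s,attenuation_np_m},
#' full \code{\%.17g} precision, \code{.} decimal and comma separator
#' regardless of locale, so curves round-trip bit-exactly through
#' [read_dispersion_csv()].
#'
#' @param curve a [dispersion()] curve.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_dispersion_csv <- function(curve, path) {
  stopifnot(inherits(curve, "dispersion_curve"))
  cols <- list(curve$omega / (2 * pi), Re(curve$E), Im(curve$E),
               Re(curve$k), Im(curve$k), curve$c_p, curve$alpha_k)
  lines <- c(paste(c("freq_hz", "re_E_pa", "im_E_pa", "re_k_per_m",
                     "im_k_per_m", "phase_velocity_m_s",
                     "attenuation_np_m"), collapse = ","),
             do.call(paste, c(lapply(cols, function(x) sprintf("%.17g", x)),
                              sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dispersion_csv
#' @export
read_dispersion_csv <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' Write the canonical fixture material files
#'
#' Emits the small YAML material descriptions used throughout the
#' examples and tests: a unit Zener solid, a fractional Kelvin-Voigt
#' solid (order 0.3) and fractional Zener solid (order 0.8, time
#' constants three decades apart) with tissue-like stiffnesses, a
#' Biot baseline medium (porosity 0.5, water-like pore fluid, soft
#' frame) and its BICSQS extension.  All magnitudes are physically
#' plausible placeholders; every file round-trips through
#' [read_material_file()].
#'
#' @param out_dir writable output directory (created if needed).
#' @return character vector of the paths written.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- list(
    zener_unit = list(model = "zener", E_e = 1, tau_eps = 2, tau_sig = 1,
                      rho = 1,
                      frequency_grid = list(min_hz = 1e-3, max_hz = 1e3,
                                            n = 121, spacing = "log")),
    frac_kv = list(model = "fractional_kv", E_e = 2000, tau_eps = 0.01,
                   alpha = 0.3, rho = 1000),
    frac_zener = list(model = "fractional_zener", E_e = 2000, tau_eps = 0.1,
                      tau_sig = 1e-4, alpha = 0.8, rho = 1000),
    biot_baseline = list(model = "biot", phi = 0.5, rho_s = 2650,
                         rho_f = 1000, K_s = 3.6e10, K_f = 2.2e9,
                         eta_f = 1e-3, B = 1e-11, tortuosity = 1.25,
                         K_r = 5e7, mu_r = 5e3),
    bicsqs = list(model = "bicsqs", mu = 5000, omega_mu = 1e6,
                  omega_eps = 4e4, omega_sig = 5.1228e4, rho = 1825)
  )
  paths <- character()
  for (nm in names(fx)) {
    path <- file.path(out_dir, paste0(nm, ".yaml"))
    yaml::write_yaml(fx[[nm]], path)
    read_material_file(path)   # every fixture must validate
    paths <- c(paths, path)
  }
  paths
}
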