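#' Isotope standards registry
#'
#' The international reference ratios that define the delta scales used in
#' bulk isotope-ratio mass spectrometry: VPDB for \eqn{\delta^{13}}C, AIR
#' for \eqn{\delta^{15}}N and VSMOW for \eqn{\delta}D. The ratios are
#' configuration, not constants baked into the computation paths: every
#' conversion takes a `standards` table, so a laboratory using a different
#' calibration can swap the registry without touching code.
#'
#' @param path Optional path to a YAML registry overriding the built-in
#'   values. The file maps isotope-pair names to `reference_name` and
#'   `reference_ratio` entries; see
#'   `system.file("extdata", "standards.yml", package = "mycoflux")` for the
#'   format.
#'
#' @return A tibble with one row per isotope pair and columns `system`
#'   (e.g. `"13C/12C"`), `element` (`"C"`, `"N"` or `"H"`),
#'   `reference_name` and `reference_ratio` (dimensionless heavy/light).
#'
#' @examples
#' iso_standards()
#' @export
iso_standards <- function(path = NULL) {
  if (is.null(path)) {
    reg <- tibble::tibble(
      system          = c("13C/12C", "15N/14N", "D/H"),
      element         = c("C", "N", "H"),
      reference_name  = c("VPDB", "AIR", "VSMOW"),
      reference_ratio = c(0.0111802, 0.0036765, 0.00015576)
    )
  } else {
    raw <- yaml::read_yaml(path)
    reg <- purrr::imap_dfr(raw, function(entry, nm) {
      tibble::tibble(
        system          = nm,
        element         = yaml_element(entry$element),
        reference_name  = entry$reference_name,
        reference_ratio = as.numeric(entry$reference_ratio)
      )
    })
  }
  validate_standards(reg)
  reg
}

# a bare `element: N` in YAML parses as logical FALSE; map it back
yaml_element <- function(x) {
  if (is.logical(x)) return(if (isFALSE(x)) "N" else NA_character_)
  as.character(x)
}

validate_standards <- function(reg) {
  required <- c("system", "element", "reference_name", "reference_ratio")
  missing <- setdiff(required, names(reg))
  if (length(missing) > 0) {
    abort(
      paste0("standards registry lacks column(s): ",
             paste(missing, collapse = ", ")),
      class = "mycoflux_config_error"
    )
  }
  if (anyDuplicated(reg$system) > 0) {
    abort("standards registry must contain exactly one entry per isotope pair",
          class = "mycoflux_config_error")
  }
  if (any(!is.finite(reg$reference_ratio) | reg$reference_ratio <= 0)) {
    abort("reference ratios must be finite and > 0",
          class = "mycoflux_config_error")
  }
  invisible(reg)
}

#' Look up one isotope system
#'
#' Accepts the isotope-pair name (`"13C/12C"`), the element symbol (`"C"`)
#' or the reference-material name (`"VPDB"`) and returns the matching
#' registry row.
#'
#' @param system Isotope pair, element or reference name.
#' @param standards Registry tibble from [iso_standards()].
#' @return A one-row tibble.
#' @export
iso_system <- function(system, standards = iso_standards()) {
  validate_standards(standards)
  hit <- standards[standards$system == system |
                     standards$element == system |
                     standards$reference_name == system, ]
  if (nrow(hit) != 1) {
    abort(paste0("unknown or ambiguous isotope system: ", system),
          class = "mycoflux_config_error")
  }
  hit
}
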