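detect_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read and write bulk-IRMS sample tables
#'
#' Delimited text (comma or tab, auto-detected) with the header columns
#' `sample_id, arm_id, compartment_id, role, element, dry_mass_g,
#' element_pct, delta_permil, replicate`. Unknown columns are preserved and
#' passed through. A missing schema column raises an error naming the
#' column; a non-numeric delta raises a row-level error with the offending
#' line.
#'
#' @param path File path.
#' @param samples A sample table tibble.
#' @param delim Output delimiter for the writer.
#' @return `read_sample_table()`: a typed tibble, one row per input row.
#' @export
read_sample_table <- function(path) {
  delim <- detect_delim(path)
  # parse problems become hard errors below; readr's interim warnings are noise
  tab <- suppressWarnings(readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      arm_id = readr::col_character(),
      compartment_id = readr::col_character(),
      role = readr::col_character(),
      element = readr::col_character(),
      dry_mass_g = readr::col_double(),
      element_pct = readr::col_double(),
      delta_permil = readr::col_double(),
      replicate = readr::col_integer(),
      .default = readr::col_guess()
    )
  ))
  check_sample_table(tab)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(paste0("non-numeric or malformed value(s) at line(s) ",
                 paste(unique(probs$row + 1), collapse = ", "),
                 " of ", path),
          class = "mycoflux_schema_error")
  }
  bad_delta <- which(is.na(tab$delta_permil))
  if (length(bad_delta) > 0) {
    abort(paste0("missing/non-numeric delta_permil at row(s) ",
                 paste(bad_delta, collapse = ", ")),
          class = "mycoflux_schema_error")
  }
  tab
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(samples, path, delim = ",") {
  check_sample_table(samples)
  readr::write_delim(samples, path, delim = delim)
  invisible(path)
}

#' Read a labelling plan
#'
#' YAML file with an `events` list (`arm_id`, `compartment_id`, `compound`,
#' `amount_mg`) and an optional `compounds` map overriding or extending
#' [tracer_compounds()].
#'
#' @param path File path.
#' @return A list with tibbles `events` and `compounds`.
#' @export
read_labelling_plan <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$events)) {
    abort("labelling plan lacks an `events` section",
          class = "mycoflux_schema_error")
  }
  events <- purrr::map_dfr(raw$events, tibble::as_tibble)
  needed <- c("arm_id", "compartment_id", "compound", "amount_mg")
  missing <- setdiff(needed, names(events))
  if (length(missing) > 0) {
    abort(paste0("labelling plan events lack field(s): ",
                 paste(missing, collapse = ", ")),
          class = "mycoflux_schema_error")
  }
  compounds <- tracer_compounds()
  if (!is.null(raw$compounds)) {
    extra <- purrr::imap_dfr(raw$compounds, function(def, nm) {
      tibble::tibble(name = nm, element = yaml_element(def$element),
                     molar_mass = as.numeric(def$molar_mass),
                     labelled_atoms = as.integer(def$labelled_atoms),
                     af_tracer = def$af_tracer %||% 0.99)
    })
    compounds <- dplyr::bind_rows(
      dplyr::filter(compounds, !.data$name %in% extra$name), extra
    )
  }
  list(events = events, compounds = compounds)
}

#' Read and write ion-count matrices
#'
#' One 2-D integer matrix per species per plane as delimited text (no
#' header), the exchange format expected from the upstream image-export
#' step. Raw vendor files (.im) are out of scope; export matrices from the
#' acquisition software instead.
#'
#' @param path File path.
#' @param m An integer matrix.
#' @param delim Delimiter (default tab).
#' @return `read_ion_matrix()`: an integer matrix.
#' @export
read_ion_matrix <- function(path, delim = "\t") {
  m <- as.matrix(utils::read.table(path, sep = delim, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0)) {
    abort(paste0("ion-count matrix has missing or negative entries: ", path),
          class = "mycoflux_schema_error")
  }
  m
}

#' @rdname read_ion_matrix
#' @export
write_ion_matrix <- function(m, path, delim = "\t") {
  utils::write.table(m, path, sep = delim, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
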