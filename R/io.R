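#' Write / read time-series traces as annotated CSV
#'
#' Writes a trace table (drive signals, trajectories, session recordings)
#' as CSV with a header row preceded by a `# units:` comment line; values
#' are written with 15 significant digits so a round trip is lossless well
#' beyond 12 significant digits.
#'
#' @param x A data frame whose first column is `t`.
#' @param path File path.
#' @param units Character vector of unit labels, one per column.
#' @return `write_traces_csv` returns `path` invisibly; `read_traces_csv`
#'   returns a tibble with the units stored in attribute `units`.
#' @export
write_traces_csv <- function(x, path, units = NULL) {
  if (is.null(units)) {
    defaults <- c(t = "s", p_rcmus = "cmH2O", p_dimus = "cmH2O",
                  p_rex = "cmH2O", v_rc = "L", v_ab = "L", v_l = "L",
                  p_pl = "cmH2O", p_ab = "cmH2O", x_di = "cm",
                  displacement = "cm", flow = "L/s", depth = "cm",
                  pressure = "kPa", target = "kPa", t_index = "1")
    units <- unname(defaults[names(x)])
    units[is.na(units)] <- "1"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", paste(units, collapse = ", ")), con)
  writeLines(paste(names(x), collapse = ","), con)
  num <- vapply(seq_len(nrow(x)), function(i) {
    paste(vapply(x[i, ], function(v) {
      if (is.numeric(v)) sprintf("%.15g", v) else as.character(v)
    }, character(1)), collapse = ",")
  }, character(1))
  writeLines(num, con)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  first <- readLines(path, n = 1L)
  units <- NULL
  skip <- 0L
  if (startsWith(first, "# units:")) {
    units <- trimws(strsplit(sub("^# units:\\s*", "", first), ",")[[1L]])
    skip <- 1L
  }
  out <- tibble::as_tibble(utils::read.csv(path, skip = skip,
                                           comment.char = ""))
  attr(out, "units") <- units
  out
}

#' Write / read a waveform configuration as YAML
#'
#' Serializes a breath pattern plus robot program (shape, level, timing,
#' amplitudes, transmission gain) to a YAML block and back.
#'
#' @param pattern A [breath_pattern()].
#' @param program A [robot_program()] or `NULL`.
#' @param path File path.
#' @return `write_waveform_yaml` returns `path` invisibly;
#'   `read_waveform_yaml` returns `list(pattern =, program =)`.
#' @export
write_waveform_yaml <- function(pattern, program = NULL, path) {
  cfg <- list(breath = unclass(pattern))
  if (!is.null(program)) cfg$robot <- unclass(program)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_waveform_yaml
#' @export
read_waveform_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  pattern <- do.call(breath_pattern, cfg$breath)
  program <- if (!is.null(cfg$robot)) do.call(robot_program, cfg$robot)
  list(pattern = pattern, program = program)
}

#' Write a report list as JSON
#'
#' @param report A named list.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# SHA-256 of a file via the system binary, md5 fallback (algorithm recorded)
file_checksum <- function(path) {
  sha <- Sys.which("sha256sum")
  if (nzchar(sha)) {
    out <- tryCatch(system2(sha, shQuote(path), stdout = TRUE),
                    error = function(e) character(0), warning = function(w) character(0))
    if (length(out) >= 1L) {
      return(list(algorithm = "sha256", value = strsplit(out[1L], "\\s+")[[1L]][1L]))
    }
  }
  list(algorithm = "md5", value = unname(tools::md5sum(path)))
}
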