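#' Write a trajectory to CSV
#'
#' Comma-separated with a header row, `.` decimal mark, no thousands
#' separators; numeric values are printed with 17 significant digits so
#' the file round-trips bit-for-bit through [read_trajectory_csv()].
#'
#' @param traj a `trajectory` data.frame (see [integrate_model()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  fmt <- as.data.frame(lapply(traj, function(col) sprintf("%.17g", col)),
                       stringsAsFactors = FALSE)
  names(fmt) <- names(traj)
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path file path.
#' @return a `trajectory` data.frame.
#' @export
read_trajectory_csv <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "numeric")
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Serialize a stability report to JSON
#'
#' Complex eigenvalues are written as `{re, im}` pairs; all other fields
#' are plain numbers or strings. [read_stability_json()] reconstructs the
#' `stability_report` object.
#'
#' @param report a [stability_report()] (including the extended Leslie
#'   variant).
#' @param path output file path; `NULL` returns the JSON string instead.
#' @return the path (invisibly), or the JSON string when `path` is `NULL`.
#' @export
write_stability_json <- function(report, path = NULL) {
  payload <- unclass(report)
  payload$jacobian <- unname(payload$jacobian)
  payload$eigenvalues <- lapply(payload$eigenvalues,
                                function(z) list(re = Re(z), im = Im(z)))
  if (!is.null(payload$point)) payload$point <- as.list(payload$point)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_stability_json
#' @export
read_stability_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.matrix(payload$jacobian)) {
    payload$jacobian <- matrix(unlist(payload$jacobian), nrow = 2,
                               byrow = TRUE)
  }
  payload$eigenvalues <- vapply(payload$eigenvalues,
                                function(z) complex(real = z$re,
                                                    imaginary = z$im),
                                complex(1))
  if (!is.null(payload$point)) payload$point <- unlist(payload$point)
  class(payload) <- "stability_report"
  payload
}

#' Sample a vector field on a regular grid
#'
#' Quantitative phase-portrait data: the velocity field evaluated on an
#' `n`-per-axis grid, one row per grid point. Points where the field is
#' singular (e.g. the Gower term on the `i = 0` axis) get `NA` velocities.
#'
#' @param rhs vector field `function(t, x)`.
#' @param lower,upper box limits (length 1 or 2).
#' @param n grid points per axis (default 20).
#' @return data.frame with the grid coordinates followed by one velocity
#'   column per coordinate (`d<coord>`).
#' @examples
#' p <- stage_scenario("early")
#' head(phase_field(leslie_field(p), c(0.5, 0.5), c(10, 10), n = 5))
#' @export
phase_field <- function(rhs, lower, upper, n = 20) {
  if (length(lower) != length(upper) || n < 2) {
    stop("invalid grid specification", call. = FALSE)
  }
  axes <- mapply(function(lo, hi) seq(lo, hi, length.out = n),
                 lower, upper, SIMPLIFY = FALSE)
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- paste0("x", seq_along(axes))
  vel <- t(apply(grid, 1, function(pt) {
    tryCatch(as.numeric(rhs(0, as.numeric(pt))),
             error = function(e) rep(NA_real_, length(pt)))
  }))
  if (length(lower) == 1) vel <- matrix(vel, ncol = 1)
  colnames(vel) <- paste0("d", names(grid))
  cbind(grid, as.data.frame(vel))
}

#' Read a model configuration file
#'
#' JSON (`.json`) or YAML (`.yaml` / `.yml`) parameter files, returned as
#' a nested list. Recognised blocks include `hawk_dove` (keys `a`, `b`),
#' `leslie` (keys `r1`, `r2`, `c1`, `c2`, `b`, `k`, `c` or a `stage`
#' preset name) and `coalition` (keys `a1`, `a2`, `b1`, `b2`).
#'
#' @param path configuration file path.
#' @return nested list.
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: ", ext, " (use JSON or YAML)",
         call. = FALSE)
  }
}

#' Run manifest for reproducible outputs
#'
#' A small JSON record written alongside every command-line output:
#' command, model, scenario, seed, configuration (verbatim plus an MD5
#' digest), output paths, package version and timestamp. Re-running a
#' deterministic command with the same manifest reproduces its outputs
#' bit-for-bit.
#'
#' @param command subcommand name.
#' @param model model name.
#' @param scenario scenario/stage identifier (or `NULL`).
#' @param config configuration list (serialized verbatim).
#' @param seed integer seed or `NULL` for deterministic runs.
#' @param outputs character vector of output paths.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(command, model, scenario = NULL, config = list(),
                         seed = NULL, outputs = character()) {
  structure(list(command = command,
                 model = model,
                 scenario = scenario,
                 config = config,
                 config_hash = config_digest(config),
                 seed = seed,
                 outputs = outputs,
                 package_version = as.character(packageVersion("leukegame")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output file path.
#' @export
write_manifest <- function(manifest, path) {
  writeLines(jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE,
                              digits = NA, null = "null", pretty = TRUE),
             path)
  invisible(path)
}

config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}
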