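# File formats: probe config (YAML/JSON), measurement and calibration-session
# CSV, matrix / calibration / decomposition JSON, and run manifests.
# All CSV is comma-separated UTF-8 with a mandatory header and dot decimals;
# angles are serialized in degrees everywhere; matrices are row-major.

#' Read a probe configuration file
#'
#' YAML (`.yaml`/`.yml`) or JSON (`.json`), with the keys accepted by
#' [build_probe()]; unknown keys are rejected.
#'
#' @param path Path to the configuration file.
#' @return A `probe_model`.
#' @export
read_probe_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  config <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext)
  )
  build_probe(as.list(config))
}

#' Write a measurement set as CSV
#'
#' Two columns `pair,intensity`, nine rows in the canonical pair order.
#'
#' @param meas Named intensity vector (see [simulate_measurement_set()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_measurement_set <- function(meas, path) {
  meas <- unlist(meas)
  if (is.null(names(meas)) || !setequal(names(meas), pair_labels())) {
    stop("measurement set must cover exactly the nine scheme pairs")
  }
  df <- data.frame(pair = pair_labels(),
                   intensity = unname(meas[pair_labels()]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement set from CSV
#'
#' @param path CSV with header `pair,intensity` and exactly the nine scheme
#'   pairs.
#' @return Named intensity vector in canonical pair order.
#' @export
read_measurement_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pair", "intensity") %in% names(df))) {
    stop("measurement CSV must have header `pair,intensity`")
  }
  missing <- setdiff(pair_labels(), df$pair)
  if (length(missing) > 0) {
    stop("measurement CSV is missing pair(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(df$pair, pair_labels())
  if (length(extra) > 0 || anyDuplicated(df$pair)) {
    stop("measurement CSV must contain each of the nine pairs exactly once")
  }
  stats::setNames(df$intensity, df$pair)[pair_labels()]
}

#' Write / read a calibration session CSV
#'
#' Header `angle_deg,pair,intensity`; one row per angle and pair (27 rows for
#' the default three-angle session).
#'
#' @param session Data frame from [simulate_calibration_session()].
#' @param path CSV path.
#' @return `write_calibration_session()`: the path, invisibly;
#'   `read_calibration_session()`: the validated session data frame.
#' @export
write_calibration_session <- function(session, path) {
  stopifnot(all(c("angle_deg", "pair", "intensity") %in% names(session)))
  utils::write.csv(session[, c("angle_deg", "pair", "intensity")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration_session
#' @export
read_calibration_session <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("angle_deg", "pair", "intensity") %in% names(df))) {
    stop("session CSV must have header `angle_deg,pair,intensity`")
  }
  .validate_session(df)
  df
}

#' Write a reconstruction (or plain matrix) as JSON
#'
#' Stores both the raw and m11-normalized matrices as row-major nested
#' arrays, plus row/column ordering metadata.
#'
#' @param x A `reconstruction` or a plain 3x3 matrix.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_matrix_json <- function(x, path) {
  if (inherits(x, "reconstruction")) {
    m <- x$m
    mn <- x$m_normalized
    residual <- x$residual
  } else {
    .check_mueller(x, 3L, "x")
    m <- x
    mn <- if (m[1, 1] != 0) m / m[1, 1] else m
    residual <- NULL
  }
  payload <- list(
    m = apply(m, 1, identity, simplify = FALSE),
    m_normalized = apply(mn, 1, identity, simplify = FALSE),
    normalized = FALSE,
    element_order = "row-major m11..m33",
    residual = residual
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a matrix JSON written by [write_matrix_json()]
#'
#' @param path JSON path.
#' @param normalized Return the m11-normalized matrix instead of the raw one.
#' @return 3x3 matrix.
#' @export
read_matrix_json <- function(path, normalized = FALSE) {
  payload <- jsonlite::fromJSON(path)
  m <- if (normalized) payload$m_normalized else payload$m
  m <- as.matrix(m)
  .check_mueller(m, 3L, "matrix JSON payload")
  dimnames(m) <- NULL
  m
}

#' Write / read calibration coefficients as JSON
#'
#' @param result A `calibration_result`.
#' @param path JSON path.
#' @return `write_calibration_json()`: the path, invisibly;
#'   `read_calibration_json()`: a `calibration_result`.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  payload <- list(c = as.list(result$c), gauge = result$gauge,
                  objective_value = result$objective_value,
                  converged = result$converged,
                  pair_order = pair_labels())
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  payload <- jsonlite::fromJSON(path)
  cc <- unlist(payload$c)
  if (!setequal(names(cc), pair_labels())) {
    stop("calibration JSON must name all nine pairs")
  }
  structure(list(c = cc[pair_labels()], gauge = payload$gauge,
                 objective_value = payload$objective_value,
                 converged = payload$converged),
            class = "calibration_result")
}

#' Write a decomposition result as JSON
#'
#' @param decomp A `decomposition`.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_decomposition_json <- function(decomp, path) {
  stopifnot(inherits(decomp, "decomposition"))
  payload <- list(
    delta_meas_deg = decomp$delta_meas_deg,
    delta_phys_deg = decomp$delta_phys_deg,
    axis_deg = decomp$axis_deg,
    axis_ambiguous = decomp$axis_ambiguous,
    depolarisation_pct = decomp$depolarisation_pct,
    diattenuation = decomp$diattenuation,
    factors = lapply(decomp$factors,
                     function(f) apply(f, 1, identity, simplify = FALSE))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# One manifest per CLI run: enough metadata to reproduce the outputs.
.write_manifest <- function(out, command, args, seed = NULL,
                            config_path = NULL) {
  payload <- list(
    command = command,
    args = as.list(args),
    seed = seed,
    config_md5 = if (!is.null(config_path) && file.exists(config_path)) {
      unname(tools::md5sum(config_path))
    },
    package_version = as.character(utils::packageVersion("muellerprobe")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- paste0(out, ".manifest.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
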