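# Shared table I/O: profile and curve CSVs with an explicit units header,
# strict schema validation, and YAML run configuration.
#
# Every CSV written here starts with a comment line "# units: <col>=<unit>,
# ..." so that files are self-describing; readers reject files without it.

.write_units_csv <- function(df, path, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ",
                    paste(names(units), units, sep = "=", collapse = ", ")),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_units_csv <- function(path, required) {
  first <- readLines(path, n = 1)
  if (!grepl("^# units:", first)) {
    stop("missing '# units:' header in ", path)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema violation in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("unknown column(s) preserved: ", paste(extra, collapse = ", "))
  }
  df
}

#' Write a per-residue profile as CSV
#'
#' Generic writer for profile-shaped results (rate, free-energy,
#' occupancy, packing, fluctuation profiles): any data.frame with a
#' \code{residue_number} column.  Rows are ordered by residue number so
#' output is bit-stable.
#'
#' @param profile data.frame with a \code{residue_number} column.
#' @param path Output CSV path.
#' @param units Named character vector mapping columns to units.
#' @export
write_profile_csv <- function(profile, path, units = NULL) {
  stopifnot("residue_number" %in% names(profile))
  df <- as.data.frame(profile)
  df <- df[order(df$residue_number), , drop = FALSE]
  if (is.null(units)) {
    units <- stats::setNames(rep("-", ncol(df)), names(df))
  }
  .write_units_csv(df, path, units)
}

#' Read a per-residue profile CSV
#'
#' @param path CSV path written by \code{\link{write_profile_csv}}.
#' @param required Columns that must be present.
#' @return data.frame.
#' @export
read_profile_csv <- function(path, required = "residue_number") {
  .read_units_csv(path, required)
}

#' Write / read an overall exchange curve
#'
#' @param curve \code{overall_exchange_curve}.
#' @param path CSV path.
#' @export
write_overall_curve <- function(curve, path) {
  .write_units_csv(as.data.frame(curve), path,
                   c(time_min = "min", mean_D = "deuterons",
                     sem = "deuterons", n = "count"))
}

#' @rdname write_overall_curve
#' @export
read_overall_curve <- function(path) {
  df <- .read_units_csv(path, c("time_min", "mean_D", "sem", "n"))
  overall_exchange_curve(df$time_min, df$mean_D, df$sem, df$n)
}

#' Write / read an ETD fragment table
#'
#' @param fragments data.frame with columns \code{ion_type},
#'   \code{fragment_length}, \code{replicate}, \code{time_min},
#'   \code{deuterons}.
#' @param path CSV path.
#' @export
write_fragments <- function(fragments, path) {
  need <- c("ion_type", "fragment_length", "replicate", "time_min",
            "deuterons")
  stopifnot(all(need %in% names(fragments)))
  df <- fragments[do.call(order, fragments[need[1:4]]), need]
  .write_units_csv(df, path,
                   c(ion_type = "c|z", fragment_length = "residues",
                     replicate = "id", time_min = "min",
                     deuterons = "count"))
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  .read_units_csv(path, c("ion_type", "fragment_length", "replicate",
                          "time_min", "deuterons"))
}

#' Run configuration
#'
#' Reads a declarative YAML document of analysis parameters, filling in
#' defaults for missing keys.  \code{write_run_config} echoes the
#' configuration used into an output directory so every analysis is
#' reproducible from config + inputs + seed.
#'
#' @param path YAML file (NULL = defaults only).
#' @return Named list of class \code{run_config}.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    pH = 5.0, temperature = 293.15, direction = "DHX",
    residual_label_fraction = 0.05,
    hbond_dist_nm = 0.26, hbond_angle_deg = 60,
    packing_r_on = 0.35, packing_r_off = 0.50,
    block_ns = 30, n_boot = 10000,
    segments = list(tm_n = c(31, 35), tm_c = c(47, 51)),
    fma_window = c(44, 47), fma_components = 6,
    seed = 1)
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) {
      warning("unknown config key(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname read_run_config
#' @param config \code{run_config} to echo.
#' @param out_dir Directory receiving \code{config_used.yaml}.
#' @export
write_run_config <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_used.yaml"))
  invisible(file.path(out_dir, "config_used.yaml"))
}
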