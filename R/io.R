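## Tabular / JSON writers, parameter configs and run manifests.

#' Write a trajectory as CSV
#'
#' Columns `t,x,y,z,I`, `t` in integer time steps from the first recorded
#' state; reals carry 17 significant digits so the file parses back
#' losslessly.
#'
#' @param traj a `ktz_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  d <- as.data.frame(traj)
  num <- vapply(d, is.double, logical(1))
  d[num] <- lapply(d[num], function(v) sprintf("%.17g", v))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a parameter set as flat JSON
#'
#' The config dialect is flat JSON with keys exactly
#' `K, T, H, delta, lambda, xR, gain`.
#'
#' @param params a [ktz_params()].
#' @param path file path.
#' @return `write_params`: `path` invisibly; `read_params`: a
#'   [ktz_params()].
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  ktz_params(K = v$K, T = v$T, H = v$H %||% 0, delta = v$delta %||% 0,
             lambda = v$lambda %||% 0, xR = v$xR %||% 0,
             gain = v$gain %||% "logistic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run manifest
#'
#' Every CLI artifact is accompanied by a manifest recording the command,
#' the full configuration (parameters, thresholds, seeds), the package
#' version, the output files and the wall time, so any artifact can be
#' regenerated from its manifest alone (bit-identically, wall time aside).
#'
#' @param command the subcommand run.
#' @param config a named list of every setting used.
#' @param outputs character vector of files written.
#' @param wall_time elapsed seconds.
#' @return A list of class `ktz_manifest`.
#' @export
run_manifest <- function(command, config, outputs, wall_time = NA_real_) {
  structure(list(command = command,
                 config = config,
                 package_version =
                   as.character(utils::packageVersion("ktzlog")),
                 outputs = outputs,
                 wall_time_s = wall_time),
            class = "ktz_manifest")
}

#' @rdname run_manifest
#' @param manifest a `ktz_manifest`.
#' @param path output JSON file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
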