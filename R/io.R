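# Serialization: bank configs (YAML), CSV exports with JSON sidecars.

#' Write and read bank configurations
#'
#' A bank serialises to a flat YAML mapping (natural frequencies, gamma,
#' per-link coupling, f0, forcing mask), round-tripping exactly.
#'
#' @param bank a [reed_bank()].
#' @param path file path.
#' @return `read_bank_config()` returns a [reed_bank()];
#'   `write_bank_config()` returns `path` invisibly.
#' @export
write_bank_config <- function(bank, path) {
  stopifnot(inherits(bank, "reed_bank"))
  yaml::write_yaml(list(n = bank$n,
                        natural_freq_hz = bank$natural_freq_hz,
                        gamma = bank$gamma,
                        coupling = bank$coupling,
                        f0 = bank$f0,
                        forcing_mask = bank$forcing_mask),
                   path, precision = 17)
  invisible(path)
}

#' @rdname write_bank_config
#' @export
read_bank_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  reed_bank(cfg$natural_freq_hz, gamma = cfg$gamma, coupling = cfg$coupling,
            f0 = cfg$f0, forcing_mask = cfg$forcing_mask)
}

#' Export package objects as CSV
#'
#' Tidy CSV writers for the main result objects.  `write_result_csv()`
#' dispatches on class via [as.data.frame()]: banks export as
#' `(index, natural_freq_hz, kappa_left, kappa_right, forcing_mask)`,
#' trajectories in long format `(time_s, reed_index, displacement)`,
#' profiles and phasor responses per reed.  When `sidecar = TRUE` a JSON
#' sidecar `<path>.json` records the analysis parameters in `meta`.
#'
#' @param x a package object with an [as.data.frame()] method.
#' @param path output CSV path.
#' @param meta optional named list written to a JSON sidecar.
#' @param sidecar write the sidecar?
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path, meta = NULL, sidecar = !is.null(meta)) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  if (sidecar)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
as.data.frame.response_map <- function(x, ...) {
  df <- as.data.frame(x$amplitude)
  names(df) <- sprintf("reed_%03d", seq_along(x$natural_freq_hz))
  cbind(data.frame(drive_freq_hz = x$drive_freq_hz), df)
}

#' @export
as.data.frame.reed_spectrum <- function(x, ...) {
  n <- nrow(x$magnitude)
  data.frame(reed_index = rep(seq_len(n), each = ncol(x$magnitude)),
             freq_hz = rep(x$freq_hz, times = n),
             magnitude = as.vector(t(x$magnitude)))
}

#' @export
as.data.frame.plateau_map <- function(x, ...) {
  data.frame(reed_index = seq_along(x$dominant_hz),
             natural_freq_hz = x$natural_freq_hz,
             dominant_hz = x$dominant_hz)
}
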