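# Column dictionary for observation tables. `required` columns must be
# present; `known` columns are validated when present; anything else is
# warned about and passed through.
OBS_REQUIRED <- c("tree_id", "provenance", "treatment", "day")
OBS_KNOWN <- c(OBS_REQUIRED, "days_since_start", "time", "measure_order",
               "t_canopy", "t_wet", "t_dry", "cwsi", "ig", "pswd",
               "air_temp", "rh", "radiation", "vpd", "height", "diameter")

validate_observations <- function(obs) {
  check_columns(obs, OBS_REQUIRED)
  unknown <- setdiff(names(obs), OBS_KNOWN)
  if (length(unknown))
    warning("unknown observation column(s) passed through: ",
            paste(unknown, collapse = ", "))
  if ("rh" %in% names(obs)) {
    bad <- which(!is.na(obs$rh) & (obs$rh <= 0 | obs$rh > 100))
    if (length(bad))
      stop("relative humidity outside (0, 100] in row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  if (all(c("t_wet", "t_dry") %in% names(obs))) {
    bad <- which(!is.na(obs$t_wet) & !is.na(obs$t_dry) &
                   obs$t_wet >= obs$t_dry)
    if (length(bad))
      stop("wet reference not below dry reference in row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  invisible(obs)
}

#' Read and write observation tables
#'
#' CSV (UTF-8, "." decimal regardless of locale) with one row per tree and
#' measuring day. Required columns: `tree_id`, `provenance`, `treatment`,
#' `day`; recognised optional columns include the region temperatures
#' (`t_canopy`, `t_wet`, `t_dry`), the indices (`cwsi`, `ig`), `pswd`,
#' the meteorology (`air_temp`, `rh`, `radiation`, `vpd`) and the seedling
#' dimensions. Validation errors name the offending column or row; unknown
#' columns are warned about and preserved. Write-then-read is the identity
#' for finite values.
#'
#' @param path CSV file path.
#' @param obs observation data.frame.
#' @return `read_observations()`: validated data.frame.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_observations(obs)
  obs
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  validate_observations(obs)
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
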