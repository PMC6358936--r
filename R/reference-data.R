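#' Bundled reference study summary
#'
#' A published per-participant summary from a driving-simulator study with
#' a steering-wheel gyroscope: 15 participants, urban and interurban
#' scenario classes, with traffic offences per second and the mean and
#' standard deviation of the steering angular speed (deg/s). Rows are
#' stored in decreasing order of the offence rate within each scenario
#' class, which makes the table a convenient ordering fixture for the
#' offence-rate normalisation.
#'
#' @param scenario_class Optional filter, `"urban"` or `"interurban"`.
#' @return Data frame with columns `scenario_class`, `participant`,
#'   `offences_per_s`, `mean_angular_speed`, `sd_angular_speed`.
#' @export
#' @examples
#' head(reference_study_summary("urban"))
reference_study_summary <- function(scenario_class = NULL) {
  path <- system.file("extdata", "reference_study_summary.csv",
                      package = "drivesense", mustWork = TRUE)
  df <- read_table_file(path, c("scenario_class", "participant",
                                "offences_per_s", "mean_angular_speed",
                                "sd_angular_speed"))
  df$scenario_class <- as.character(df$scenario_class)
  df$participant <- as.integer(df$participant)
  if (!is.null(scenario_class)) {
    df <- df[df$scenario_class == scenario_class, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
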