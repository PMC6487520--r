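## Bundled trial tables from the two germination studies, for worked
## examples and score-arithmetic checks.

#' Pea study trial table
#'
#' The 33 explored conditions of the pea study: four daily temperatures
#' `t1..t4` (degC), three daily water amounts `w1..w3` (ml), and the
#' observed target score. The starting expert condition is row 1
#' (y = 0.73); the best condition is row 20 (y = 1.13, from 80 germinated
#' + 33 well-germinated of 100 seeds). A few water entries are a
#' best-effort reconstruction from a typographically damaged source table;
#' the scores and the marked rows are exact.
#'
#' @return data.frame with columns `t1..t4`, `w1..w3`, `target`.
#' @export
peaTrials <- function() {
  utils::read.csv(system.file("extdata", "pea_trials.csv",
                              package = "germBO"))
}

#' Radish study trial table
#'
#' The 11 explored temperature schedules of the radish study (`t1..t4`,
#' degC) with the mean and standard deviation of the target score over 6
#' repeated runs of 96 seeds. Rows 1-4 are the constant-temperature
#' initialization trials (21-24 degC); row 9 is the best schedule
#' (mean 1.903).
#'
#' @return data.frame with columns `t1..t4`, `mean`, `sd`.
#' @export
radishTrials <- function() {
  utils::read.csv(system.file("extdata", "radish_trials.csv",
                              package = "germBO"))
}
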