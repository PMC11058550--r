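#' Clinical evaluation fixtures
#'
#' Per-participant outcome tables from the 4-week proof-of-concept
#' evaluation of the device, bundled as plain CSV:
#' \describe{
#'   \item{`"sessions"`}{completed training sessions per participant and
#'     week (8 program completers, 6 prescribed sessions/week).}
#'   \item{`"success"`}{baseline and post-training tongue/lip success
#'     rates (percent).}
#'   \item{`"ahi"`}{pre/post apnea-hypopnea index (events/h).}
#' }
#' These printed per-participant values are the acceptance inputs for the
#' compliance and outcome analytics.
#'
#' @param name which table to load.
#' @return a data.frame.
#' @examples
#' compute_compliance(rowSums(study_fixture("sessions")[, -1]))
#' @export
study_fixture <- function(name = c("sessions", "success", "ahi")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("study_", name, ".csv"),
                      package = "myotrain", mustWork = TRUE)
  utils::read.csv(path)
}
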