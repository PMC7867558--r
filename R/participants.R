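#' Participant characteristics of the motivating tailored-tACS trial
#'
#' The published demographic and tailoring table of the 15 fibromyalgia
#' participants who completed the first arm of the motivating crossover
#' trial: age, sex, education, the prevailing EEG rhythm identified from
#' the baseline z-map, the stimulation site and the assigned stimulation
#' frequency. Used as a worked example for the frequency decision rule and
#' the demographic summaries.
#'
#' @return Data frame with columns `subject`, `age_years`, `sex`,
#'   `education_years`, `prevailing_band`, `site`, `stim_frequency_hz`.
#' @export
#' @examples
#' p <- trial_participants()
#' mean(p$age_years)
trial_participants <- function() {
  path <- system.file("extdata", "trial_participants.csv",
                      package = "tacstailor", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Apply the stimulation-frequency decision rule to a participant table
#'
#' Classifies each prevailing band as slow- or fast-excess and derives the
#' stimulation frequency (30 Hz for slow, 4 Hz for fast).
#'
#' @param participants Data frame with a `prevailing_band` column (default:
#'   [trial_participants()]).
#' @return The input with added columns `band_class` and
#'   `derived_frequency_hz`.
#' @export
#' @examples
#' tab <- tailoring_table()
#' table(tab$band_class)
tailoring_table <- function(participants = trial_participants()) {
  cls <- band_class(participants$prevailing_band)
  participants$band_class <- paste0(cls, "-excess")
  participants$derived_frequency_hz <- ifelse(cls == "slow", 30, 4)
  participants
}

#' Enrolment flow of a trial from stage-wise loss counts
#'
#' Computes the number of participants remaining after each attrition
#' stage. Defaults reproduce the motivating trial's flow: 24 recruited, 7
#' excluded at screening, 2 lost during the first arm, 4 lost during the
#' second arm, leaving 15 first-arm and 11 both-arm completers.
#'
#' @param recruited Number recruited.
#' @param excluded Excluded at eligibility screening.
#' @param lost_first_arm Lost between enrolment and first-arm completion.
#' @param lost_second_arm Lost between arms or during the second arm.
#' @return Data frame with columns `stage` and `n`.
#' @export
#' @examples
#' enrollment_flow()
enrollment_flow <- function(recruited = 24, excluded = 7,
                            lost_first_arm = 2, lost_second_arm = 4) {
  entered <- recruited - excluded
  first <- entered - lost_first_arm
  both <- first - lost_second_arm
  if (both < 0) stop("loss counts exceed recruitment", call. = FALSE)
  data.frame(
    stage = c("recruited", "eligible", "completed_first_arm",
              "completed_both_arms"),
    n = c(recruited, entered, first, both),
    stringsAsFactors = FALSE
  )
}
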