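#' Auditory Verbal Comprehension composite score
#'
#' The WAB-R Auditory Verbal Comprehension (AVC) composite is a 0-10 weighted
#' scale: the total of the three comprehension subtests (Yes/No Questions,
#' 0-60; Auditory Word Recognition, 0-60; Sequential Commands, 0-80; together
#' out of 200 points) divided by 20.
#'
#' @param yes_no Yes/No Questions subtest points, 0-60.
#' @param word_recognition Auditory Word Recognition subtest points, 0-60.
#' @param seq_commands Sequential Commands subtest points, 0-80.
#' @return AVC score on the 0-10 scale. Vectorized over its arguments.
#' @examples
#' avc_score(60, 60, 80)   # 10
#' avc_score(30, 40, 50)   # 6
#' @export
avc_score <- function(yes_no, word_recognition, seq_commands) {
  check_range <- function(x, lo, hi, what) {
    if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi)) {
      stop(sprintf("`%s` must be within [%g, %g]", what, lo, hi))
    }
  }
  check_range(yes_no, 0, 60, "yes_no")
  check_range(word_recognition, 0, 60, "word_recognition")
  check_range(seq_commands, 0, 80, "seq_commands")
  (yes_no + word_recognition + seq_commands) / 20
}

#' Spontaneous Speech composite score
#'
#' The WAB-R Spontaneous Speech composite (0-20) is the sum of the
#' Information Content and Fluency subscores, each rated on a 0-10 scale.
#'
#' @param info_content Information Content subscore, 0-10.
#' @param fluency Fluency subscore, 0-10.
#' @return Spontaneous Speech score on the 0-20 scale. Vectorized.
#' @examples
#' spontaneous_speech_score(7, 4)   # 11
#' @export
spontaneous_speech_score <- function(info_content, fluency) {
  if (!is.numeric(info_content) || anyNA(info_content) ||
      any(info_content < 0) || any(info_content > 10)) {
    stop("`info_content` must be within [0, 10]")
  }
  if (!is.numeric(fluency) || anyNA(fluency) ||
      any(fluency < 0) || any(fluency > 10)) {
    stop("`fluency` must be within [0, 10]")
  }
  info_content + fluency
}

#' Interquartile range from printed quartiles
#'
#' Convenience for cohort descriptor tables that print the first and third
#' quartiles: the interquartile range is their difference.
#'
#' @param q1 First quartile.
#' @param q3 Third quartile.
#' @return `q3 - q1`.
#' @export
iqr_from_quartiles <- function(q1, q3) {
  if (!is.numeric(q1) || !is.numeric(q3)) stop("quartiles must be numeric")
  if (any(q3 < q1)) stop("`q3` must be >= `q1`")
  q3 - q1
}
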