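# Grade values assigned to the five-letter annotator scale.
GRADE_VALUES <- c(A = 0.95, B = 0.85, C = 0.75, D = 0.6, F = 0)

#' Aggregate annotator letter grades into an AC/UN reference label
#'
#' Volunteer annotators grade each record A (outstanding) through F
#' (uninterpretable). Grades map to numeric scores (A = 0.95, B = 0.85,
#' C = 0.75, D = 0.6, F = 0) and are averaged. A record is Acceptable
#' (`"AC"`) when at least two grades are available, the average exceeds 0.7,
#' and at most one grade is F; otherwise it is Unacceptable (`"UN"`). An
#' average of exactly 0.7 resolves to UN (the conservative reading of the
#' strict "larger than 0.7" requirement). Records with fewer than two grades
#' are labeled UN with a message, since how such records should be labeled
#' is not defined by the grading protocol.
#'
#' @param grades character vector of letters from A, B, C, D, F (any case).
#' @return `"AC"` or `"UN"`.
#' @examples
#' aggregate_annotations(c("A", "B"))      # "AC"
#' aggregate_annotations(c("A", "A", "F", "F"))  # "UN": two F grades
#' @export
aggregate_annotations <- function(grades) {
  grades <- toupper(as.character(grades))
  bad <- setdiff(grades, names(GRADE_VALUES))
  if (length(bad))
    stop_input("aggregate_annotations: illegal grade(s): %s",
               paste(unique(bad), collapse = ", "))
  if (length(grades) < 2L) {
    message(sprintf("aggregate_annotations: only %d grade(s) available; labeling UN",
                    length(grades)))
    return("UN")
  }
  avg <- mean(GRADE_VALUES[grades])
  if (avg > 0.7 && sum(grades == "F") <= 1L) "AC" else "UN"
}
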