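## Outcome construction: composite burden, person-mean-centered binary
## labels, single-symptom labels, the three non-sensor features, and
## next-day target alignment.

#' Daily composite symptom burden
#'
#' Sums the ten 0-10 symptom ratings into a 0-100 composite per
#' participant-day.
#'
#' @param diary `data.table` with `participant_id`, `date`, and one
#'   column per symptom in [symptom_names()].
#' @return `data.table` with `participant_id`, `date`, `score`.
#' @export
composite_burden <- function(diary) {
  syms <- symptom_names()
  missing_cols <- setdiff(syms, names(diary))
  if (length(missing_cols)) stop("diary missing symptom column(s): ",
                                 paste(missing_cols, collapse = ", "))
  vals <- as.matrix(diary[, syms, with = FALSE])
  if (any(vals < 0 | vals > 10, na.rm = TRUE)) stop("symptom ratings must be in [0, 10]")
  data.table::data.table(participant_id = diary$participant_id,
                         date = diary$date, score = rowSums(vals))
}

#' Person-mean-centered high/low labels
#'
#' Each participant's mean score over their retained scored days is
#' subtracted from their daily scores; the residual is labeled high
#' (1) when strictly positive and average-or-below (0) otherwise, so a
#' tie at exactly the person mean is class 0.  "High" therefore means
#' higher than that individual's own typical level, not an absolute
#' severity.
#'
#' @param scores `data.table` with `participant_id`, `date`, `score`
#'   (already restricted to retained days).
#' @return The input with `person_mean` and integer `label` columns
#'   added.
#' @export
center_labels <- function(scores) {
  out <- data.table::copy(data.table::as.data.table(scores))
  if (nrow(out) == 0L) stop("need at least one scored day")
  out[, person_mean := mean(score), by = participant_id]
  out[, label := as.integer(score - person_mean > 0)]
  out[]
}

#' Single-symptom labels
#'
#' Applies the same person-mean centering to one symptom's 0-10 rating
#' instead of the 0-100 composite.
#'
#' @param diary Diary table as for [composite_burden()].
#' @param symptom One of `"pain"`, `"fatigue"`, `"bowel"`.
#' @return As [center_labels()], with `score` being the single rating.
#' @export
single_symptom_labels <- function(diary, symptom = c("pain", "fatigue", "bowel")) {
  symptom <- match.arg(symptom)
  scores <- data.table::data.table(participant_id = diary$participant_id,
                                   date = diary$date,
                                   score = as.numeric(diary[[symptom]]))
  center_labels(scores)
}

#' The three non-sensor context features
#'
#' For each requested participant-day: signed days since surgery, the
#' most recent observed score strictly before the day, and the running
#' mean of scores strictly before the day.  The two score features are
#' missing (NA) when no prior score exists; they are imputed downstream
#' like any other feature.
#'
#' @param scores `data.table` with `participant_id`, `date`, `score`.
#' @param meta Participant metadata with `participant_id`,
#'   `surgery_date`.
#' @param days `data.table` with `participant_id`, `date` rows to
#'   annotate (defaults to the scored days themselves).
#' @return `days` with `days_since_surgery`, `most_recent_score`,
#'   `running_mean_score` columns added.
#' @export
nonsensor_features <- function(scores, meta, days = NULL) {
  scores <- data.table::as.data.table(scores)
  if (is.null(days)) days <- scores[, .(participant_id, date)]
  out <- data.table::copy(data.table::as.data.table(days))
  surg <- setNames(meta$surgery_date, meta$participant_id)
  out[, days_since_surgery := as.numeric(date - surg[participant_id])]
  scores <- data.table::copy(scores)
  data.table::setorderv(scores, c("participant_id", "date"))
  out[, c("most_recent_score", "running_mean_score") := {
    s <- scores[participant_id == .BY[[1]]]
    ## number of scored days strictly before each requested date
    k <- findInterval(as.numeric(date) - 0.5, as.numeric(s$date))
    cum <- cumsum(s$score)
    list(ifelse(k > 0, s$score[pmax(k, 1)], NA_real_),
         ifelse(k > 0, cum[pmax(k, 1)] / k, NA_real_))
  }, by = participant_id]
  out[]
}

#' Pair day-t features with day-t+1 labels
#'
#' Sensor behavior on day t predicts the NEXT day's symptom class, so
#' each feature row is joined with the label of the calendar-consecutive
#' following day; rows whose next calendar day has no label are dropped
#' (no pairing across gaps).
#'
#' @param features `data.table` with `participant_id`, `date`, feature
#'   columns.
#' @param labels `data.table` with `participant_id`, `date`, `label`.
#' @return The feature rows that have a next-day label, with integer
#'   column `y` (the day-t+1 label) added.
#' @export
align_targets <- function(features, labels) {
  lab <- data.table::as.data.table(labels)[, .(participant_id, next_date = date, y = label)]
  out <- data.table::copy(data.table::as.data.table(features))
  out[, next_date := date + 1L]
  out <- merge(out, lab, by = c("participant_id", "next_date"))
  out[, next_date := NULL]
  data.table::setorderv(out, c("participant_id", "date"))
  out[]
}
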