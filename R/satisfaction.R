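# Length-of-stay -> satisfaction scoring. Experts (the department chief and
# senior nurses) gave, per patient type, optimistic / most-likely /
# pessimistic values of both the length of stay (minutes) and the matching
# satisfaction score (percent); each triple is read as a triangular
# distribution. A patient's LOS is standardized by the LOS triangle's mean
# and SD and mapped onto the score scale with the score triangle's mean and
# SD, in the negative direction (longer stays score lower), clamped to
# [0, 100].

#' Moments of a triangular distribution
#'
#' @param spec numeric triple `(a, m, b)` in any order consistent with a
#'   triangular distribution (sorted internally).
#' @return `tri_mean`: the mean `(a+m+b)/3`; `tri_sd`: the standard deviation
#'   `sqrt((a^2+m^2+b^2-am-ab-mb)/18)`.
#' @export
#' @examples
#' tri_mean(c(55, 90, 120)) # 88.33 min
#' tri_sd(c(50, 75, 100))   # ~10.21
tri_mean <- function(spec) {
  stopifnot(length(spec) == 3, is.numeric(spec))
  sum(spec) / 3
}

#' @rdname tri_mean
#' @export
tri_sd <- function(spec) {
  stopifnot(length(spec) == 3, is.numeric(spec))
  s <- sort(spec)
  a <- s[1]; m <- s[2]; b <- s[3]
  sqrt((a^2 + m^2 + b^2 - a * m - a * b - m * b) / 18)
}

#' Build a LOS-to-score mapping
#'
#' The default source, `"triangular_moments"`, takes the means and SDs from
#' the elicited triangles themselves. `"empirical"` accepts user-supplied
#' moments (e.g. observed LOS statistics) for the LOS side.
#'
#' @param profile a satisfaction profile: list with `los = c(opt, ml, pess)`
#'   minutes and `score = c(opt, ml, pess)` percent.
#' @param source `"triangular_moments"` or `"empirical"`.
#' @param mean_los,sd_los LOS moments, required when `source = "empirical"`.
#' @return a `score_mapping`: list with `mean_los`, `sd_los`, `mean_score`,
#'   `sd_score`, `source`.
#' @export
score_mapping <- function(profile, source = c("triangular_moments", "empirical"),
                          mean_los = NULL, sd_los = NULL) {
  source <- match.arg(source)
  if (source == "triangular_moments") {
    mean_los <- tri_mean(profile$los)
    sd_los <- tri_sd(profile$los)
  } else if (is.null(mean_los) || is.null(sd_los)) {
    stop("empirical mapping needs mean_los and sd_los", call. = FALSE)
  }
  mean_score <- tri_mean(profile$score)
  sd_score <- tri_sd(profile$score)
  if (sd_los <= 0 || sd_score <= 0) {
    stop("degenerate satisfaction profile: zero spread makes the ",
         "standardization undefined", call. = FALSE)
  }
  structure(list(mean_los = mean_los, sd_los = sd_los,
                 mean_score = mean_score, sd_score = sd_score,
                 source = source),
            class = "score_mapping")
}

#' Convert length of stay to a satisfaction score
#'
#' `score = clamp(mean_score - sd_score * (los - mean_los) / sd_los, 0, 100)`:
#' strictly decreasing in LOS between the clamps, so a longer stay never
#' scores higher.
#'
#' @param mapping a [score_mapping()].
#' @param los length(s) of stay, minutes (`>= 0`).
#' @return satisfaction score(s) in `[0, 100]` percent.
#' @export
#' @examples
#' m <- score_mapping(satisfaction_profiles_default()[["2"]])
#' los_to_score(m, 35)  # at the mean LOS: the mean score, 75
los_to_score <- function(mapping, los) {
  stopifnot(inherits(mapping, "score_mapping"), all(los >= 0))
  z <- (los - mapping$mean_los) / mapping$sd_los
  pmin(100, pmax(0, mapping$mean_score - mapping$sd_score * z))
}

#' Average satisfaction objective
#'
#' The satisfaction objective of a run: the arithmetic mean of the
#' per-patient scores.
#'
#' @param x a numeric vector of scores, or a `replication_record` with a
#'   `score` column (from [simulate_day()]).
#' @return mean satisfaction, percent.
#' @export
average_satisfaction <- function(x) {
  scores <- if (inherits(x, "replication_record")) x$patients$score else x
  if (is.null(scores) || length(scores) == 0) {
    stop("average_satisfaction: no scored patients", call. = FALSE)
  }
  mean(scores)
}
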