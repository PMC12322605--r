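# Purdue Pegboard eligibility screening and the demographic summary table.

#' Purdue Pegboard norm table
#'
#' Published average scores (pins placed in 30 s, mean and SD) by age band
#' and gender used as the eligibility benchmark: 20-29 years male 12.8 (2.9),
#' female 13.6 (0.9); 60 years and older male 7.9 (1.7), female 8.2 (1.8).
#'
#' @return Data frame with columns `age_band`, `gender`, `mean`, `sd`.
#' @export
ppt_norms <- function() {
  data.frame(age_band = c("20-29", "20-29", "60+", "60+"),
             gender = c("male", "female", "male", "female"),
             mean = c(12.8, 13.6, 7.9, 8.2),
             sd = c(2.9, 0.9, 1.7, 1.8))
}

.age_band <- function(group) ifelse(group == "young", "20-29", "60+")

#' Screen participants against pegboard norms
#'
#' Each participant's score is the mean of their available pegboard trials;
#' a participant is excluded when that score falls outside
#' `mean +/- k_sd * SD` of their age-band/gender norm cell (older adults,
#' 65-80, are screened against the "60+" band, the only band covering them).
#'
#' @param roster validated roster with `ppt_*` columns.
#' @param norms norm table as from [ppt_norms()].
#' @param k_sd half-width of the acceptance band in SD units (default 2).
#' @return List with `included` and `excluded` rosters; `excluded` carries a
#'   `reason` column. The two partition the input.
#' @export
screen_participants <- function(roster, norms = ppt_norms(), k_sd = 2) {
  roster <- validate_roster(roster)
  if (nrow(roster) == 0)
    return(list(included = roster,
                excluded = cbind(roster, reason = character(0))))
  ppt_cols <- grep("^ppt_[0-9]+$", names(roster), value = TRUE)
  if (!length(ppt_cols)) stop("roster has no ppt_* score columns")
  score <- rowMeans(roster[, ppt_cols, drop = FALSE], na.rm = TRUE)
  if (any(is.nan(score)))
    stop("participants without any pegboard score: ",
         paste(roster$participant_id[is.nan(score)], collapse = ", "))
  band <- .age_band(roster$group)
  idx <- match(paste(band, roster$gender),
               paste(norms$age_band, norms$gender))
  if (anyNA(idx))
    stop("config error: no norm cell for ",
         paste(unique(paste(band, roster$gender))[is.na(match(
           unique(paste(band, roster$gender)),
           paste(norms$age_band, norms$gender)))], collapse = "; "))
  lo <- norms$mean[idx] - k_sd * norms$sd[idx]
  hi <- norms$mean[idx] + k_sd * norms$sd[idx]
  out <- score < lo | score > hi
  excluded <- roster[out, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- sprintf(
      "pegboard score %.2f outside [%.2f, %.2f] (%s %s norm %.1f +/- %g SD)",
      score[out], lo[out], hi[out], band[out], roster$gender[out],
      norms$mean[idx][out], k_sd)
  else excluded$reason <- character(0)
  rownames(excluded) <- NULL
  included <- roster[!out, , drop = FALSE]
  rownames(included) <- NULL
  list(included = included, excluded = excluded)
}

#' Demographic summary by group
#'
#' Tabulates the roster the way cohort descriptions are reported: per-group n
#' as a percentage of the total sample, and within-group gender, education
#' and dominant-hand breakdowns (percent of the group), age mean (SD), and
#' mean pegboard score.
#'
#' @param roster validated roster.
#' @return List of data frames: `groups` (group, n, pct of total), `gender`,
#'   `education`, `dominant_hand` (group, level, n, pct of group), `age`
#'   (group, mean, sd), `ppt` (group, mean).
#' @export
demographic_summary <- function(roster) {
  roster <- validate_roster(roster)
  n_total <- nrow(roster)
  groups <- unique(roster$group)
  tab_groups <- do.call(rbind, lapply(groups, function(g) {
    n <- sum(roster$group == g)
    data.frame(group = g, n = n, pct = round(100 * n / n_total, 2))
  }))
  breakdown <- function(col) {
    do.call(rbind, lapply(groups, function(g) {
      sub <- roster[roster$group == g, ]
      t <- table(sub[[col]])
      data.frame(group = g, level = names(t), n = as.integer(t),
                 pct = round(100 * as.integer(t) / nrow(sub), 2))
    }))
  }
  age <- do.call(rbind, lapply(groups, function(g) {
    a <- roster$age[roster$group == g]
    data.frame(group = g, mean = round(mean(a), 2), sd = round(stats::sd(a), 2))
  }))
  ppt_cols <- grep("^ppt_[0-9]+$", names(roster), value = TRUE)
  ppt <- if (length(ppt_cols)) {
    s <- rowMeans(roster[, ppt_cols, drop = FALSE], na.rm = TRUE)
    do.call(rbind, lapply(groups, function(g)
      data.frame(group = g, mean = round(mean(s[roster$group == g]), 2))))
  } else NULL
  list(groups = tab_groups, gender = breakdown("gender"),
       education = breakdown("education"),
       dominant_hand = breakdown("dominant_hand"), age = age, ppt = ppt)
}
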