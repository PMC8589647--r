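#' Split controls into balanced train/test halves within sites
#'
#' Controls are split 50:50 within each site-by-sex cell, stratified over
#' age bins so both halves preserve the chronological age distribution;
#' all MDD participants are assigned to the test side. Sites contributing
#' fewer than `min_controls` controls of a given sex are excluded entirely
#' for that sex (train and test), reflecting the inclusion floor for
#' normative model training. When an age bin holds an odd number of
#' controls the extra participant alternates between train and test within
#' the site-by-sex cell, so the halves never differ by more than one.
#'
#' Assignments are deterministic given `seed` and invariant to the input
#' row order (rows are sorted by `participant_id` before sampling).
#'
#' @param cohort Cohort data.frame with `participant_id`, `site_id`,
#'   `sex`, `age`, `dx`.
#' @param seed Integer seed for within-stratum sampling.
#' @param bin_width_years Age-bin width in years used for stratification.
#' @param min_controls Per-sex site inclusion floor (default 10).
#' @return Data.frame with `participant_id`, `role` (`"train"`/`"test"`),
#'   and `stratum` (site x sex x age-bin label).
#' @export
split_controls <- function(cohort, seed = 1L, bin_width_years = 5,
                           min_controls = 10L) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  stopifnot(bin_width_years > 0)
  cohort <- cohort[order(cohort$participant_id), ]
  breaks <- seq(18, 75 + bin_width_years, by = bin_width_years)
  bin <- cut(pmin(pmax(cohort$age, 18), 75), breaks, right = FALSE,
             include.lowest = TRUE)
  cell <- interaction(cohort$site_id, cohort$sex, drop = TRUE)

  # per-sex inclusion floor on control counts
  keep_cell <- tapply(cohort$dx == "control", cell, sum) >= min_controls
  kept <- keep_cell[as.character(cell)]
  kept[is.na(kept)] <- FALSE
  if (!any(kept))
    stop(sprintf(
      "all sites excluded: every site x sex cell has fewer than %d controls",
      min_controls), call. = FALSE)

  out <- data.frame(participant_id = cohort$participant_id,
                    role = NA_character_,
                    stratum = paste(cohort$site_id, cohort$sex,
                                    as.character(bin), sep = ":"),
                    stringsAsFactors = FALSE)
  out$role[kept & cohort$dx == "MDD"] <- "test"

  with_seed(seed, {
    for (cl in levels(cell)[keep_cell]) {
      rows <- which(cell == cl & cohort$dx == "control")
      toggle <- TRUE  # first odd stratum sends its extra to train
      for (b in levels(droplevels(bin[rows]))) {
        idx <- rows[bin[rows] == b]
        idx <- idx[sample.int(length(idx))]
        k <- length(idx) %/% 2
        extra <- length(idx) %% 2
        n_train <- k + if (extra == 1 && toggle) 1L else 0L
        if (extra == 1) toggle <- !toggle
        out$role[idx[seq_len(n_train)]] <- "train"
        out$role[idx[setdiff(seq_along(idx), seq_len(n_train))]] <- "test"
      }
    }
  })
  out[!is.na(out$role), ]
}

#' Summarize a train/test assignment
#'
#' @param assignment Output of [split_controls()].
#' @param cohort The cohort the assignment was derived from.
#' @return Data.frame with one row per role x sex: participant counts by
#'   diagnosis, age mean/SD, and number of contributing sites.
#' @export
summarize_split <- function(assignment, cohort) {
  m <- merge(assignment, cohort, by = "participant_id")
  out <- list()
  for (role in c("train", "test")) {
    for (sex in c("male", "female")) {
      d <- m[m$role == role & m$sex == sex, ]
      if (nrow(d) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        role = role, sex = sex,
        n = nrow(d),
        n_control = sum(d$dx == "control"),
        n_mdd = sum(d$dx == "MDD"),
        age_mean = mean(d$age), age_sd = stats::sd(d$age),
        n_sites = length(unique(d$site_id)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
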