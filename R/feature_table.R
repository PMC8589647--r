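#' Average left and right hemisphere measures
#'
#' Collapses the 153 raw measures (76 left/right pairs plus unpaired ICV)
#' to the 77-feature analysis matrix by taking the arithmetic mean
#' (left + right) / 2 of each pair. Column order follows
#' [feature_registry()]. Input that is already averaged (no paired columns
#' remain) is returned unchanged up to column ordering, so the operation
#' is idempotent.
#'
#' @param raw Data.frame with `participant_id` and raw feature columns.
#' @return Data.frame with `participant_id` and 77 averaged feature
#'   columns.
#' @export
#' @examples
#' sim <- generate_cohort(sim_config(site_specs = default_site_specs(0.02)))
#' avg <- average_hemispheres(sim$features)
#' ncol(avg) - 1  # 77
average_hemispheres <- function(raw) {
  reg <- feature_registry()
  if (all(reg$feature %in% names(raw))) {
    return(raw[, c("participant_id", reg$feature)])
  }
  out <- data.frame(participant_id = raw$participant_id,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(reg))) {
    if (reg$modality[i] == "icv") {
      if (!"ICV" %in% names(raw))
        stop("schema error: missing column ICV", call. = FALSE)
      out[["ICV"]] <- raw[["ICV"]]
    } else {
      l <- reg$left[i]; r <- reg$right[i]
      miss <- setdiff(c(l, r), names(raw))
      if (length(miss))
        stop(sprintf("schema error: missing hemisphere column(s) %s for %s",
                     paste(miss, collapse = ", "), reg$feature[i]),
             call. = FALSE)
      out[[reg$feature[i]]] <- (raw[[l]] + raw[[r]]) / 2
    }
  }
  out
}

#' Flag and remove morphometric outliers
#'
#' Computes within-sex z-scores per feature; cells with |z| exceeding
#' `threshold_z` are set missing, and participants with any missing
#' feature are dropped (complete-case policy). Surviving values are never
#' altered. The default threshold of 6 SD removes only corrupt records in
#' clean data.
#'
#' @param features Averaged feature matrix (data.frame with
#'   `participant_id`).
#' @param sex Character vector aligned with `features` rows (`"male"` /
#'   `"female"`), used for within-sex standardization.
#' @param threshold_z Positive z threshold; `Inf` disables QC.
#' @return List with `features` (filtered matrix) and `report` (list with
#'   `n_in`, `n_dropped`, `dropped_ids`, and a data.frame `flags` of
#'   participant_id, feature, z).
#' @export
qc_outliers <- function(features, sex, threshold_z = 6) {
  if (!is.numeric(threshold_z) || length(threshold_z) != 1L ||
      is.na(threshold_z) || threshold_z <= 0)
    stop_config("threshold_z must be a positive number")
  stopifnot(length(sex) == nrow(features))
  cols <- setdiff(names(features), "participant_id")
  flags <- list()
  bad <- matrix(FALSE, nrow(features), length(cols),
                dimnames = list(NULL, cols))
  if (is.finite(threshold_z)) {
    for (s in unique(sex)) {
      rows <- which(sex == s)
      for (j in cols) {
        v <- features[[j]][rows]
        sdv <- stats::sd(v)
        if (!is.finite(sdv) || sdv == 0) next
        z <- (v - mean(v)) / sdv
        hit <- which(abs(z) > threshold_z)
        if (length(hit)) {
          bad[rows[hit], j] <- TRUE
          flags[[length(flags) + 1L]] <- data.frame(
            participant_id = features$participant_id[rows[hit]],
            feature = j, z = z[hit], stringsAsFactors = FALSE)
        }
      }
    }
  }
  drop <- rowSums(bad) > 0
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(participant_id = character(), feature = character(),
               z = numeric(), stringsAsFactors = FALSE)
  list(features = features[!drop, , drop = FALSE],
       report = list(n_in = nrow(features), n_dropped = sum(drop),
                     dropped_ids = features$participant_id[drop],
                     threshold_z = threshold_z, flags = flags))
}
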