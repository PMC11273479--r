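# Trawl-survey indices: CPUE by number and weight, average individual
# weight (AIW), seasonal summaries and environmental envelopes.

.sp_cols <- function(species) {
  list(count = paste0("count_", species),
       weight = paste0("weight_", species, "_g"))
}

.env_cols <- c("depth_m", "sst_c", "sbt_c", "sss_psu", "sbs_psu",
               "ssdo_mgl", "sbdo_mgl")

#' Catch per unit effort
#'
#' `CPUE_n = N_i / t_i` (ind/h) and `CPUE_w = W_i / t_i` (g/h) per station.
#'
#' @param records Station data.frame (station-CSV dialect).
#' @param species Species suffix, e.g. `"beka"`.
#' @return `records` with columns `cpue_n` and `cpue_w` appended.
#' @export
compute_cpue <- function(records, species) {
  cols <- .sp_cols(species)
  if (!all(unlist(cols) %in% names(records))) {
    stop(sprintf("no catch columns for species '%s'", species))
  }
  if (any(records$tow_hours <= 0)) stop("tow_hours must be positive")
  records$cpue_n <- records[[cols$count]] / records$tow_hours
  records$cpue_w <- records[[cols$weight]] / records$tow_hours
  records
}

#' Average individual weight
#'
#' Station-wise `AIW = CPUE_w / CPUE_n` (g/ind); because tow duration
#' cancels, this equals catch weight over catch count. Defined only at
#' collection stations (`CPUE_n > 0`).
#'
#' @param cpue_w,cpue_n Station CPUE by weight and number.
#' @return AIW in g/ind.
#' @export
compute_aiw <- function(cpue_w, cpue_n) {
  if (length(cpue_w) != length(cpue_n)) stop("inputs must have equal length")
  if (any(cpue_n <= 0)) {
    stop("AIW undefined where cpue_n is zero; restrict to collection stations")
  }
  cpue_w / cpue_n
}

.aiw_breaks <- c(0, 5, 10, 15, 20, Inf)
.aiw_labels <- c("0-5", "5-10", "10-15", "15-20", ">20")

#' Seasonal CPUE / AIW summary for one species
#'
#' Per season: mean CPUE (weight and number) over all stations and over
#' collection stations only (catch count > 0), CPUE ranges, mean and range
#' of station-wise AIW, and counts of collection stations in AIW bins
#' 0-5, 5-10, 10-15, 15-20, >20 g/ind (left-closed, right-open).
#'
#' @param records Station data.frame.
#' @param species Species suffix.
#' @return data.frame, one row per season in chronological order.
#' @export
seasonal_summary <- function(records, species) {
  if (nrow(records) < 1) stop("need at least one record")
  rec <- compute_cpue(records, species)
  seasons <- unique(rec$season[order(rec$date_index)])
  out <- lapply(seasons, function(s) {
    r <- rec[rec$season == s, ]
    coll <- r[r$cpue_n > 0, ]
    aiw <- if (nrow(coll)) compute_aiw(coll$cpue_w, coll$cpue_n) else numeric(0)
    bins <- table(cut(aiw, breaks = .aiw_breaks, labels = .aiw_labels,
                      right = FALSE))
    row <- data.frame(
      species = species, season = s,
      n_stations = nrow(r), n_collection = nrow(coll),
      mean_cpue_w_all = mean(r$cpue_w),
      mean_cpue_w_coll = if (nrow(coll)) mean(coll$cpue_w) else NA_real_,
      min_cpue_w = if (nrow(coll)) min(coll$cpue_w) else NA_real_,
      max_cpue_w = if (nrow(coll)) max(coll$cpue_w) else NA_real_,
      mean_cpue_n_all = mean(r$cpue_n),
      mean_cpue_n_coll = if (nrow(coll)) mean(coll$cpue_n) else NA_real_,
      min_cpue_n = if (nrow(coll)) min(coll$cpue_n) else NA_real_,
      max_cpue_n = if (nrow(coll)) max(coll$cpue_n) else NA_real_,
      mean_aiw = if (length(aiw)) mean(aiw) else NA_real_,
      min_aiw = if (length(aiw)) min(aiw) else NA_real_,
      max_aiw = if (length(aiw)) max(aiw) else NA_real_
    )
    for (i in seq_along(.aiw_labels)) {
      row[[paste0("aiw_bin_", gsub(">", "gt", .aiw_labels[i]))]] <-
        as.integer(bins[i])
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Environmental envelope at presence stations
#'
#' Seasonal min-max of each environmental covariate over the stations where
#' the species was caught. Covariates that are entirely missing in a season
#' (e.g. dissolved oxygen in a cruise without a DO record) are reported as
#' NA; seasons with no presence are flagged `absent`.
#'
#' @param records Station data.frame.
#' @param species Species suffix.
#' @return data.frame with one row per season x covariate.
#' @export
environmental_envelope <- function(records, species) {
  if (nrow(records) < 1) stop("need at least one record")
  cols <- .sp_cols(species)
  seasons <- unique(records$season[order(records$date_index)])
  out <- list()
  for (s in seasons) {
    r <- records[records$season == s & records[[cols$count]] > 0, ]
    for (cv in intersect(.env_cols, names(records))) {
      vals <- r[[cv]]
      vals <- vals[is.finite(vals)]
      out[[length(out) + 1]] <- data.frame(
        species = species, season = s, covariate = cv,
        absent = nrow(r) == 0,
        min = if (length(vals)) min(vals) else NA_real_,
        max = if (length(vals)) max(vals) else NA_real_
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
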