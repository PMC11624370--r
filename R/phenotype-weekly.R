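#' Weekly aggregation and editing of daily methane records
#'
#' Daily methane measurements (g/d) are averaged within ISO calendar week
#' per cow. Only first-lactation records are kept; weeks need at least
#' `min_daily` daily measurements; the week midpoint (median measurement
#' date) must fall within the days-in-milk window; and weekly means beyond
#' `sd_limit` standard deviations of the overall weekly-mean distribution
#' are removed in a single pass. The edit can instead be applied to daily
#' values before averaging via `sd_filter_on = "daily"`.
#'
#' @param daily tibble with columns `animal`, `date`, `ch4`, `dim`,
#'   `lactation`.
#' @param min_daily minimum daily measurements per retained week.
#' @param dim_window days-in-milk window for the week midpoint.
#' @param sd_limit standard-deviation edit threshold.
#' @param sd_filter_on apply the SD edit to `"weekly"` means (default) or
#'   `"daily"` values.
#' @return Tibble with `animal`, `week`, `ch4_weekly`, `n_daily`,
#'   `midpoint_date`, `dim_mid`.
#' @export
weekly_aggregate_and_edit <- function(daily, min_daily = 2,
                                      dim_window = c(5, 305),
                                      sd_limit = 3.5,
                                      sd_filter_on = c("weekly", "daily")) {
  sd_filter_on <- match.arg(sd_filter_on)
  d <- dplyr::filter(daily, .data$lactation == 1)
  if (sd_filter_on == "daily" && nrow(d) > 1) {
    mu <- mean(d$ch4); s <- stats::sd(d$ch4)
    if (s > 0) d <- dplyr::filter(d, abs(.data$ch4 - mu) <= sd_limit * s)
  }
  wk <- d |>
    dplyr::mutate(week = format(.data$date, "%G_W%V")) |>
    dplyr::group_by(.data$animal, .data$week) |>
    dplyr::summarise(
      ch4_weekly = mean(.data$ch4),
      n_daily = dplyr::n(),
      midpoint_date = stats::median(.data$date),
      dim_mid = stats::median(.data$dim),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_daily >= min_daily,
                  .data$dim_mid >= dim_window[1],
                  .data$dim_mid <= dim_window[2])
  if (sd_filter_on == "weekly" && nrow(wk) > 1) {
    mu <- mean(wk$ch4_weekly)
    s <- stats::sd(wk$ch4_weekly)
    if (s > 0) {
      wk <- dplyr::filter(wk, abs(.data$ch4_weekly - mu) <= sd_limit * s)
    }
  }
  wk
}

#' Match weekly methane phenotypes to milk MIR spectra
#'
#' Each weekly phenotype is matched to the same cow's spectrum closest in
#' date to the week midpoint; a record is left unmatched when the nearest
#' spectrum is more than `max_days` away. Ties go to the earlier spectrum
#' date.
#'
#' @param weekly tibble from [weekly_aggregate_and_edit()].
#' @param spectra_meta tibble with `animal`, `spectrum_id`, `date`.
#' @param max_days maximum allowed distance in days (default 11).
#' @return `weekly` with `spectrum_id` and `match_days` columns (`NA`
#'   when unmatched).
#' @export
match_weekly_to_spectrum <- function(weekly, spectra_meta, max_days = 11) {
  pick <- function(animal, midpoint) {
    sp <- spectra_meta[spectra_meta$animal == animal, ]
    if (nrow(sp) == 0) {
      return(tibble::tibble(spectrum_id = NA, match_days = NA_real_))
    }
    dist <- abs(as.numeric(sp$date - midpoint))
    best <- which(dist == min(dist))
    if (length(best) > 1) best <- best[which.min(sp$date[best])]
    if (min(dist) > max_days) {
      return(tibble::tibble(spectrum_id = NA, match_days = NA_real_))
    }
    tibble::tibble(spectrum_id = sp$spectrum_id[best],
                   match_days = dist[best])
  }
  matched <- purrr::map2_dfr(weekly$animal, weekly$midpoint_date, pick)
  dplyr::bind_cols(weekly, matched)
}
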