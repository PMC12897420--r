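#' Extract the antecedent flow window for a sampling event
#'
#' Returns the `w` daily flows immediately preceding (and excluding) the
#' sampling day, in chronological order.
#'
#' @param discharge A discharge data frame with columns `date` and
#'   `q_total` (e.g. from [simulate_discharge()]).
#' @param event_date Sampling date.
#' @param w Window length in days (>= 2).
#' @return Numeric vector of `w` flows for days `event_date - w` through
#'   `event_date - 1`.
#' @export
extract_window <- function(discharge, event_date, w) {
  stopifnot(w >= 2)
  event_date <- as.Date(event_date)
  dates <- as.Date(discharge$date)
  wanted <- event_date - seq.int(w, 1)
  idx <- match(wanted, dates)
  if (anyNA(idx)) {
    stop("event ", format(event_date), ": insufficient antecedent history (",
         sum(is.na(idx)), " of ", w, " days missing from the series)")
  }
  discharge$q_total[idx]
}

#' Antecedent-flow descriptors of one window
#'
#' Six descriptors of the flow history in a window of `w` daily flows: mean
#' discharge; the Richards-Baker flashiness index (sum of absolute
#' day-to-day changes divided by total flow, 0 for an all-zero window);
#' the number of day-to-day rises; and the cumulative magnitudes of rises,
#' falls (reported as a non-negative magnitude) and all absolute changes.
#' Day-to-day changes are taken between consecutive days inside the window
#' only, so there are `w - 1` of them; ties (zero change) count neither as
#' rises nor falls.
#'
#' @param window Numeric vector of `w >= 2` non-negative daily flows in
#'   chronological order.
#' @return A one-row data frame with columns `q_mean`, `rb`, `n_rise`,
#'   `sum_rise`, `sum_fall`, `sum_abs`. Identity: `sum_abs = sum_rise +
#'   sum_fall`; for non-negative flows `rb` lies in \[0, 2\].
#' @examples
#' flow_descriptors(c(1, 2, 1))
#' @export
flow_descriptors <- function(window) {
  if (length(window) < 2) stop("window must contain at least 2 flows")
  if (any(window < 0)) stop("negative flows in window")
  d <- diff(window)
  tot <- sum(window)
  data.frame(
    q_mean = mean(window),
    rb = if (tot > 0) sum(abs(d)) / tot else 0,
    n_rise = sum(d > 0),
    sum_rise = sum(d[d > 0]),
    sum_fall = abs(sum(d[d < 0])),
    sum_abs = sum(abs(d))
  )
}

#' Antecedent descriptors for every event and window
#'
#' Applies [extract_window()] and [flow_descriptors()] to each combination
#' of sampling event and antecedent window length.
#'
#' @param discharge Discharge data frame (`date`, `q_total`, ...).
#' @param event_dates Vector of sampling dates, each with at least
#'   `max(windows)` days of discharge history before it.
#' @param windows Integer vector of window lengths (default `c(3, 6, 9)`).
#' @return A data frame with one row per event x window:
#'   `event_date`, `window`, `q_mean`, `rb`, `n_rise`, `sum_rise`,
#'   `sum_fall`, `sum_abs`.
#' @export
descriptor_table <- function(discharge, event_dates, windows = c(3, 6, 9)) {
  stopifnot(length(windows) >= 1, all(windows >= 2))
  event_dates <- as.Date(event_dates)
  rows <- lapply(windows, function(w) {
    per_event <- lapply(event_dates, function(ed) {
      cbind(data.frame(event_date = ed, window = w),
            flow_descriptors(extract_window(discharge, ed, w)))
    })
    do.call(rbind, per_event)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
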