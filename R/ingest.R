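#' Read GPS fixes from a delimited file
#'
#' Expects columns `bird_id`, `timestamp` (ISO-8601, interpreted in a fixed
#' UTC offset; no daylight saving), `x_m`, `y_m` (planar metres). Rows
#' duplicated on (`bird_id`, `timestamp`) are collapsed to their first
#' occurrence with a warning, since a transmitter emits one fix per slot.
#'
#' @param path CSV file path.
#' @param tz_offset fixed UTC offset in hours for local time (default -8,
#'   i.e. Pacific Standard Time).
#' @return Tibble `bird_id`, `t` (POSIXct), `x_m`, `y_m`, ordered by bird and
#'   time.
#' @export
read_fixes <- function(path, tz_offset = -8) {
  if (!file.exists(path)) stop("fix file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("bird_id", "timestamp", "x_m", "y_m")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("fix file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tz <- sprintf("Etc/GMT%+d", -tz_offset)  # POSIX sign convention is inverted
  t <- as.POSIXct(raw$timestamp, tz = tz, format = "%Y-%m-%dT%H:%M:%S")
  t2 <- as.POSIXct(raw$timestamp, tz = tz, format = "%Y-%m-%d %H:%M:%S")
  t[is.na(t)] <- t2[is.na(t)]
  if (anyNA(t)) {
    stop("malformed timestamp at row(s): ",
         paste(utils::head(which(is.na(t)), 5), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(bird_id = as.character(raw$bird_id), t = t,
                        x_m = as.numeric(raw$x_m), y_m = as.numeric(raw$y_m))
  dup <- duplicated(out[, c("bird_id", "t")])
  if (any(dup)) {
    warning(sum(dup), " duplicated (bird_id, timestamp) fix(es) dropped; first kept")
    out <- out[!dup, ]
  }
  dplyr::arrange(out, .data$bird_id, .data$t)
}

#' Read a bird attribute table
#'
#' @param path CSV keyed by `bird_id` with columns `sex`, `age_class`,
#'   `breeder`, `release_site`, `rearing`. If an `age` column (years) is
#'   present and `age_class` is absent, birds of 6 years and older are
#'   classed `adult` and younger birds `immature` (breeding does not occur
#'   regularly before age 6).
#' @return Tibble of attributes, one row per bird.
#' @export
read_bird_attributes <- function(path) {
  if (!file.exists(path)) stop("attribute file not found: ", path, call. = FALSE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"age_class" %in% names(out) && "age" %in% names(out)) {
    out$age_class <- ifelse(out$age >= 6, "adult", "immature")
  }
  need <- c("bird_id", "sex", "age_class", "breeder", "release_site", "rearing")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop("attribute file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(out$bird_id)) stop("duplicate bird_id in attribute table", call. = FALSE)
  tibble::as_tibble(out)
}

#' Keep fixes inside the daytime duty-cycle window
#'
#' Retains fixes whose local clock time falls in `[start_hour, end_hour]`,
#' endpoints inclusive — the transmitter schedule names its first and last
#' hourly slots, so both boundary fixes are scheduled data.
#'
#' @param fixes tibble with a POSIXct column `t`.
#' @param start_hour,end_hour window bounds in local hours (defaults 5 and
#'   20, the 0500-2000 h duty cycle).
#' @return The filtered tibble.
#' @export
window_filter <- function(fixes, start_hour = 5, end_hour = 20) {
  if (nrow(fixes) == 0) return(fixes)
  lt <- as.POSIXlt(fixes$t)
  hr <- lt$hour + lt$min / 60 + lt$sec / 3600
  fixes[hr >= start_hour & hr <= end_hour, ]
}

#' Assemble bird-month panels with a minimum-sampling filter
#'
#' Groups fixes by bird and calendar month (local time) and retains panels
#' with at least `min_fixes` locations, the adequacy threshold for a monthly
#' utilization distribution.
#'
#' @param fixes tibble `bird_id`, `t`, `x_m`, `y_m` (already windowed).
#' @param min_fixes minimum locations per bird-month (default 100).
#' @return Tibble with one row per retained panel: `bird_id`, `year`,
#'   `month`, `n_fixes`, and a list-column `fixes` of per-panel fix tibbles.
#'   Dropped panel counts are reported via `message()`.
#' @export
build_panels <- function(fixes, min_fixes = 100) {
  if (nrow(fixes) == 0) {
    return(tibble::tibble(bird_id = character(), year = integer(),
                          month = integer(), n_fixes = integer(),
                          fixes = list()))
  }
  lt <- as.POSIXlt(fixes$t)
  fixes$year <- lt$year + 1900L
  fixes$month <- lt$mon + 1L
  panels <- fixes |>
    tidyr::nest(fixes = c("t", "x_m", "y_m")) |>
    dplyr::mutate(n_fixes = purrr::map_int(.data$fixes, nrow)) |>
    dplyr::select("bird_id", "year", "month", "n_fixes", "fixes") |>
    dplyr::arrange(.data$bird_id, .data$year, .data$month)
  dropped <- sum(panels$n_fixes < min_fixes)
  if (dropped > 0) {
    message(dropped, " bird-month panel(s) dropped below the ", min_fixes,
            "-fix minimum")
  }
  panels[panels$n_fixes >= min_fixes, ]
}
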