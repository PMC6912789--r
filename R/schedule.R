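#' Observation schedules
#'
#' Video observation after mixing runs in daytime blocks; the analysis clock
#' counts *cumulative observed hours* with the unobserved gaps removed, so
#' all rising time windows are indexed on that clock. The presets mirror the
#' study design for the three mixing events:
#' \itemize{
#'   \item `piglet`: day 1 12:00-18:00, day 2 07:00-18:00, day 3
#'     07:00-18:00 (28 observed hours);
#'   \item `fattener`, `gilt`: day 1 12:00-18:00, day 2 07:00-18:00
#'     (17 observed hours).
#' }
#'
#' @param profile `"piglet"`, `"fattener"` or `"gilt"`.
#' @return an `obs_schedule`: data.frame of blocks (`day`, `start`, `end`,
#'   clock hours) with attribute `total_hours`.
#' @examples
#' schedule_preset("piglet")
#' @export
schedule_preset <- function(profile) {
  blocks <- switch(profile,
    piglet = data.frame(day = 1:3, start = c(12, 7, 7), end = c(18, 18, 18)),
    fattener = ,
    gilt = data.frame(day = 1:2, start = c(12, 7), end = c(18, 18)),
    stop("unknown schedule profile: ", profile, call. = FALSE)
  )
  observation_schedule(blocks)
}

#' Build an observation schedule from explicit blocks
#'
#' @param blocks data.frame with columns `day` (integer), `start`, `end`
#'   (clock hours, `start < end`); blocks must be ordered and non-overlapping.
#' @return an `obs_schedule` object.
#' @export
observation_schedule <- function(blocks) {
  stopifnot(is.data.frame(blocks), all(c("day", "start", "end") %in% names(blocks)))
  if (any(blocks$end <= blocks$start))
    stop("each block needs start < end", call. = FALSE)
  key <- blocks$day * 24 + blocks$start
  if (is.unsorted(key, strictly = TRUE))
    stop("blocks must be ordered in time", call. = FALSE)
  prev_end <- blocks$day[-nrow(blocks)] * 24 + blocks$end[-nrow(blocks)]
  if (nrow(blocks) > 1 && any(key[-1] < prev_end))
    stop("blocks overlap", call. = FALSE)
  structure(blocks[, c("day", "start", "end")],
            total_hours = sum(blocks$end - blocks$start),
            class = c("obs_schedule", "data.frame"))
}

#' Total observed hours of a schedule
#' @param schedule an `obs_schedule`.
#' @return numeric scalar.
#' @export
total_hours <- function(schedule) attr(schedule, "total_hours")

#' Map cumulative observed hours to wall-clock time
#'
#' Strictly monotone and bijective on `[0, total_hours]`: the unobserved
#' gaps are skipped. An instant falling exactly on a block boundary is
#' reported as the end of the earlier block.
#'
#' @param schedule an `obs_schedule`.
#' @param t_obs cumulative observed hours, in `[0, total_hours]` (vectorised).
#' @return data.frame with columns `day` and `clock` (decimal clock hour).
#' @examples
#' obs_hour_to_wall_clock(schedule_preset("piglet"), c(1, 6, 7))
#' @export
obs_hour_to_wall_clock <- function(schedule, t_obs) {
  tot <- total_hours(schedule)
  if (any(t_obs < 0 | t_obs > tot))
    stop("t_obs outside [0, ", tot, "]", call. = FALSE)
  len <- schedule$end - schedule$start
  cum_end <- cumsum(len)
  cum_start <- cum_end - len
  out <- data.frame(day = integer(length(t_obs)), clock = numeric(length(t_obs)))
  for (i in seq_along(t_obs)) {
    t <- t_obs[i]
    # boundary instants belong to the earlier block
    k <- which(t <= cum_end)[1L]
    if (t == 0) k <- 1L
    out$day[i] <- schedule$day[k]
    out$clock[i] <- schedule$start[k] + (t - cum_start[k])
  }
  out
}

#' Map wall-clock time back to cumulative observed hours
#'
#' Inverse of [obs_hour_to_wall_clock()] on block interiors.
#'
#' @param schedule an `obs_schedule`.
#' @param day observation day index (vectorised).
#' @param clock decimal clock hour within that day's block.
#' @return numeric vector of cumulative observed hours.
#' @export
wall_clock_to_obs_hour <- function(schedule, day, clock) {
  len <- schedule$end - schedule$start
  cum_start <- cumsum(len) - len
  n <- max(length(day), length(clock))
  day <- rep_len(day, n); clock <- rep_len(clock, n)
  vapply(seq_len(n), function(i) {
    k <- which(schedule$day == day[i] &
               schedule$start <= clock[i] & clock[i] <= schedule$end)
    if (!length(k))
      stop("day ", day[i], " clock ", clock[i], " outside observation blocks",
           call. = FALSE)
    cum_start[k[1L]] + (clock[i] - schedule$start[k[1L]])
  }, numeric(1))
}
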