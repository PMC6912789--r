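#' Generator configuration for synthetic agonistic event logs
#'
#' The generator emulates the structure of post-mixing agonistic
#' interaction logs in group-housed pigs: a latent dominance score per
#' animal drives contest outcomes, fight intensity decays exponentially
#' after mixing, and a fraction of interactions end without a clear winner.
#'
#' Presets (group sizes, observation schedules and interaction-rate targets
#' match the three studied mixing events):
#' \itemize{
#'  \item `piglet`: ~9 animals/pen (6-11), 28 observed hours, 18.4
#'    interactions/animal;
#'  \item `fattener`: ~21 animals/pen (17-25), 17 h, 5.9 interactions/animal;
#'  \item `gilt`: ~21 animals/pen (16-27), 17 h, 5.3 interactions/animal.
#' }
#'
#' @param profile age-group preset: `"piglet"`, `"fattener"` or `"gilt"`.
#' @param n_pens number of pens to simulate.
#' @param n_per_pen fixed group size, or `NULL` to sample per pen from the
#'   preset's truncated-normal size distribution.
#' @param events_per_animal_target expected interactions per animal over the
#'   whole observation period, counting each interaction for both
#'   participants (so the expected number of events per pen is
#'   `n * target / 2`).
#' @param decay_tau e-folding time (hours) of the post-mixing decay in
#'   fight intensity.
#' @param alpha initiator-selection strength: an animal initiates with
#'   probability proportional to `exp(alpha * theta)`.
#' @param beta outcome discrimination: the initiator wins with probability
#'   `plogis(beta * (theta_init - theta_recv) + delta)`.
#' @param delta initiator advantage on the log-odds scale.
#' @param p_indecisive probability that an interaction ends without a clear
#'   winner/loser.
#' @param receiver_bias if nonzero, receivers are drawn with probability
#'   proportional to `exp(receiver_bias * theta)` instead of uniformly.
#' @param seed master seed; per-pen seeds are derived from it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(profile = "piglet",
                             n_pens = NULL,
                             n_per_pen = NULL,
                             events_per_animal_target = NULL,
                             decay_tau = 3,
                             alpha = 0.5,
                             beta = 2,
                             delta = 0.25,
                             p_indecisive = 0.1,
                             receiver_bias = 0,
                             seed = 1L) {
  presets <- list(
    piglet   = list(n_pens = 93L, size_mean = 8.9, size_sd = 0.6,
                    size_range = c(6L, 11L), target = 18.4),
    fattener = list(n_pens = 26L, size_mean = 20.9, size_sd = 1.7,
                    size_range = c(17L, 25L), target = 5.9),
    gilt     = list(n_pens = 12L, size_mean = 20.8, size_sd = 3.4,
                    size_range = c(16L, 27L), target = 5.3)
  )
  if (!profile %in% names(presets))
    stop("unknown profile: ", profile, call. = FALSE)
  p <- presets[[profile]]
  cfg <- list(
    profile = profile,
    n_pens = if (is.null(n_pens)) p$n_pens else as.integer(n_pens),
    n_per_pen = if (is.null(n_per_pen)) NULL else as.integer(n_per_pen),
    size_mean = p$size_mean, size_sd = p$size_sd, size_range = p$size_range,
    events_per_animal_target =
      if (is.null(events_per_animal_target)) p$target
      else events_per_animal_target,
    decay_tau = decay_tau, alpha = alpha, beta = beta, delta = delta,
    p_indecisive = p_indecisive, receiver_bias = receiver_bias,
    seed = as.integer(seed),
    schedule = schedule_preset(profile)
  )
  stopifnot(cfg$n_pens >= 0,
            is.null(cfg$n_per_pen) || cfg$n_per_pen >= 2,
            cfg$events_per_animal_target > 0, cfg$decay_tau > 0,
            cfg$p_indecisive >= 0, cfg$p_indecisive <= 1)
  class(cfg) <- "generator_config"
  cfg
}

# pen size from the preset's truncated rounded normal
sample_pen_size <- function(cfg) {
  if (!is.null(cfg$n_per_pen)) return(cfg$n_per_pen)
  repeat {
    n <- round(stats::rnorm(1, cfg$size_mean, cfg$size_sd))
    if (n >= cfg$size_range[1] && n <= cfg$size_range[2]) return(as.integer(n))
  }
}

#' Simulate one pen of agonistic interactions
#'
#' Latent dominance scores `theta_i` are i.i.d. standard normal. Event
#' times follow a non-homogeneous Poisson process on observed hours with
#' intensity `lambda0 * exp(-t / decay_tau)`, `lambda0` calibrated so the
#' expected event count is `n * events_per_animal_target / 2` (each event
#' involves two animals). For each event the initiator is drawn with
#' probability proportional to `exp(alpha * theta)`, the receiver uniformly
#' from the remaining pen mates, and the initiator wins with probability
#' `plogis(beta * (theta_init - theta_recv) + delta)`; with probability
#' `p_indecisive` the outcome is recorded as indecisive.
#'
#' @param cfg a [generator_config()].
#' @param pen_id pen identifier.
#' @param seed seed for this pen (defaults to the config seed).
#' @return list with `roster`, `truth` (data.frame `pen_id`, `animal_id`,
#'   `theta`) and `events` (chronological).
#' @export
simulate_pen <- function(cfg, pen_id = "P1", seed = cfg$seed) {
  set.seed(seed)
  n <- sample_pen_size(cfg)
  ids <- sprintf("%s_a%02d", pen_id, seq_len(n))
  roster <- pen_roster(pen_id, ids, cfg$profile)
  theta <- stats::rnorm(n)
  truth <- data.frame(pen_id = pen_id, animal_id = ids, theta = theta,
                      stringsAsFactors = FALSE)

  T_end <- total_hours(cfg$schedule)
  expected_events <- n * cfg$events_per_animal_target / 2
  n_events <- stats::rpois(1, expected_events)
  if (n_events == 0) {
    ev <- interaction_events(character(0), numeric(0), character(0),
                             character(0))
    return(list(roster = roster, truth = truth, events = ev))
  }
  # event times: inverse-CDF draws from the truncated exponential density
  u <- stats::runif(n_events)
  mass <- 1 - exp(-T_end / cfg$decay_tau)
  t_obs <- sort(-cfg$decay_tau * log(1 - u * mass))

  w_init <- exp(cfg$alpha * theta)
  init <- sample.int(n, n_events, replace = TRUE, prob = w_init)
  recv <- vapply(init, function(i) {
    others <- setdiff(seq_len(n), i)
    w <- if (cfg$receiver_bias != 0) exp(cfg$receiver_bias * theta[others])
         else NULL
    if (length(others) == 1L) others else sample(others, 1L, prob = w)
  }, integer(1))
  p_win <- stats::plogis(cfg$beta * (theta[init] - theta[recv]) + cfg$delta)
  init_wins <- stats::runif(n_events) < p_win
  indecisive <- stats::runif(n_events) < cfg$p_indecisive
  winner <- ifelse(indecisive, NA_character_,
                   ifelse(init_wins, ids[init], ids[recv]))
  loser <- ifelse(indecisive, NA_character_,
                  ifelse(init_wins, ids[recv], ids[init]))
  ev <- interaction_events(pen_id, t_obs, ids[init], ids[recv], winner, loser)
  list(roster = roster, truth = truth, events = ev)
}

#' Simulate a full study (several independent pens)
#'
#' Per-pen seeds are derived deterministically from the master seed, so the
#' same configuration always yields byte-identical event logs.
#'
#' @param cfg a [generator_config()].
#' @return list with stacked `roster`, `truth` and `events` data.frames and
#'   the `config`.
#' @export
simulate_study <- function(cfg) {
  if (cfg$n_pens == 0L) {
    return(list(roster = pen_roster("void", c("x", "y"))[0, ],
                truth = data.frame(pen_id = character(0),
                                   animal_id = character(0),
                                   theta = numeric(0)),
                events = interaction_events(character(0), numeric(0),
                                            character(0), character(0)),
                config = cfg))
  }
  set.seed(cfg$seed)
  pen_seeds <- sample.int(.Machine$integer.max, cfg$n_pens)
  pens <- lapply(seq_len(cfg$n_pens), function(k) {
    simulate_pen(cfg, pen_id = sprintf("P%03d", k), seed = pen_seeds[k])
  })
  list(roster = do.call(rbind, lapply(pens, `[[`, "roster")),
       truth = do.call(rbind, lapply(pens, `[[`, "truth")),
       events = do.call(rbind, lapply(pens, `[[`, "events")),
       config = cfg)
}

#' Calibration summary of a simulated (or real) study
#'
#' Reports the quantities used to judge whether a generated dataset matches
#' the descriptive structure of the study data: interactions per animal
#' (counting each interaction for both participants), and per rising
#' window the initiator-win proportion among decisive fights and the mean
#' isolated-animal fraction per pen (winner-loser flavour on decisive
#' events, matching how isolated animals lack a dominance index).
#'
#' @param study output of [simulate_study()], or a list with `roster`,
#'   `events` and `config` elements.
#' @return list with `events_per_animal`, and a data.frame `by_window`
#'   (`window_hours`, `initiator_win_prop`, `isolated_fraction`).
#' @export
summarize_calibration <- function(study) {
  schedule <- study$config$schedule
  windows <- seq_len(total_hours(schedule))
  ev <- study$events
  n_animals <- nrow(study$roster)
  events_per_animal <- if (n_animals) 2 * nrow(ev) / n_animals else NA_real_
  pens <- unique(study$roster$pen_id)
  by_window <- data.frame(window_hours = windows,
                          initiator_win_prop = NA_real_,
                          isolated_fraction = NA_real_)
  for (k in seq_along(windows)) {
    sub <- ev[ev$t_obs <= windows[k], , drop = FALSE]
    dec <- filter_decisive(sub)
    by_window$initiator_win_prop[k] <-
      if (nrow(dec)) mean(dec$winner == dec$initiator) else NA_real_
    iso <- vapply(pens, function(p) {
      ros <- study$roster[study$roster$pen_id == p, , drop = FALSE]
      pe <- dec[dec$pen_id == p, , drop = FALSE]
      isolated_fraction(build_network(pe, ros, "WL"))
    }, numeric(1))
    by_window$isolated_fraction[k] <- mean(iso)
  }
  list(events_per_animal = events_per_animal, by_window = by_window)
}
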