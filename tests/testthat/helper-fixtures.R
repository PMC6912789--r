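# Worked-example pen of six pigs: pig 4 initiates four interactions but wins
# only two (vs pigs 2 and 3); pig 3 is attacked by pigs 4 and 6 and loses
# both; pig 1 never interacts.
example_roster <- function() pen_roster("PEX", as.character(1:6), "custom")

example_events <- function() {
  interaction_events(
    pen_id = "PEX",
    t_obs = c(0.5, 1.0, 1.5, 2.0, 2.5),
    initiator = c("4", "6", "4", "4", "4"),
    receiver  = c("3", "3", "2", "5", "6"),
    winner    = c("4", "6", "4", "5", "6"),
    loser     = c("3", "3", "2", "4", "4")
  )
}

# tiny deterministic generator config for fast property runs
tiny_config <- function(seed = 1, ...) {
  generator_config("piglet", n_pens = 4, n_per_pen = 9,
                   events_per_animal_target = 18.4, seed = seed, ...)
}

make_panel_study <- function(seed = 1, n_pens = 6, ...) {
  st <- simulate_study(generator_config("piglet", n_pens = n_pens,
                                        seed = seed, ...))
  st$schedule <- schedule_preset("piglet")
  st
}
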