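test_that("rising windows are nested, hourly, boundary-inclusive", {
  ros <- pen_roster("P1", c("a", "b", "c"))
  ev <- interaction_events("P1", c(0.5, 1.0, 1.5, 27.9),
                           rep("a", 4), rep("b", 4), rep("a", 4), rep("b", 4))
  w <- rising_windows(ev, schedule_preset("piglet"))
  expect_length(w, 28)
  expect_equal(nrow(w[["1"]]), 2)   # t = 1.0 belongs to the earlier window
  expect_equal(nrow(w[["2"]]), 3)
  expect_equal(nrow(w[["28"]]), 4)
  for (k in 2:28) expect_true(nrow(w[[k]]) >= nrow(w[[k - 1]]))
  w0 <- rising_windows(ev[0, ], schedule_preset("gilt"))
  expect_length(w0, 17)
  expect_true(all(vapply(w0, nrow, integer(1)) == 0))
})

test_that("zero-event windows give zero centralities and missing DIs", {
  ros <- pen_roster("P1", c("a", "b", "c"))
  pan <- compute_panel(interaction_events(character(0), numeric(0),
                                          character(0), character(0)),
                       ros, window_hours = 1L)
  expect_true(all(is.na(pan$di1)) && all(is.na(pan$di2)))
  cent_cols <- setdiff(names(pan), c("pen_id", "animal_id", "window_hours",
                                     "di1", "di2"))
  expect_true(all(pan[, cent_cols] == 0))
})

test_that("window panels equal from-scratch computation on the subset", {
  st <- make_panel_study(seed = 9, n_pens = 2)
  pans <- compute_panels(st$events, st$roster, st$schedule,
                         windows = c(3, 28))
  for (p in unique(st$roster$pen_id)) {
    ros <- st$roster[st$roster$pen_id == p, ]
    sub3 <- st$events[st$events$pen_id == p & st$events$t_obs <= 3, ]
    direct <- compute_panel(sub3, ros, 3L)
    got <- pans[pans$pen_id == p & pans$window_hours == 3, ]
    rownames(got) <- rownames(direct) <- NULL
    expect_equal(got, direct)
    # full-period window equals whole-dataset computation
    whole <- compute_panel(st$events[st$events$pen_id == p, ], ros, 28L)
    got28 <- pans[pans$pen_id == p & pans$window_hours == 28, ]
    rownames(got28) <- rownames(whole) <- NULL
    expect_equal(got28, whole)
  }
})

test_that("standardized out-degree never decreases across windows", {
  st <- make_panel_study(seed = 10, n_pens = 3)
  pans <- compute_panels(st$events, st$roster, st$schedule)
  for (flavor in c("out_degree_IR", "out_degree_WL")) {
    wide <- reshape(pans[, c("animal_id", "window_hours", flavor)],
                    idvar = "animal_id", timevar = "window_hours",
                    direction = "wide")
    mat <- as.matrix(wide[, -1])
    expect_true(all(diff(t(mat)) >= -1e-12))
  }
})

test_that("spearman_rho matches hand values and the rank-Pearson oracle", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rs, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rs, -1)
  expect_equal(spearman_rho(1:5, c(1, 2, 3, 5, 4))$rs, 0.9)
  set.seed(31)
  for (i in 1:80) {
    n <- sample(4:40, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- x + rnorm(n)
    r <- spearman_rho(x, y)
    expect_equal(r$rs, oracle_spearman(x, y), tolerance = 1e-12)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(r$rs, unname(ct$estimate), tolerance = 1e-12)
  }
})

test_that("spearman_rho handles missingness and degenerate input", {
  x <- c(1, 2, NA, 4, 5); y <- c(2, 1, 3, NA, 6)
  r <- spearman_rho(x, y)
  expect_equal(r$n, 3)
  expect_true(r$defined)
  expect_false(spearman_rho(c(1, 1, 1), c(1, 2, 3))$defined)
  expect_false(spearman_rho(c(1, 2), c(1, 2))$defined)
  # perfect monotone concordance: p-value collapses to 0
  expect_equal(spearman_rho(1:5, 2 * (1:5))$p_value, 0)
})

test_that("correlation series carry flags and respect pairwise deletion", {
  st <- make_panel_study(seed = 12, n_pens = 4)
  pans <- compute_panels(st$events, st$roster, st$schedule,
                         windows = c(1, 28))
  series <- correlation_series(pans)
  pooled <- series$pooled
  expect_setequal(unique(pooled$window_hours), c(1, 28))
  expect_equal(nrow(pooled), 2 * 20)   # 2 windows x (2 DIs x 10 centralities)
  final <- pooled[pooled$window_hours == 28, ]
  n_with_di <- sum(!is.na(pans$di2[pans$window_hours == 28]))
  expect_true(all(final$n == n_with_di))
  # the paper-style sign structure on strong-signal data
  expect_gt(final$rs[final$di == "di2" & final$centrality == "out_degree_WL"],
            0.7)
  expect_lt(final$rs[final$di == "di2" & final$centrality == "in_degree_WL"],
            0)
  expect_true(all(c("pen_id") %in% names(series$per_pen)))
})

test_that("undefined series entries are flagged, not fabricated", {
  ros <- pen_roster("P1", c("a", "b", "c", "d"))
  ev <- interaction_events("P1", 0.5, "a", "b", "a", "b")
  pan <- compute_panel(ev, ros, 1L)
  pan$window_hours <- 1L
  s <- correlation_series(pan)$pooled
  expect_true(all(!s$defined))
  expect_true(all(is.na(s$rs)))
})

test_that("descriptive trajectories track wins and isolation", {
  ros <- pen_roster("P1", c("a", "b", "c"))
  ev <- interaction_events("P1", c(0.5, 5), c("a", "a"), c("b", "c"),
                           c("a", "a"), c("b", "c"))
  tr <- descriptive_trajectories(ev, ros, schedule_preset("gilt"))
  expect_equal(nrow(tr), 17)
  expect_true(all(tr$initiator_win_prop == 1))
  expect_equal(tr$isolated_fraction[1], 1 / 3)
  expect_equal(tr$isolated_fraction[17], 0)
  expect_true(all(diff(tr$isolated_fraction) <= 1e-12))
})
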