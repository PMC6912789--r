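#' Rising cumulative time windows
#'
#' Window `k` (hours) contains every event with `t_obs <= k`, for
#' `k = 1, ..., total_hours`; the subsets are nested, so cumulative
#' statistics can only gain information as the window grows. Events falling
#' exactly on a window boundary belong to the earlier window.
#'
#' @param events event `data.frame`.
#' @param schedule an `obs_schedule` giving `total_hours`.
#' @return named list of event subsets, one per window length.
#' @export
rising_windows <- function(events, schedule) {
  ks <- seq_len(total_hours(schedule))
  out <- lapply(ks, function(k) events[events$t_obs <= k, , drop = FALSE])
  names(out) <- as.character(ks)
  out
}

panel_parameters <- c("di1", "di2",
                      "in_degree_IR", "out_degree_IR",
                      "closeness_in_IR", "closeness_out_IR", "betweenness_IR",
                      "in_degree_WL", "out_degree_WL",
                      "closeness_in_WL", "closeness_out_WL", "betweenness_WL")

#' Per-animal parameter panel for one window
#'
#' Computes both dominance indices and the five centralities for both
#' network flavours from the window's decisive events. Degrees are reported
#' standardized (`raw / (n - 1)`) so all centralities live on `[0, 1]`.
#' Isolated animals have 0 centralities and missing dominance indices —
#' the two semantics are deliberately kept distinct.
#'
#' @param events events of one pen restricted to one window.
#' @param roster roster of that pen.
#' @param window_hours window length to stamp on the rows.
#' @return `data.frame`, one row per rostered animal, with `pen_id`,
#'   `animal_id`, `window_hours` and the twelve parameter columns.
#' @export
compute_panel <- function(events, roster, window_hours = NA_integer_) {
  dec <- filter_decisive(events)
  dom <- dominance_indices(dec, roster)
  net_ir <- build_network(dec, roster, "IR")
  net_wl <- build_network(dec, roster, "WL")
  c_ir <- centrality_table(net_ir)
  c_wl <- centrality_table(net_wl)
  data.frame(pen_id = roster$pen_id[1L],
             animal_id = roster$animal_id,
             window_hours = window_hours,
             di1 = dom$di1, di2 = dom$di2,
             in_degree_IR = c_ir$in_degree_std,
             out_degree_IR = c_ir$out_degree_std,
             closeness_in_IR = c_ir$closeness_in,
             closeness_out_IR = c_ir$closeness_out,
             betweenness_IR = c_ir$betweenness,
             in_degree_WL = c_wl$in_degree_std,
             out_degree_WL = c_wl$out_degree_std,
             closeness_in_WL = c_wl$closeness_in,
             closeness_out_WL = c_wl$closeness_out,
             betweenness_WL = c_wl$betweenness,
             stringsAsFactors = FALSE)
}

#' Parameter panels for every rising window of a study
#'
#' @param events event `data.frame` (any number of pens).
#' @param roster roster covering those pens.
#' @param schedule an `obs_schedule`.
#' @param windows integer window lengths; defaults to all of them.
#' @return stacked panel `data.frame` (pen x animal x window).
#' @export
compute_panels <- function(events, roster, schedule,
                           windows = seq_len(total_hours(schedule))) {
  pens <- unique(roster$pen_id)
  out <- vector("list", length(windows) * length(pens))
  i <- 0L
  for (k in windows) {
    sub <- events[events$t_obs <= k, , drop = FALSE]
    for (p in pens) {
      i <- i + 1L
      out[[i]] <- compute_panel(sub[sub$pen_id == p, , drop = FALSE],
                                roster[roster$pen_id == p, , drop = FALSE],
                                window_hours = k)
    }
  }
  do.call(rbind, out)
}

# midranks with average ties
average_rank <- function(x) {
  r <- rank(x, ties.method = "average")
  r
}

#' Spearman rank correlation with t-approximate p-value
#'
#' Ranks both vectors with average ranks for ties, computes the Pearson
#' correlation of the ranks, and derives a two-sided p-value from the
#' t-approximation with `length - 2` degrees of freedom. Pairs with a
#' missing value in either vector are removed first.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rs`, `p_value`, `n` (pairs used) and `defined`
#'   (`FALSE` when fewer than 3 pairs remain or a vector is constant).
#' @export
spearman_rho <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rs = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  rx <- average_rank(x); ry <- average_rank(y)
  rs <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rs) >= 1) {
    p <- 0
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rs = rs, p_value = p, n = n, defined = TRUE)
}

default_pairs <- function() {
  cents <- c("in_degree", "out_degree", "closeness_in", "closeness_out",
             "betweenness")
  pairs <- expand.grid(di = c("di1", "di2"),
                       centrality = as.vector(outer(cents, c("IR", "WL"),
                                                    paste, sep = "_")),
                       stringsAsFactors = FALSE)
  pairs
}

#' Spearman correlation series over rising windows
#'
#' For each requested (dominance index, centrality) pair and each window,
#' the Spearman rank correlation over animals, with animals lacking the
#' dominance index (isolated at that window) excluded pairwise. Two scopes
#' are returned: `pooled` (animals of all pens pooled per window — the
#' default reported series) and `per_pen`.
#'
#' @param panels stacked output of [compute_panels()].
#' @param pairs data.frame with columns `di` and `centrality` naming panel
#'   columns; defaults to every index x centrality x flavour combination.
#' @param alpha significance threshold for the flag (two-sided, unadjusted).
#' @return list of two data.frames, `pooled` and `per_pen`, with columns
#'   `window_hours`, `di`, `centrality`, (`pen_id`,) `rs`, `p_value`, `n`,
#'   `defined`, `significant`.
#' @export
correlation_series <- function(panels, pairs = default_pairs(), alpha = 0.05) {
  run <- function(df, extra) {
    rows <- lapply(seq_len(nrow(pairs)), function(j) {
      r <- spearman_rho(df[[pairs$di[j]]], df[[pairs$centrality[j]]])
      cbind(extra, data.frame(di = pairs$di[j],
                              centrality = pairs$centrality[j],
                              rs = r$rs, p_value = r$p_value, n = r$n,
                              defined = r$defined,
                              significant = isTRUE(r$p_value < alpha),
                              stringsAsFactors = FALSE))
    })
    do.call(rbind, rows)
  }
  pooled <- per_pen <- list()
  for (k in sort(unique(panels$window_hours))) {
    pk <- panels[panels$window_hours == k, , drop = FALSE]
    pooled[[length(pooled) + 1L]] <-
      run(pk, data.frame(window_hours = k))
    for (p in unique(pk$pen_id)) {
      per_pen[[length(per_pen) + 1L]] <-
        run(pk[pk$pen_id == p, , drop = FALSE],
            data.frame(window_hours = k, pen_id = p))
    }
  }
  list(pooled = do.call(rbind, pooled), per_pen = do.call(rbind, per_pen))
}

#' Descriptive trajectories over rising windows
#'
#' Per window: the mean isolated-animal fraction across pens (winner-loser
#' network on decisive events) and the proportion of decisive fights won by
#' their initiator.
#'
#' @param events event `data.frame`.
#' @param roster roster covering the pens.
#' @param schedule an `obs_schedule`.
#' @return `data.frame` with `window_hours`, `isolated_fraction`,
#'   `initiator_win_prop`, `n_decisive`.
#' @export
descriptive_trajectories <- function(events, roster, schedule) {
  pens <- unique(roster$pen_id)
  ks <- seq_len(total_hours(schedule))
  out <- data.frame(window_hours = ks, isolated_fraction = NA_real_,
                    initiator_win_prop = NA_real_, n_decisive = NA_integer_)
  for (i in seq_along(ks)) {
    dec <- filter_decisive(events[events$t_obs <= ks[i], , drop = FALSE])
    out$n_decisive[i] <- nrow(dec)
    out$initiator_win_prop[i] <-
      if (nrow(dec)) mean(dec$winner == dec$initiator) else NA_real_
    iso <- vapply(pens, function(p) {
      isolated_fraction(build_network(dec[dec$pen_id == p, , drop = FALSE],
                                      roster[roster$pen_id == p, , drop = FALSE],
                                      "WL"))
    }, numeric(1))
    out$isolated_fraction[i] <- mean(iso)
  }
  out
}
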