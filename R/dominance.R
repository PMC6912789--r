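#' Tally wins, defeats and distinct opponents per animal
#'
#' For each rostered animal, counts fights won and lost and the number of
#' distinct pen mates beaten at least once (`p_won`) or lost to at least
#' once (`p_lost`). An opponent both beaten and lost to contributes to both
#' counts. Animals with no decisive interaction get the zero tally.
#'
#' @param events decisive events of a single pen (see [filter_decisive()]).
#' @param roster roster of that pen.
#' @return `data.frame` with columns `animal_id`, `wins`, `defeats`,
#'   `p_won`, `p_lost`, one row per rostered animal (roster order).
#' @export
tally_fights <- function(events, roster) {
  if (nrow(events)) {
    if (!all(events$decisive))
      stop("tally_fights expects decisive events only; call filter_decisive()",
           call. = FALSE)
    validate_events(events, roster)
    if (length(unique(events$pen_id)) > 1L)
      stop("tally_fights expects events of a single pen", call. = FALSE)
  }
  ids <- roster$animal_id
  tal <- data.frame(animal_id = ids,
                    wins = 0L, defeats = 0L, p_won = 0L, p_lost = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(events)) {
    wtab <- table(factor(events$winner, levels = ids))
    ltab <- table(factor(events$loser, levels = ids))
    tal$wins <- as.integer(wtab)
    tal$defeats <- as.integer(ltab)
    dyads <- unique(events[, c("winner", "loser")])
    tal$p_won <- as.integer(table(factor(dyads$winner, levels = ids)))
    tal$p_lost <- as.integer(table(factor(dyads$loser, levels = ids)))
  }
  tal
}

#' Dominance index DI1 (win-defeat balance)
#'
#' `DI1 = (wins - defeats) / (wins + defeats)`, ranging from -1 (absolute
#' subordinate) to +1 (absolute dominant). Undefined (`NA`) for animals
#' involved in no decisive interaction.
#'
#' @param wins,defeats non-negative counts (vectorised).
#' @return numeric in `[-1, 1]` or `NA`.
#' @export
di1 <- function(wins, defeats) {
  tot <- wins + defeats
  ifelse(tot == 0, NA_real_, (wins - defeats) / tot)
}

#' Dominance index DI2 (opponent-weighted balance)
#'
#' `DI2 = (wins * p_won - defeats * p_lost) / ((wins + defeats) * (n - 1))`,
#' weighting the win-defeat balance by the numbers of distinct pen mates
#' beaten (`p_won`) and lost to (`p_lost`) and the group size `n`. Same
#' range and missingness convention as [di1()]; its distribution is
#' narrower because repeated wins over the same opponent count less.
#'
#' @param wins,defeats non-negative counts (vectorised).
#' @param p_won,p_lost distinct opponents beaten / lost to.
#' @param n group size (>= 2).
#' @return numeric in `[-1, 1]` or `NA`.
#' @export
di2 <- function(wins, defeats, p_won, p_lost, n) {
  if (any(n < 2)) stop("group size n must be >= 2", call. = FALSE)
  tot <- wins + defeats
  ifelse(tot == 0, NA_real_,
         (wins * p_won - defeats * p_lost) / (tot * (n - 1)))
}

#' Per-animal dominance indices for one pen
#'
#' Convenience wrapper: tallies decisive fights and evaluates both indices.
#'
#' @param events events of one pen (indecisive rows are dropped internally).
#' @param roster roster of that pen.
#' @return `data.frame` with `pen_id`, `animal_id`, `wins`, `defeats`,
#'   `p_won`, `p_lost`, `di1`, `di2` (`NA` for isolated animals).
#' @export
dominance_indices <- function(events, roster) {
  tal <- tally_fights(filter_decisive(events), roster)
  n <- nrow(roster)
  cbind(pen_id = roster$pen_id[1L], tal,
        di1 = di1(tal$wins, tal$defeats),
        di2 = di2(tal$wins, tal$defeats, tal$p_won, tal$p_lost, n))
}
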