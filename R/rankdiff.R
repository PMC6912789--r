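#' Map a parameter onto the common [0, 1] scale
#'
#' Rank-difference comparisons across dominance indices and centralities
#' need one bounded scale. Dominance indices live on `[-1, 1]` and are
#' mapped affinely by `(x + 1) / 2`; standardized degrees, closeness and
#' betweenness already live on `[0, 1]` and pass through. Missing values
#' stay missing.
#'
#' @param values numeric vector.
#' @param parameter panel column name (e.g. `"di2"`, `"out_degree_WL"`).
#' @return numeric vector in `[0, 1]`.
#' @export
standardize_parameter <- function(values, parameter) {
  if (parameter %in% c("di1", "di2")) (values + 1) / 2 else values
}

# comparison cutoffs per age-group profile: highest "k:(k+1)" retained
rank_cutoff <- function(profile) {
  switch(profile, piglet = 8L, fattener = 20L, gilt = 18L,
         stop("no rank-comparison cutoff for profile: ", profile,
              call. = FALSE))
}

#' Absolute differences between subsequent rank positions
#'
#' Per pen and parameter: standardize, drop missing values, sort
#' descending, and record `|value(rank k) - value(rank k+1)|` for
#' `k = 1, ..., min(cutoff, available - 1)` (comparison label `"k:(k+1)"`).
#' Ties yield zero differences; tied values are ordered by animal id so the
#' output is deterministic.
#'
#' @param panel one-window panel (see [compute_panel()]), any number of pens.
#' @param parameters panel columns to analyse.
#' @param cutoff highest comparison index `k` retained; defaults to the
#'   profile-specific cutoff when `profile` is given.
#' @param profile optional age-group label used to look up the cutoff
#'   (8:9 for piglets, 20:21 for fatteners, 18:19 for gilts).
#' @return `data.frame` with `pen_id`, `parameter`, `comparison`, `k`,
#'   `abs_diff`.
#' @export
rank_differences <- function(panel,
                             parameters = c("di1", "di2", "in_degree_WL",
                                            "out_degree_WL", "closeness_in_WL",
                                            "closeness_out_WL", "betweenness_WL"),
                             cutoff = NULL, profile = NULL) {
  if (is.null(cutoff)) {
    if (is.null(profile))
      stop("supply either cutoff or profile", call. = FALSE)
    cutoff <- rank_cutoff(profile)
  }
  rows <- list()
  for (p in unique(panel$pen_id)) {
    sub <- panel[panel$pen_id == p, , drop = FALSE]
    for (param in parameters) {
      v <- standardize_parameter(sub[[param]], param)
      ids <- sub$animal_id[!is.na(v)]
      v <- v[!is.na(v)]
      if (length(v) < 2) next
      ord <- order(-v, ids)
      v <- v[ord]
      kmax <- min(cutoff, length(v) - 1L)
      k <- seq_len(kmax)
      rows[[length(rows) + 1L]] <- data.frame(
        pen_id = p, parameter = param,
        comparison = sprintf("%d:%d", k, k + 1L), k = k,
        abs_diff = v[k] - v[k + 1L],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pen_id = character(0), parameter = character(0),
                      comparison = character(0), k = integer(0),
                      abs_diff = numeric(0)))
  do.call(rbind, rows)
}

#' Contrast every parameter against DI2 per comparison, Holm-adjusted
#'
#' Fits the fixed-effects least-squares model
#' `abs_diff ~ parameter + comparison + parameter:comparison` with pens as
#' replicates, then contrasts each parameter's cell mean against DI2's
#' within each comparison level, using the pooled residual variance and its
#' degrees of freedom. The family of all parameter-vs-DI2 contrasts is
#' Holm-adjusted.
#'
#' @param records output of [rank_differences()]; must contain `"di2"`.
#' @param alpha significance threshold applied to the adjusted p-values.
#' @return list with `contrasts` (`parameter`, `comparison`, `estimate`,
#'   `se`, `p_raw`, `p_holm`, `significant`) and the underlying `fit`
#'   (`lm` object).
#' @export
contrast_vs_di2 <- function(records, alpha = 0.05) {
  if (!"di2" %in% records$parameter)
    stop("records must include parameter 'di2'", call. = FALSE)
  if (length(unique(records$pen_id)) < 2)
    stop("need at least 2 pens for a residual variance", call. = FALSE)
  d <- records
  d$parameter <- factor(d$parameter)
  d$comparison <- factor(d$comparison, levels = unique(d$comparison[order(d$k)]))
  fit <- stats::lm(abs_diff ~ parameter * comparison, data = d)
  s2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  cells <- stats::aggregate(abs_diff ~ parameter + comparison, data = d,
                            FUN = mean)
  counts <- stats::aggregate(abs_diff ~ parameter + comparison, data = d,
                             FUN = length)
  names(counts)[3] <- "n"
  cells <- merge(cells, counts, by = c("parameter", "comparison"))
  params <- setdiff(levels(d$parameter), "di2")
  rows <- list()
  for (cmp in levels(d$comparison)) {
    ref <- cells[cells$parameter == "di2" & cells$comparison == cmp, ]
    if (!nrow(ref)) next
    for (param in params) {
      cell <- cells[cells$parameter == param & cells$comparison == cmp, ]
      if (!nrow(cell)) next  # empty cell: skipped
      est <- cell$abs_diff - ref$abs_diff
      se <- sqrt(s2 * (1 / cell$n + 1 / ref$n))
      tval <- if (se > 0) est / se else if (est == 0) 0 else Inf
      p <- 2 * stats::pt(-abs(tval), df = fit$df.residual)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = param, comparison = cmp, estimate = est, se = se,
        p_raw = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_holm <- stats::p.adjust(res$p_raw, method = "holm")
  res$significant <- res$p_holm < alpha
  list(contrasts = res, fit = fit)
}
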