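#' Specify a PLS path model
#'
#' A model is a set of latent variables, each measured reflectively
#' (Mode A) by a block of indicator columns, plus directed structural paths
#' between latents (the structural graph must be acyclic). The default
#' models relate latent dominance `D` (indicators DI1, DI2) to centrality
#' blocks from the initiator-receiver (`C_IR`) and winner-loser (`C_WL`)
#' networks, with paths `C_IR -> D` and `C_WL -> D`.
#'
#' @param blocks named list; each element is a character vector of
#'   indicator column names assigned to that latent. An indicator belongs
#'   to exactly one latent; the latent's score sign is fixed to correlate
#'   positively with its first listed indicator.
#' @param paths 2-column data.frame (`from`, `to`) of structural edges.
#' @return a `pls_spec` object.
#' @export
pls_spec <- function(blocks, paths) {
  stopifnot(is.list(blocks), !is.null(names(blocks)),
            all(c("from", "to") %in% names(paths)))
  inds <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(inds))
    stop("each indicator must belong to exactly one latent", call. = FALSE)
  latents <- names(blocks)
  if (!all(c(paths$from, paths$to) %in% latents))
    stop("path endpoints must be declared latents", call. = FALSE)
  # cycle check by repeated pruning of sink-free nodes
  rem <- latents
  edges <- paths
  repeat {
    sinks <- setdiff(rem, edges$from)
    if (!length(sinks)) break
    rem <- setdiff(rem, sinks)
    edges <- edges[edges$to %in% rem, , drop = FALSE]
    if (!length(rem)) break
  }
  if (length(rem)) stop("structural graph has a cycle", call. = FALSE)
  structure(list(blocks = blocks, paths = paths[, c("from", "to")],
                 latents = latents),
            class = "pls_spec")
}

#' Default PLS model for an age-group profile
#'
#' Out-degree and outgoing closeness measure both centrality blocks in all
#' profiles; betweenness of the initiator-receiver network joins the
#' `C_IR` block for the fattener and gilt models only.
#'
#' @param profile `"piglet"`, `"fattener"` or `"gilt"`.
#' @return a `pls_spec`.
#' @export
default_pls_spec <- function(profile = "piglet") {
  c_ir <- c("out_degree_IR", "closeness_out_IR")
  if (profile %in% c("fattener", "gilt")) c_ir <- c(c_ir, "betweenness_IR")
  pls_spec(
    blocks = list(D = c("di1", "di2"),
                  C_IR = c_ir,
                  C_WL = c("out_degree_WL", "closeness_out_WL")),
    paths = data.frame(from = c("C_IR", "C_WL"), to = c("D", "D"),
                       stringsAsFactors = FALSE)
  )
}

# unit-variance standardization, n-1 denominator; errors on constants
standardize_cols <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0))
    stop("constant indicator: ", paste(colnames(X)[sdv == 0], collapse = ", "),
         call. = FALSE)
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

#' Fit a PLS path model (Mode A, path weighting scheme)
#'
#' Indicators are standardized to zero mean and unit variance. Outer
#' weights start at +1 and are iterated: (a) latent scores are the
#' standardized weighted indicator sums; (b) each latent's inner proxy
#' combines its structural neighbours with path weighting (predecessors
#' weighted by the multiple-regression coefficients of the latent on them,
#' successors by correlations); (c) Mode A updates each weight to the
#' correlation between indicator and inner proxy. After convergence,
#' loadings are indicator-score correlations, structural path coefficients
#' come from ordinary least squares among the latent scores, and the
#' outer-model quality measures (indicator reliability, composite
#' reliability, average variance extracted) are derived from the loadings.
#' Path coefficients are plain regression coefficients and may exceed 1 in
#' magnitude when exogenous latents are collinear.
#'
#' Rows with any missing indicator are dropped (complete-case analysis;
#' animals without a dominance index have no DI indicator) and the dropped
#' count is recorded.
#'
#' @param data data.frame containing all indicator columns.
#' @param spec a [pls_spec()].
#' @param tol convergence tolerance on the maximum absolute outer-weight
#'   change.
#' @param max_iter iteration cap; exceeding it flags non-convergence.
#' @return object of class `pls_fit`: outer `weights` and `loadings`,
#'   unit-variance latent `scores`, `paths` (with `estimate`), `r2` per
#'   endogenous latent, `reliability` tables, `converged`, `iterations`,
#'   `n_used`, `n_dropped`.
#' @export
fit_pls <- function(data, spec, tol = 1e-7, max_iter = 300L) {
  stopifnot(inherits(spec, "pls_spec"))
  inds <- unlist(spec$blocks, use.names = FALSE)
  missing_cols <- setdiff(inds, names(data))
  if (length(missing_cols))
    stop("data lacks indicator columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X0 <- as.matrix(data[, inds, drop = FALSE])
  cc <- stats::complete.cases(X0)
  X0 <- X0[cc, , drop = FALSE]
  n <- nrow(X0)
  if (n < 10) stop("fewer than 10 complete observations", call. = FALSE)
  X <- standardize_cols(X0)
  latents <- spec$latents
  blocks <- spec$blocks
  w <- lapply(blocks, function(b) stats::setNames(rep(1, length(b)), b))

  score_of <- function(w) {
    Y <- vapply(latents, function(j) {
      y <- X[, blocks[[j]], drop = FALSE] %*% w[[j]]
      as.numeric(y / stats::sd(y))
    }, numeric(n))
    colnames(Y) <- latents
    Y
  }

  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Y <- score_of(w)
    # inner proxies, path weighting scheme
    Z <- matrix(0, n, length(latents), dimnames = list(NULL, latents))
    for (j in latents) {
      preds <- spec$paths$from[spec$paths$to == j]
      succs <- spec$paths$to[spec$paths$from == j]
      z <- numeric(n)
      if (length(preds)) {
        b <- stats::coef(stats::lm.fit(cbind(1, Y[, preds, drop = FALSE]),
                                       Y[, j]))[-1]
        z <- z + as.numeric(Y[, preds, drop = FALSE] %*% b)
      }
      for (s in succs) z <- z + stats::cor(Y[, j], Y[, s]) * Y[, s]
      Z[, j] <- z
    }
    w_new <- lapply(latents, function(j) {
      zz <- Z[, j]
      if (stats::sd(zz) == 0) return(w[[j]])  # isolated latent: keep weights
      stats::setNames(as.numeric(stats::cor(X[, blocks[[j]], drop = FALSE], zz)),
                      blocks[[j]])
    })
    names(w_new) <- latents
    delta <- max(abs(unlist(w_new) - unlist(w)))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  Y <- score_of(w)
  # sign convention: each score correlates positively with its first indicator
  for (j in latents) {
    s <- stats::cor(Y[, j], X[, blocks[[j]][1L]])
    if (!is.na(s) && s < 0) { Y[, j] <- -Y[, j]; w[[j]] <- -w[[j]] }
  }
  loadings <- lapply(latents, function(j)
    stats::setNames(as.numeric(stats::cor(X[, blocks[[j]], drop = FALSE],
                                          Y[, j])), blocks[[j]]))
  names(loadings) <- latents

  endo <- unique(spec$paths$to)
  paths <- spec$paths
  paths$estimate <- NA_real_
  r2 <- stats::setNames(numeric(length(endo)), endo)
  for (j in endo) {
    preds <- spec$paths$from[spec$paths$to == j]
    fit <- stats::lm.fit(cbind(1, Y[, preds, drop = FALSE]), Y[, j])
    b <- stats::coef(fit)[-1]
    paths$estimate[paths$to == j] <- b[match(preds, preds)]
    for (i in seq_along(preds))
      paths$estimate[paths$to == j & paths$from == preds[i]] <- b[i]
    r2[j] <- 1 - sum(fit$residuals^2) / sum((Y[, j] - mean(Y[, j]))^2)
  }

  reliability <- do.call(rbind, lapply(latents, function(j) {
    l <- loadings[[j]]
    data.frame(latent = j, indicator = names(l), loading = unname(l),
               indicator_reliability = unname(l)^2,
               stringsAsFactors = FALSE)
  }))
  block_quality <- do.call(rbind, lapply(latents, function(j) {
    l <- loadings[[j]]
    cr <- sum(abs(l))^2 / (sum(abs(l))^2 + sum(1 - l^2))
    data.frame(latent = j, composite_reliability = cr, ave = mean(l^2),
               stringsAsFactors = FALSE)
  }))

  structure(list(spec = spec, weights = w, loadings = loadings,
                 scores = Y, paths = paths, r2 = r2,
                 reliability = reliability, block_quality = block_quality,
                 converged = converged, iterations = iter,
                 n_used = n, n_dropped = sum(!cc)),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, digits = 3, ...) {
  cat(sprintf("PLS path model (Mode A, path weighting): n = %d (%d dropped), %s in %d iterations\n",
              x$n_used, x$n_dropped,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("Structural paths:\n")
  p <- x$paths
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %s -> %s: %.*f\n", p$from[i], p$to[i], digits,
                p$estimate[i]))
  for (j in names(x$r2))
    cat(sprintf("R-squared (%s): %.*f\n", j, digits, x$r2[j]))
  invisible(x)
}

#' @export
coef.pls_fit <- function(object, ...) {
  stats::setNames(object$paths$estimate,
                  paste(object$paths$from, object$paths$to, sep = "->"))
}

#' @export
summary.pls_fit <- function(object, ...) {
  structure(list(fit = object, gates = quality_gates(object)),
            class = "summary.pls_fit")
}

#' @export
print.summary.pls_fit <- function(x, ...) {
  print(x$fit)
  cat("\nOuter model:\n")
  print(x$fit$reliability, row.names = FALSE, digits = 3)
  cat("\nBlock quality:\n")
  print(x$fit$block_quality, row.names = FALSE, digits = 3)
  cat("\nQuality gates:\n")
  print(x$gates$gates, row.names = FALSE)
  cat(sprintf("R-squared band: %s\n",
              paste(sprintf("%s=%s", names(x$gates$r2_band), x$gates$r2_band),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.pls_fit <- function(x, ...) {
  rel <- x$reliability
  graphics::barplot(rel$indicator_reliability,
                    names.arg = paste(rel$latent, rel$indicator, sep = ":"),
                    las = 2, ylim = c(0, 1),
                    ylab = "indicator reliability", ...)
  graphics::abline(h = 0.7, lty = 2)
  invisible(x)
}

#' Bootstrap inference for the structural paths
#'
#' Observations are resampled with replacement and the model refitted; the
#' sign convention (score positively correlated with the block's first
#' indicator) aligns every replicate with the original fit. The standard
#' error is the standard deviation of replicate path estimates and the
#' two-sided p-value comes from `t = estimate / SE` with `n - 1` degrees of
#' freedom. Replicates that fail or do not converge are counted; more than
#' 5% failures triggers a warning.
#'
#' @param data,spec,tol,max_iter as in [fit_pls()].
#' @param n_boot number of bootstrap replicates (>= 500).
#' @param seed RNG seed for resampling.
#' @return list with `paths` (adds `se`, `t`, `p_value` to the path table),
#'   `n_boot_ok`, `n_boot_failed`, `replicates` (matrix of path estimates).
#' @export
bootstrap_paths <- function(data, spec, n_boot = 5000L, seed = 1L,
                            tol = 1e-7, max_iter = 300L) {
  if (n_boot < 500L) stop("n_boot must be at least 500", call. = FALSE)
  fit0 <- fit_pls(data, spec, tol = tol, max_iter = max_iter)
  inds <- unlist(spec$blocks, use.names = FALSE)
  cc <- stats::complete.cases(data[, inds, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  n <- nrow(d)
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, nrow(fit0$paths))
  colnames(reps) <- paste(fit0$paths$from, fit0$paths$to, sep = "->")
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_fit <- tryCatch(fit_pls(d[idx, , drop = FALSE], spec, tol = tol,
                                max_iter = max_iter),
                        error = function(e) NULL)
    if (is.null(rep_fit) || !rep_fit$converged) {
      failed <- failed + 1L
    } else {
      reps[b, ] <- rep_fit$paths$estimate
    }
  }
  if (failed > 0.05 * n_boot)
    warning(sprintf("%d of %d bootstrap replicates failed", failed, n_boot))
  se <- apply(reps, 2, stats::sd, na.rm = TRUE)
  paths <- fit0$paths
  paths$se <- unname(se)
  paths$t <- paths$estimate / paths$se
  paths$p_value <- 2 * stats::pt(-abs(paths$t), df = fit0$n_used - 1)
  list(paths = paths, n_boot_ok = n_boot - failed, n_boot_failed = failed,
       replicates = reps, fit = fit0)
}

#' Outer- and inner-model quality gates
#'
#' Composite reliability should fall in the exploratory band 0.6-0.9
#' (values above 0.9 are flagged as suspiciously redundant indicators),
#' indicator reliability should exceed 0.7, and the average variance
#' extracted should exceed 0.5. The coefficient of determination is mapped
#' to a verbal band: below 0.25 negligible, then weak, moderate from 0.50,
#' substantial from 0.75.
#'
#' @param fit a `pls_fit`.
#' @return list with `gates` (`latent`/`indicator`, `criterion`, `value`,
#'   `pass`) and `r2_band` (named character).
#' @export
quality_gates <- function(fit) {
  stopifnot(inherits(fit, "pls_fit"))
  g <- list()
  for (i in seq_len(nrow(fit$block_quality))) {
    bq <- fit$block_quality[i, ]
    g[[length(g) + 1L]] <- data.frame(
      unit = bq$latent, criterion = "composite_reliability_0.6_0.9",
      value = bq$composite_reliability,
      pass = bq$composite_reliability >= 0.6 & bq$composite_reliability <= 0.9,
      stringsAsFactors = FALSE)
    g[[length(g) + 1L]] <- data.frame(
      unit = bq$latent, criterion = "ave_above_0.5", value = bq$ave,
      pass = bq$ave > 0.5, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(fit$reliability))) {
    r <- fit$reliability[i, ]
    g[[length(g) + 1L]] <- data.frame(
      unit = paste(r$latent, r$indicator, sep = ":"),
      criterion = "indicator_reliability_above_0.7",
      value = r$indicator_reliability,
      pass = r$indicator_reliability > 0.7, stringsAsFactors = FALSE)
  }
  band <- vapply(fit$r2, function(v) {
    if (v >= 0.75) "substantial"
    else if (v >= 0.50) "moderate"
    else if (v >= 0.25) "weak"
    else "negligible"
  }, character(1))
  list(gates = do.call(rbind, g), r2_band = band)
}
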