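# Goodness of fit on response-pattern tables, G-squared-based information
# criteria, and the 2-4 class enumeration sweep with the 5%-decrease rule.

#' Free-parameter count of a (multigroup) latent class model
#'
#' With C classes, J binary items and G groups: membership probabilities
#' contribute `G * (C - 1)` and item-response probabilities `C * J` when
#' constrained equal across groups (`rho_invariant`), else `G * C * J`.
#' G = 1 reduces to `(C - 1) + C * J`.
#'
#' @param C,J,G Positive integers (G defaults to 1).
#' @param rho_invariant Are item-response probabilities shared across groups?
#' @return Integer parameter count.
#' @export
count_free_parameters <- function(C, J, G = 1L, rho_invariant = TRUE) {
  if (C < 1L || J < 1L || G < 1L) stop("C, J and G must be positive")
  as.integer(G * (C - 1L) + if (rho_invariant) C * J else G * C * J)
}

#' Observed response-pattern table
#'
#' Tabulates complete-case records by their response pattern. Records with
#' any missing item enter estimation via the MAR likelihood but not the
#' goodness-of-fit table.
#'
#' @param data A [response_matrix()].
#' @return An object of class `pattern_table`: `patterns` (2^J x J matrix of
#'   all complete patterns, items varying fastest in the last column),
#'   `counts` (observed frequencies, zeros included) and `n_complete`.
#' @export
pattern_table <- function(data) {
  stopifnot(inherits(data, "response_matrix"))
  J <- ncol(data$items)
  grid <- as.matrix(expand.grid(rep(list(c(0L, 1L)), J))[, J:1, drop = FALSE])
  colnames(grid) <- data$item_names
  complete <- data$items[stats::complete.cases(data$items), , drop = FALSE]
  key <- apply(grid, 1L, paste, collapse = "")
  obs <- apply(complete, 1L, paste, collapse = "")
  counts <- as.integer(table(factor(obs, levels = key)))
  structure(list(patterns = grid, counts = counts,
                 n_complete = nrow(complete)),
            class = "pattern_table")
}

#' G-squared and Pearson goodness of fit
#'
#' Compares observed complete-case pattern frequencies with the model's
#' expected frequencies: `G2 = 2 sum obs log(obs/exp)` over patterns with
#' positive observed count, `X2 = sum (obs-exp)^2/exp` over all patterns.
#' Residual df is `2^J - 1 - n_params`; when df <= 0 the model is saturated
#' and the tail probability is undefined.
#'
#' @param params An [lca_params()] object.
#' @param table A [pattern_table()].
#' @param n_params Free-parameter count (defaults to
#'   [count_free_parameters()] for the single-group model).
#' @return A list: `gsq`, `xsq`, `df`, `p`, `saturated`.
#' @export
goodness_of_fit <- function(params, table, n_params = NULL) {
  stopifnot(inherits(params, "lca_params"), inherits(table, "pattern_table"))
  if (is.null(n_params)) {
    n_params <- count_free_parameters(n_classes(params), n_items(params))
  }
  n <- table$n_complete
  probs <- exp(vapply(seq_len(nrow(table$patterns)), function(i)
    pattern_log_probability(params, table$patterns[i, ]), numeric(1)))
  expected <- n * probs
  obs <- table$counts
  if (any(expected == 0 & obs > 0)) {
    stop("expected count 0 with positive observed count for pattern ",
         paste(table$patterns[which(expected == 0 & obs > 0)[1L], ],
               collapse = ""))
  }
  pos <- obs > 0
  gsq <- 2 * sum(obs[pos] * log(obs[pos] / expected[pos]))
  nz <- expected > 0
  xsq <- sum((obs[nz] - expected[nz])^2 / expected[nz])
  df <- as.integer(2^ncol(table$patterns) - 1L - n_params)
  saturated <- df <= 0L
  p <- if (saturated) NA_real_ else chi_square_tail(max(gsq, 0), df)
  list(gsq = gsq, xsq = xsq, df = df, p = p, saturated = saturated)
}

#' G-squared-based information criteria
#'
#' `AIC = G2 + 2 p` and `BIC = G2 + log(n) p`, the convention in which the
#' saturated-model deviance replaces -2 log-likelihood. `n_used` is the
#' number of records entering the likelihood.
#'
#' @param gsq G-squared statistic.
#' @param n_params Free-parameter count.
#' @param n_used Number of records entering the likelihood (>= 1).
#' @return Named numeric vector `c(aic=, bic=)`.
#' @export
information_criteria <- function(gsq, n_params, n_used) {
  if (n_used < 1L) stop("n_used must be >= 1")
  c(aic = gsq + 2 * n_params, bic = gsq + log(n_used) * n_params)
}

#' Upper-tail chi-square probability
#'
#' @param x Non-negative statistic.
#' @param df Positive integer degrees of freedom.
#' @return `P(Chi2_df >= x)`.
#' @export
chi_square_tail <- function(x, df) {
  if (any(x < 0)) stop("x must be non-negative")
  if (any(df < 1)) stop("df must be >= 1")
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Class enumeration by GOF screen and AIC/BIC 5%-decrease rule
#'
#' Fits every candidate C in `c_min:c_max` with shared EM settings, then
#' walks forward from the smallest candidate. The sweep advances to C+1
#' when the current model fails the goodness-of-fit screen (G-squared
#' p <= 0.05 — a rejected model cannot be retained regardless of parsimony)
#' or when both AIC and BIC decrease by at least `drop` (default 5%)
#' relative to the current model; otherwise it stops. Saturated models
#' (df <= 0) cannot be rejected by the screen. Non-converged candidates are
#' flagged and the sweep does not advance onto them. Model interpretability
#' (distinguishable, non-trivial classes) is left to the analyst.
#'
#' @param data A [response_matrix()].
#' @param c_min,c_max Candidate class range (the study swept 2-4).
#' @param config An [em_config()].
#' @param drop Required relative decrease in both criteria (default 0.05).
#' @return An object of class `selection_report`: `candidate_fits` (named
#'   list of [fit_em()] results), `selected_C`, and `rule_trace` (one row per
#'   candidate with criteria, relative drops, GOF flags, and whether the
#'   sweep advanced).
#' @export
select_classes <- function(data, c_min, c_max, config, drop = 0.05) {
  stopifnot(c_min >= 1L, c_max >= c_min)
  cs <- seq.int(c_min, c_max)
  fits <- lapply(cs, function(C) fit_em(data, C, config))
  names(fits) <- paste0("C", cs)
  trace <- data.frame(
    C = cs,
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    gsq = vapply(fits, function(f) f$gsq, numeric(1)),
    df = vapply(fits, function(f) as.numeric(f$df), numeric(1)),
    gof_p = vapply(fits, function(f) f$gof_p, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1))
  )
  trace$gof_ok <- is.na(trace$gof_p) | trace$gof_p > 0.05
  trace$aic_drop <- c(NA, -diff(trace$aic) / abs(trace$aic[-nrow(trace)]))
  trace$bic_drop <- c(NA, -diff(trace$bic) / abs(trace$bic[-nrow(trace)]))
  trace$advanced <- FALSE
  sel <- 1L
  while (sel < length(cs)) {
    nxt <- sel + 1L
    if (!trace$converged[nxt]) break
    gof_reject <- !trace$gof_ok[sel]
    crit_drop <- !is.na(trace$aic_drop[nxt]) && !is.na(trace$bic_drop[nxt]) &&
      trace$aic_drop[nxt] >= drop && trace$bic_drop[nxt] >= drop
    if (gof_reject || crit_drop) {
      trace$advanced[nxt] <- TRUE
      sel <- nxt
    } else break
  }
  structure(list(candidate_fits = fits, selected_C = cs[sel],
                 rule_trace = trace, drop = drop),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> candidates ", min(x$rule_trace$C), "-",
      max(x$rule_trace$C), ", selected C = ", x$selected_C, "\n", sep = "")
  print(x$rule_trace, digits = 4, row.names = FALSE)
  invisible(x)
}
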