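# Multi-start EM for the latent class model. Works on collapsed pattern
# tables (unique response/group patterns with counts), so each iteration is
# a handful of small matrix products regardless of n.

#' EM estimation settings
#'
#' @param seed Integer seed driving every random initialization (mandatory).
#' @param n_starts Number of random starts; the run with the highest
#'   log-likelihood is kept.
#' @param max_iter Iteration cap per start.
#' @param mad_tol Convergence tolerance: maximum absolute deviation (MAD) of
#'   any parameter between successive iterations.
#' @param rho_floor Clamp applied to rho inside likelihood evaluations only
#'   (reported estimates may touch 0 or 1); must lie in (0, 0.5).
#' @return A list of class `em_config`.
#' @export
em_config <- function(seed, n_starts = 20L, max_iter = 5000L,
                      mad_tol = 1e-8, rho_floor = 1e-6) {
  if (missing(seed)) stop("an explicit integer seed is required")
  stopifnot(n_starts >= 1L, max_iter >= 1L, mad_tol > 0,
            rho_floor > 0, rho_floor < 0.5)
  structure(list(seed = as.integer(seed), n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), mad_tol = mad_tol,
                 rho_floor = rho_floor),
            class = "em_config")
}

# Random initialization: gamma from a flat simplex draw, rho uniform on
# (0.1, 0.9). Multigroup: one gamma row per group.
init_params <- function(C, J, G = 1L) {
  g <- matrix(stats::rexp(G * C), G, C)
  g <- g / rowSums(g)
  list(gamma = g, rho = matrix(stats::runif(C * J, 0.1, 0.9), C, J))
}

# One EM run on a collapsed multigroup pattern table.
#   cp: collapse_patterns() output (group column indexes gamma rows)
#   gamma: G x C, rho: C x J (shared across groups when rho_invariant,
#   else the free model is fitted per group by the caller with G = 1).
em_run <- function(cp, gamma, rho, config, item_names) {
  G <- nrow(gamma)
  C <- ncol(gamma)
  J <- ncol(rho)
  m <- nrow(cp$X)
  M <- 1 - is.na(cp$X)
  X0 <- ifelse(is.na(cp$X), 0, cp$X)
  w <- cp$counts
  gi <- cp$group
  trace <- numeric(0L)
  ll <- -Inf
  mad <- Inf
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    rho_c <- clamp_rho(rho, config$rho_floor)
    lr <- t(log(rho_c))
    lq <- t(log1p(-rho_c))
    lp <- X0 %*% lr + (M - X0) %*% lq +
      log(pmax(gamma, 1e-300))[gi, , drop = FALSE]
    tot <- logsumexp_rows(lp)
    ll <- sum(w * tot)
    trace[iter] <- ll
    post <- exp(lp - tot)                      # m x C responsibilities
    pw <- post * w
    # M-step
    gamma_new <- gamma
    for (g in seq_len(G)) {
      rows <- gi == g
      gamma_new[g, ] <- colSums(pw[rows, , drop = FALSE]) /
        sum(w[rows])
    }
    num <- t(pw) %*% X0                        # C x J endorsed mass
    den <- t(pw) %*% M                         # C x J observed mass
    rho_new <- ifelse(den > 0, num / den, rho)
    mad <- max(abs(c(gamma_new - gamma, rho_new - rho)))
    gamma <- gamma_new
    rho <- rho_new
    if (mad < config$mad_tol) break
  }
  # Final log-likelihood at the returned parameters.
  rho_c <- clamp_rho(rho, config$rho_floor)
  lp <- X0 %*% t(log(rho_c)) + (M - X0) %*% t(log1p(-rho_c)) +
    log(pmax(gamma, 1e-300))[gi, , drop = FALSE]
  ll <- sum(w * logsumexp_rows(lp))
  trace[iter + 1L] <- ll
  list(gamma = gamma, rho = rho, loglik = ll,
       converged = mad < config$mad_tol, final_mad = mad,
       n_iter = iter, trace = trace)
}

# Shared multi-start driver. Returns the best em_run plus its start seed.
em_multistart <- function(cp, C, G, config, fixed_init = NULL) {
  J <- ncol(cp$X)
  best <- NULL
  best_seed <- NA_integer_
  for (s in seq_len(config$n_starts)) {
    start_seed <- config$seed + s - 1L
    set.seed(start_seed)
    ini <- init_params(C, J, G)
    run <- em_run(cp, ini$gamma, ini$rho, config, NULL)
    if (is.null(best) || run$loglik > best$loglik) {
      best <- run
      best_seed <- start_seed
    }
  }
  best$best_start_seed <- best_seed
  best
}

#' Fit a latent class model by multi-start EM
#'
#' Maximum-likelihood estimation of a C-class model of J binary items under
#' conditional independence. Each start iterates the E-step (posterior class
#' responsibilities) and M-step (gamma = mean responsibility; rho = the
#' responsibility-weighted endorsement rate over records where the item is
#' observed) until the maximum absolute parameter deviation (MAD) between
#' iterations falls below `mad_tol`. Missing items are marginalized out
#' (MAR); records with every item missing are excluded. The best start by
#' log-likelihood is returned with classes sorted by ascending mean rho
#' (minor to major severity).
#'
#' @param data A [response_matrix()].
#' @param n_classes_fit Number of latent classes C (>= 1).
#' @param config An [em_config()].
#' @return An object of class `lca_fit`: `params`, `loglik`, `n_params`,
#'   goodness-of-fit fields (`gsq`, `xsq`, `df`, `gof_p` from the
#'   complete-case pattern table), `aic`/`bic` (G-squared-based) and
#'   `aic_ll`/`bic_ll` (deviance-based, reported for transparency),
#'   `converged`, `best_start_seed`, `final_mad`, `n_used`, `n_iter`,
#'   `trace` (per-iteration log-likelihood of the best start).
#' @export
fit_em <- function(data, n_classes_fit, config) {
  stopifnot(inherits(data, "response_matrix"), inherits(config, "em_config"))
  C <- as.integer(n_classes_fit)
  if (C < 1L) stop("n_classes_fit must be >= 1")
  cp <- collapse_patterns(data$items)
  if (cp$n_used < 1L) stop("no record has an observed item")
  n_distinct <- nrow(cp$X)
  if (C > n_distinct) {
    warning("n_classes_fit (", C, ") exceeds the ", n_distinct,
            " distinct observed patterns; the model is not identifiable")
  }
  J <- ncol(cp$X)
  if (C == 1L) {
    # Closed-form MLE: rho_j is the observed mean of item j.
    M <- 1 - is.na(cp$X)
    X0 <- ifelse(is.na(cp$X), 0, cp$X)
    rho <- matrix(colSums(cp$counts * X0) / colSums(cp$counts * M), 1L, J)
    params <- lca_params(1, rho, item_names = data$item_names)
    ll <- log_likelihood(params, data)
    best <- list(loglik = ll, converged = TRUE, final_mad = 0,
                 n_iter = 0L, trace = ll, best_start_seed = config$seed)
  } else {
    best <- em_multistart(cp, C, 1L, config)
    params <- lca_params(best$gamma[1L, ], best$rho,
                         item_names = data$item_names)
    params <- sort_classes(params, class_names = severity_labels(C))
  }
  finish_fit(params, best, data, cp$n_used, config)
}

# Assemble an lca_fit from a parameter set and the winning EM run.
finish_fit <- function(params, best, data, n_used, config) {
  C <- n_classes(params)
  J <- n_items(params)
  np <- count_free_parameters(C, J)
  tab <- pattern_table(data)
  gof <- if (tab$n_complete > 0L) goodness_of_fit(params, tab, np)
         else list(gsq = NA_real_, xsq = NA_real_, df = NA_integer_,
                   p = NA_real_, saturated = NA)
  ic <- information_criteria(gof$gsq, np, n_used)
  structure(list(
    params = params, loglik = best$loglik, n_params = np,
    gsq = gof$gsq, xsq = gof$xsq, df = gof$df, gof_p = gof$p,
    saturated = isTRUE(gof$saturated),
    aic = ic[["aic"]], bic = ic[["bic"]],
    aic_ll = -2 * best$loglik + 2 * np,
    bic_ll = -2 * best$loglik + log(n_used) * np,
    converged = best$converged, best_start_seed = best$best_start_seed,
    final_mad = best$final_mad, n_used = n_used,
    n_iter = best$n_iter, trace = best$trace,
    config = config
  ), class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat("<lca_fit> C = ", n_classes(x$params), ", J = ", n_items(x$params),
      ", n_used = ", x$n_used, "\n", sep = "")
  cat(sprintf("  loglik %.3f | G2 %.3f (df %s, p %s) | AIC %.2f | BIC %.2f\n",
              x$loglik, x$gsq, format(x$df),
              ifelse(is.na(x$gof_p), "NA", sprintf("%.3f", x$gof_p)),
              x$aic, x$bic))
  cat("  converged: ", x$converged, " (final MAD ",
      format(x$final_mad, digits = 3), ", ", x$n_iter, " iterations)\n",
      sep = "")
  print(x$params)
  invisible(x)
}
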