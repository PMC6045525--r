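# Likelihood machinery for the mixture of independent Bernoulli items.
# Missing items are marginalized out of each record's pattern probability
# (MAR), so a fully missing record has probability 1.

# Row-wise log-sum-exp, tolerating -Inf columns.
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx_safe <- ifelse(is.finite(mx), mx, 0)
  mx_safe + log(rowSums(exp(m - mx_safe)))
}

clamp_rho <- function(rho, floor) pmin(pmax(rho, floor), 1 - floor)

# Per-class log probability of each pattern row: an m x C matrix.
# X: m x J matrix in {0,1,NA}. Items with NA are skipped.
class_log_prob <- function(params, X, rho_floor = 0) {
  rho <- clamp_rho(params$rho, rho_floor)
  M <- 1 - is.na(X)               # observed mask
  X0 <- ifelse(is.na(X), 0, X)    # NA -> 0 (masked out below)
  # log P(pattern | class c) = sum_j obs [x log rho + (1-x) log(1-rho)]
  lr <- t(log(rho))               # J x C
  lq <- t(log1p(-rho))
  lr[!is.finite(lr)] <- -Inf
  lq[!is.finite(lq)] <- -Inf
  A <- X0 %*% lr                  # may produce NaN from 0 * -Inf
  B <- (M - X0) %*% lq
  # 0 * -Inf (unobserved or unendorsed item against rho = 0/1) must count as 0:
  # recompute the rare non-finite cells exactly.
  out <- A + B
  bad <- which(!is.finite(out) | is.nan(out))
  if (length(bad) > 0L) {
    for (k in bad) {
      i <- ((k - 1L) %% nrow(out)) + 1L
      cc <- ((k - 1L) %/% nrow(out)) + 1L
      obs <- which(!is.na(X[i, ]))
      v <- 0
      for (j in obs) {
        v <- v + if (X[i, j] == 1L) log(rho[cc, j]) else log1p(-rho[cc, j])
      }
      out[i, cc] <- v
    }
  }
  out
}

# Collapse records to unique (pattern, group) rows with counts. Records with
# every item missing are dropped (they contribute nothing to the likelihood).
collapse_patterns <- function(items, group = NULL) {
  keep <- rowSums(!is.na(items)) > 0L
  items <- items[keep, , drop = FALSE]
  grp <- if (is.null(group)) rep(1L, nrow(items)) else as.integer(group[keep])
  key <- paste(grp, apply(items, 1L, function(r)
    paste(ifelse(is.na(r), "m", r), collapse = "")), sep = "|")
  idx <- !duplicated(key)
  list(
    X = items[idx, , drop = FALSE],
    group = grp[idx],
    counts = as.numeric(table(factor(key, levels = key[idx]))),
    n_used = nrow(items),
    n_dropped = sum(!keep)
  )
}

#' Log probability of a single response pattern
#'
#' The mixture probability of one observed pattern,
#' `P(x) = sum_c gamma_c prod_{j observed} rho_cj^x_j (1-rho_cj)^(1-x_j)`,
#' on the log scale via log-sum-exp. Missing items are marginalized out, so
#' a fully missing pattern has log probability 0.
#'
#' @param params An [lca_params()] object.
#' @param pattern Vector of length J over {0, 1, NA}.
#' @return The log mixture probability (finite whenever some class assigns
#'   the pattern nonzero mass).
#' @export
pattern_log_probability <- function(params, pattern) {
  stopifnot(inherits(params, "lca_params"))
  if (length(pattern) != n_items(params)) {
    stop("pattern length ", length(pattern), " does not match J = ",
         n_items(params))
  }
  X <- matrix(as.integer(pattern), 1L)
  lp <- class_log_prob(params, X) + rep(log(params$gamma), each = 1L)
  as.numeric(logsumexp_rows(lp))
}

#' Observed-data log-likelihood
#'
#' Sum of [pattern_log_probability()] over all records; records with every
#' item missing contribute 0. Computation collapses to unique patterns
#' for speed.
#'
#' @param params An [lca_params()] object.
#' @param data A [response_matrix()] with matching J.
#' @return The log-likelihood (0 for empty data, with a warning).
#' @export
log_likelihood <- function(params, data) {
  stopifnot(inherits(params, "lca_params"), inherits(data, "response_matrix"))
  if (ncol(data$items) != n_items(params)) {
    stop("data and params disagree on the number of items")
  }
  if (nrow(data$items) == 0L) {
    warning("empty data: log-likelihood is 0")
    return(0)
  }
  cp <- collapse_patterns(data$items)
  if (cp$n_used == 0L) return(0)
  lp <- class_log_prob(params, cp$X) +
    matrix(log(params$gamma), nrow(cp$X), n_classes(params), byrow = TRUE)
  sum(cp$counts * logsumexp_rows(lp))
}

#' Posterior class probabilities and modal assignment
#'
#' Bayes' theorem per record: posterior for class c is proportional to
#' `gamma_c` times the class-conditional pattern probability over the
#' record's observed items. Each subject is assigned to the class with the
#' highest posterior probability (ties broken toward the lowest class index).
#'
#' @param params An [lca_params()] object.
#' @param data A [response_matrix()].
#' @return A list of class `lca_posterior`: `probs` (n x C matrix, rows
#'   summing to 1) and `assigned` (integer class indices).
#' @export
posterior_probabilities <- function(params, data) {
  stopifnot(inherits(params, "lca_params"), inherits(data, "response_matrix"))
  X <- data$items
  C <- n_classes(params)
  lp <- class_log_prob(params, X) +
    matrix(log(params$gamma), nrow(X), C, byrow = TRUE)
  tot <- logsumexp_rows(lp)
  if (any(!is.finite(tot))) {
    stop("record ", which(!is.finite(tot))[1L],
         " has zero probability under every class")
  }
  probs <- exp(lp - tot)
  probs <- probs / rowSums(probs)
  colnames(probs) <- params$class_names
  assigned <- max.col(probs, ties.method = "first")
  structure(list(probs = probs, assigned = assigned),
            class = "lca_posterior")
}
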