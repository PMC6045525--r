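# Prevalence descriptives: Wilson intervals, chi-square homogeneity across
# groups (asymptotic or fixed-margin Monte Carlo), pairwise column-proportion
# comparisons with compact letter subscripts, and an inclusion-exclusion
# utility relating union ("pain at any of ...") probabilities to the joint
# pattern distribution.

#' Per-group success counts
#'
#' @param group_names G labels.
#' @param successes,totals Integer vectors; `0 <= successes <= totals`,
#'   `totals >= 1`.
#' @return An object of class `group_counts`.
#' @export
group_counts <- function(group_names, successes, totals) {
  successes <- as.integer(successes)
  totals <- as.integer(totals)
  if (length(successes) != length(group_names) ||
      length(totals) != length(group_names)) {
    stop("group_names, successes and totals must have equal length")
  }
  if (any(totals < 1L)) stop("every total must be >= 1")
  if (any(successes < 0L | successes > totals)) {
    stop("successes must lie in [0, total] for every group")
  }
  structure(list(group_names = group_names, successes = successes,
                 totals = totals),
            class = "group_counts")
}

#' Prevalence with a Wilson score interval
#'
#' Point estimate `successes/total` with the Wilson score interval (the
#' score-test inversion; asymmetric, always inside \[0, 1\]).
#'
#' @param successes,total Counts, `0 <= successes <= total`, `total >= 1`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Named numeric vector `c(estimate=, lower=, upper=)`.
#' @export
prevalence_with_ci <- function(successes, total, level = 0.95) {
  if (total < 1L || successes < 0L || successes > total) {
    stop("require 0 <= successes <= total and total >= 1")
  }
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  ci <- stats::prop.test(successes, total, conf.level = level,
                         correct = FALSE)$conf.int
  c(estimate = successes / total, lower = ci[1L], upper = ci[2L])
}

#' Chi-square homogeneity test of G proportions
#'
#' Pearson chi-square on the G x 2 success/failure table. `method =
#' "asymptotic"` uses the chi-square tail with G - 1 df; `method =
#' "monte_carlo"` estimates the exact-style p from `n_rep` resampled tables
#' with fixed margins, `p = (1 + #\{stat* >= stat\}) / (n_rep + 1)`,
#' reproducible given the seed.
#'
#' @param counts A [group_counts()] object with G >= 2 groups.
#' @param method `"asymptotic"` or `"monte_carlo"`.
#' @param seed Integer seed (Monte Carlo only).
#' @param n_rep Number of Monte Carlo resamples (default 1e5).
#' @return A list: `statistic`, `df` (NA for Monte Carlo), `p`, `method`.
#' @export
homogeneity_test <- function(counts, method = c("asymptotic", "monte_carlo"),
                             seed = NULL, n_rep = 1e5) {
  stopifnot(inherits(counts, "group_counts"))
  method <- match.arg(method)
  G <- length(counts$group_names)
  if (G < 2L) stop("homogeneity test needs at least 2 groups")
  tab <- cbind(yes = counts$successes, no = counts$totals - counts$successes)
  if (method == "asymptotic") {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ht$statistic), df = G - 1L,
         p = unname(ht$p.value), method = method)
  } else {
    if (is.null(seed)) stop("monte_carlo requires an explicit seed")
    set.seed(seed)
    ht <- suppressWarnings(
      stats::chisq.test(tab, simulate.p.value = TRUE, B = as.integer(n_rep)))
    list(statistic = unname(ht$statistic), df = NA_integer_,
         p = unname(ht$p.value), method = method)
  }
}

# Two-sided pooled two-proportion z-test p-value.
two_prop_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  if (se == 0) return(1)
  2 * stats::pnorm(abs(p1 - p2) / se, lower.tail = FALSE)
}

#' Compact letter display of pairwise column-proportion comparisons
#'
#' Runs all G(G-1)/2 two-proportion z-tests with Bonferroni adjustment at
#' `alpha`, then assigns subscript letters by the insert-and-absorb
#' procedure so that two groups share a letter exactly when their adjusted
#' comparison is non-significant. Mirrors the subscript-letter notation of
#' column-proportion tables.
#'
#' @param counts A [group_counts()] object with G >= 2 groups.
#' @param alpha Family significance level (default 0.05).
#' @return An object of class `letter_display`: `letters` (character vector,
#'   e.g. `"a"`, `"ab"`), `p_matrix` (unadjusted pairwise p-values),
#'   `nonsig` (logical adjacency at the Bonferroni-adjusted level), `alpha`.
#' @export
pairwise_letter_display <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "group_counts"))
  G <- length(counts$group_names)
  if (G < 2L) stop("letter display needs at least 2 groups")
  pm <- matrix(NA_real_, G, G,
               dimnames = list(counts$group_names, counts$group_names))
  for (i in seq_len(G - 1L)) for (j in seq.int(i + 1L, G)) {
    pm[i, j] <- pm[j, i] <- two_prop_z(counts$successes[i], counts$totals[i],
                                       counts$successes[j], counts$totals[j])
  }
  n_pairs <- G * (G - 1L) / 2L
  thresh <- alpha / n_pairs
  nonsig <- pm >= thresh
  diag(nonsig) <- TRUE
  # Insert-and-absorb: letters are maximal cliques-ish column sets built by
  # splitting a column whenever it joins a significantly different pair.
  cols <- list(rep(TRUE, G))   # start with one letter containing everyone
  for (i in seq_len(G - 1L)) for (j in seq.int(i + 1L, G)) {
    if (nonsig[i, j]) next
    k <- 1L
    while (k <= length(cols)) {
      col <- cols[[k]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[k]] <- a
        cols[[length(cols) + 1L]] <- b
      }
      k <- k + 1L
    }
    # absorb: drop columns contained in another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] && all(cols[[a]] <= cols[[b]]) &&
          !identical(cols[[a]], cols[[b]])) {
        keep[a] <- FALSE
      }
    }
    dup <- duplicated(cols)
    cols <- cols[keep & !dup]
  }
  # order letters by first member for a deterministic display
  first <- vapply(cols, function(col) which(col)[1L], integer(1))
  cols <- cols[order(first)]
  letters_out <- vapply(seq_len(G), function(g) {
    paste(letters[which(vapply(cols, function(col) col[g], logical(1)))],
          collapse = "")
  }, character(1))
  names(letters_out) <- counts$group_names
  structure(list(letters = letters_out, p_matrix = pm, nonsig = nonsig,
                 alpha = alpha, adjusted_threshold = thresh),
            class = "letter_display")
}

#' @export
print.letter_display <- function(x, ...) {
  cat("<letter_display> alpha =", x$alpha, "(Bonferroni-adjusted pairwise",
      "threshold", format(x$adjusted_threshold, digits = 3), ")\n")
  print(x$letters)
  invisible(x)
}

# ---- inclusion-exclusion between union probabilities and the joint ----

#' Forward union probabilities of a joint pattern distribution
#'
#' For each non-empty item subset S, the probability that at least one item
#' in S is endorsed. Subsets are indexed by bitmask 1..2^J-1 (bit j = item j).
#'
#' @param joint Numeric vector of length 2^J over complete patterns, indexed
#'   by bitmask + 1 (element `k+1` is the pattern whose endorsed set has
#'   bitmask `k`); must be non-negative and sum to 1.
#' @return Numeric vector of length 2^J - 1 of union probabilities.
#' @export
union_probabilities <- function(joint) {
  n_pat <- length(joint)
  J <- as.integer(round(log2(n_pat)))
  if (2^J != n_pat) stop("joint length must be a power of 2")
  if (any(joint < -1e-12) || abs(sum(joint) - 1) > 1e-9) {
    stop("joint must be a probability distribution over the 2^J patterns")
  }
  masks <- seq_len(n_pat) - 1L
  vapply(seq_len(n_pat - 1L), function(S) {
    sum(joint[bitwAnd(masks, S) != 0L])
  }, numeric(1))
}

#' Joint pattern distribution from subset union probabilities
#'
#' Inverts the union map by inclusion-exclusion: with
#' `zeros(S) = P(all items in S are 0) = 1 - union(S)` and `zeros({}) = 1`,
#' the probability of the pattern endorsing exactly the set O (zero set Z)
#' is `sum_{U subseteq O} (-1)^|U| zeros(Z union U)` (Moebius inversion).
#' An inconsistent union system (one not generated by any joint
#' distribution) yields negative cells and raises an error listing them.
#'
#' @param union_probs Numeric vector of length 2^J - 1, element `S` the
#'   probability that at least one item of the bitmask-S subset is endorsed;
#'   values in \[0, 1\].
#' @param tol Feasibility tolerance for negative cells (default 1e-9).
#' @return Numeric vector of length 2^J over patterns (bitmask + 1 indexed),
#'   summing to 1.
#' @export
joint_from_subset_unions <- function(union_probs, tol = 1e-9) {
  n_sub <- length(union_probs)
  J <- as.integer(round(log2(n_sub + 1)))
  if (2^J - 1L != n_sub) stop("union_probs must have length 2^J - 1")
  if (any(is.na(union_probs))) stop("missing subset probability")
  if (any(union_probs < 0 | union_probs > 1)) {
    stop("union probabilities must lie in [0, 1]")
  }
  zeros <- c(1, 1 - union_probs)            # indexed by bitmask + 1
  n_pat <- 2^J
  full <- n_pat - 1L
  joint <- numeric(n_pat)
  for (ones in 0:(n_pat - 1L)) {
    zero_set <- bitwAnd(full, bitwNot(ones))
    # enumerate subsets U of `ones`
    u <- ones
    s <- 0
    repeat {
      sign <- if (bitwAnd(sum(bitwAnd(2^(0:(J - 1L)), u) > 0L), 1L)) -1 else 1
      s <- s + sign * zeros[bitwOr(zero_set, u) + 1L]
      if (u == 0L) break
      u <- bitwAnd(u - 1L, ones)
    }
    joint[ones + 1L] <- s
  }
  bad <- which(joint < -tol | joint > 1 + tol)
  if (length(bad) > 0L) {
    stop("inconsistent union system: implied joint has out-of-range cells ",
         "at bitmask(s) ", paste(bad - 1L, collapse = ", "),
         " (values ", paste(signif(joint[bad], 4), collapse = ", "), ")")
  }
  joint
}
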