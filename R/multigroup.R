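# Grouped latent class models: group-specific membership probabilities with
# item-response probabilities either shared (measurement invariance) or free,
# and the chi-square difference test between the two.

#' Multigroup latent class parameters
#'
#' Membership probabilities are always group-specific (one gamma row per
#' group); item-response probabilities are either a single C x J matrix
#' shared by all groups (`rho_invariant = TRUE`) or a per-group list of
#' C x J matrices.
#'
#' @param group_names G distinct group labels.
#' @param gamma G x C matrix, each row summing to 1.
#' @param rho A C x J matrix (invariant) or a list of G such matrices (free).
#' @param rho_invariant Flag; inferred from `rho` when missing.
#' @param item_names,class_names Optional labels.
#' @return An object of class `multigroup_params`.
#' @export
multigroup_params <- function(group_names, gamma, rho, rho_invariant = NULL,
                              item_names = NULL, class_names = NULL) {
  gamma <- as.matrix(gamma)
  if (anyDuplicated(group_names)) stop("group_names must be distinct")
  if (nrow(gamma) != length(group_names)) {
    stop("gamma must have one row per group")
  }
  if (any(gamma < 0) || any(abs(rowSums(gamma) - 1) > 1e-10)) {
    stop("each gamma row must be non-negative and sum to 1")
  }
  if (is.null(rho_invariant)) rho_invariant <- !is.list(rho)
  if (rho_invariant) {
    rho <- as.matrix(rho)
    if (any(rho < 0 | rho > 1)) stop("rho entries must lie in [0, 1]")
    J <- ncol(rho)
    if (nrow(rho) != ncol(gamma)) stop("rho rows must equal C")
  } else {
    if (!is.list(rho) || length(rho) != length(group_names)) {
      stop("free rho must be a list with one C x J matrix per group")
    }
    rho <- lapply(rho, as.matrix)
    J <- ncol(rho[[1L]])
    for (r in rho) {
      if (any(r < 0 | r > 1) || nrow(r) != ncol(gamma) || ncol(r) != J) {
        stop("every free rho matrix must be C x J with entries in [0, 1]")
      }
    }
    names(rho) <- group_names
  }
  if (is.null(item_names)) item_names <- paste0("item", seq_len(J))
  if (is.null(class_names)) class_names <- paste0("class", seq_len(ncol(gamma)))
  dimnames(gamma) <- list(group_names, class_names)
  if (rho_invariant) {
    dimnames(rho) <- list(class_names, item_names)
  } else {
    rho <- lapply(rho, function(r) {
      dimnames(r) <- list(class_names, item_names)
      r
    })
    names(rho) <- group_names
  }
  structure(list(group_names = group_names, gamma = gamma, rho = rho,
                 rho_invariant = rho_invariant, item_names = item_names,
                 class_names = class_names),
            class = "multigroup_params")
}

#' Extract one group's single-group parameter set
#'
#' @param params A [multigroup_params()] object.
#' @param g Group index or name.
#' @return An [lca_params()] object for that group.
#' @export
group_params <- function(params, g) {
  stopifnot(inherits(params, "multigroup_params"))
  if (is.character(g)) g <- match(g, params$group_names)
  rho <- if (params$rho_invariant) params$rho else params$rho[[g]]
  lca_params(params$gamma[g, ], rho, item_names = params$item_names,
             class_names = params$class_names)
}

#' @export
print.multigroup_params <- function(x, digits = 3, ...) {
  cat("<multigroup_params> ", length(x$group_names), " groups, ",
      ncol(x$gamma), " classes, rho ",
      if (x$rho_invariant) "invariant" else "group-specific", "\n", sep = "")
  cat("gamma (rows = groups):\n")
  print(round(x$gamma, digits))
  invisible(x)
}

#' Degrees of freedom of the invariance test
#'
#' The parameter-count difference between the free-rho and invariant-rho
#' multigroup models: `(G - 1) * C * J`.
#'
#' @param C,J,G Positive integers.
#' @return Integer df (0 when G = 1).
#' @export
invariance_df <- function(C, J, G) {
  if (G < 1L) stop("G must be >= 1")
  as.integer((G - 1L) * C * J)
}

# Stacked per-group goodness of fit: G2/X2 summed over the groups' own
# pattern tables, df = G * (2^J - 1) - n_params.
multigroup_gof <- function(params, data, n_params) {
  groups <- params$group_names
  gsq <- 0
  xsq <- 0
  n_complete <- 0L
  for (g in seq_along(groups)) {
    sub <- subset_records(data, data$group == groups[g])
    tab <- pattern_table(sub)
    if (tab$n_complete == 0L) next
    gof_g <- goodness_of_fit(group_params(params, g), tab, n_params = 0L)
    gsq <- gsq + gof_g$gsq
    xsq <- xsq + gof_g$xsq
    n_complete <- n_complete + tab$n_complete
  }
  J <- length(params$item_names)
  df <- as.integer(length(groups) * (2^J - 1L) - n_params)
  saturated <- df <= 0L
  p <- if (saturated) NA_real_ else chi_square_tail(max(gsq, 0), df)
  list(gsq = gsq, xsq = xsq, df = df, p = p, saturated = saturated,
       n_complete = n_complete)
}

#' Fit a multigroup latent class model
#'
#' Maximizes the joint likelihood over all groups with group-specific
#' membership probabilities. With `rho_invariant = TRUE` the item-response
#' probabilities are shared: EM pools the responsibility-weighted item
#' counts across groups in the rho M-step. With `rho_invariant = FALSE` the
#' model factorizes over groups, so it is fitted as independent per-group
#' runs (seeded deterministically from `config$seed` and the group index)
#' and the per-group solutions are label-aligned to a reference.
#'
#' Records with a missing group label are eliminated first.
#'
#' @param data A [response_matrix()] with group labels.
#' @param n_classes_fit Number of classes C.
#' @param rho_invariant Share rho across groups?
#' @param config An [em_config()].
#' @param align_to Optional [lca_params()] whose rho defines the class order
#'   (used to align free per-group fits; defaults to sorting by mean rho).
#' @return An object of class `multigroup_fit`: `params`
#'   ([multigroup_params()]), `loglik`, `n_params`, stacked `gsq`/`xsq`/
#'   `df`/`gof_p`, `aic`/`bic`, `converged`, `n_used`, `group_n`.
#' @export
fit_multigroup <- function(data, n_classes_fit, rho_invariant, config,
                           align_to = NULL) {
  stopifnot(inherits(data, "response_matrix"), inherits(config, "em_config"))
  if (is.null(data$group)) stop("data carries no group labels")
  C <- as.integer(n_classes_fit)
  if (C < 1L) stop("n_classes_fit must be >= 1")
  declared <- levels(data$group)
  data <- drop_missing_group(data, quiet = TRUE)
  retained <- table(factor(data$group, levels = declared))
  if (any(retained == 0L)) {
    stop("empty group after elimination: ",
         names(retained)[retained == 0L][1L])
  }
  groups <- levels(data$group)
  G <- length(groups)
  group_n <- table(data$group)
  J <- ncol(data$items)
  np <- count_free_parameters(C, J, G, rho_invariant)

  if (rho_invariant) {
    cp <- collapse_patterns(data$items, data$group)
    best <- em_multistart(cp, C, G, config)
    gamma <- best$gamma
    rho <- best$rho
    # Sort classes by ascending mean rho for reporting.
    ord <- if (is.null(align_to)) order(rowMeans(rho))
           else attr(align_classes(
             lca_params(rep(1 / C, C), rho), align_to), "perm")
    params <- multigroup_params(groups, gamma[, ord, drop = FALSE],
                                rho[ord, , drop = FALSE],
                                rho_invariant = TRUE,
                                item_names = data$item_names,
                                class_names = if (is.null(align_to))
                                  severity_labels(C) else align_to$class_names)
    loglik <- best$loglik
    converged <- best$converged
    final_mad <- best$final_mad
    n_used <- cp$n_used
  } else {
    # Free model: independent per-group fits maximize the joint likelihood.
    ref <- align_to
    fits <- vector("list", G)
    for (g in seq_len(G)) {
      sub <- subset_records(data, data$group == groups[g])
      cfg_g <- config
      cfg_g$seed <- config$seed + 1000L * (g - 1L)
      fits[[g]] <- fit_em(sub, C, cfg_g)
      if (is.null(ref)) ref <- fits[[g]]$params
      fits[[g]]$params <- align_classes(fits[[g]]$params, ref)
    }
    params <- multigroup_params(
      groups,
      gamma = do.call(rbind, lapply(fits, function(f) f$params$gamma)),
      rho = lapply(fits, function(f) f$params$rho),
      rho_invariant = FALSE, item_names = data$item_names,
      class_names = ref$class_names
    )
    loglik <- sum(vapply(fits, function(f) f$loglik, numeric(1)))
    converged <- all(vapply(fits, function(f) f$converged, logical(1)))
    final_mad <- max(vapply(fits, function(f) f$final_mad, numeric(1)))
    n_used <- sum(vapply(fits, function(f) f$n_used, numeric(1)))
  }

  gof <- multigroup_gof(params, data, np)
  ic <- information_criteria(gof$gsq, np, n_used)
  structure(list(
    params = params, loglik = loglik, n_params = np,
    gsq = gof$gsq, xsq = gof$xsq, df = gof$df, gof_p = gof$p,
    saturated = isTRUE(gof$saturated),
    aic = ic[["aic"]], bic = ic[["bic"]],
    aic_ll = -2 * loglik + 2 * np,
    bic_ll = -2 * loglik + log(n_used) * np,
    converged = converged, final_mad = final_mad,
    n_used = n_used, group_n = group_n, config = config
  ), class = "multigroup_fit")
}

#' @export
print.multigroup_fit <- function(x, ...) {
  cat("<multigroup_fit> G = ", length(x$params$group_names),
      ", C = ", ncol(x$params$gamma), ", rho ",
      if (x$params$rho_invariant) "invariant" else "free",
      ", n_used = ", x$n_used, "\n", sep = "")
  cat(sprintf("  loglik %.3f | G2 %.3f (df %s) | AIC %.2f | BIC %.2f\n",
              x$loglik, x$gsq, format(x$df), x$aic, x$bic))
  print(x$params)
  invisible(x)
}

#' Chi-square difference test of measurement invariance
#'
#' Fits the constrained model (item-response probabilities equal across
#' groups) and the free model (group-specific rho), aligning the free
#' per-group solutions to the constrained rho, and tests the constraint by
#' the likelihood-ratio difference `Chi2_dif = G2_constrained - G2_free`
#' (identically `2 * (loglik_free - loglik_constrained)`, floored at 0)
#' against a chi-square with `(G - 1) * C * J` degrees of freedom.
#'
#' @param data A [response_matrix()] with group labels.
#' @param n_classes_fit Number of classes C.
#' @param config An [em_config()].
#' @return An object of class `invariance_result`: `chisq_diff`, `df_diff`,
#'   `p_value`, `free_fit`, `constrained_fit`, `converged`.
#' @export
invariance_test <- function(data, n_classes_fit, config) {
  constrained <- fit_multigroup(data, n_classes_fit,
                                rho_invariant = TRUE, config = config)
  ref <- lca_params(colMeans(constrained$params$gamma),
                    constrained$params$rho,
                    item_names = constrained$params$item_names,
                    class_names = constrained$params$class_names)
  free <- fit_multigroup(data, n_classes_fit, rho_invariant = FALSE,
                         config = config, align_to = ref)
  G <- length(constrained$params$group_names)
  C <- as.integer(n_classes_fit)
  J <- length(constrained$params$item_names)
  chisq_diff <- max(0, 2 * (free$loglik - constrained$loglik))
  df_diff <- invariance_df(C, J, G)
  converged <- constrained$converged && free$converged
  if (!converged) {
    warning("a component fit did not converge; the invariance p-value ",
            "may be unreliable")
  }
  structure(list(chisq_diff = chisq_diff, df_diff = df_diff,
                 p_value = chi_square_tail(chisq_diff, df_diff),
                 free_fit = free, constrained_fit = constrained,
                 converged = converged),
            class = "invariance_result")
}

#' @export
print.invariance_result <- function(x, ...) {
  cat(sprintf(
    "<invariance_result> Chi2_dif (%d) = %.2f, p = %.3f%s\n",
    x$df_diff, x$chisq_diff, x$p_value,
    if (x$converged) "" else "  [non-converged component]"))
  invisible(x)
}
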