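# End-to-end driver: simulate or ingest subject-level data, descriptive
# prevalence tables per grouping, class enumeration on the pooled data,
# multigroup fits and invariance tests per grouping variable, and rendering
# of report tables shaped like the published ones. The numbered scripts
# under analysis/ are thin narrative wrappers over these functions.

#' Analysis configuration
#'
#' Either `fixture` (simulate a dataset from a packaged parameter fixture)
#' or `input` (a delimited subject-level file) must be given.
#'
#' @param fixture Fixture name for [simulate_lca()], or `NULL`.
#' @param input Path to a subject-level CSV, or `NULL`.
#' @param item_names Item columns (default the four pain indicators).
#' @param group_columns Character vector of grouping columns in `input`;
#'   ignored for fixtures (the fixture's grouping — plus gender and age
#'   margins for the gender-age fixture — is used).
#' @param n_total,sim_seed,missing_rates Simulation settings (fixture mode).
#' @param c_min,c_max Candidate class range for enumeration (default 2-4).
#' @param em An [em_config()].
#' @param alpha Significance level for descriptive comparisons.
#' @param mc_seed,mc_rep Monte Carlo settings for the homogeneity test.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(fixture = NULL, input = NULL,
                            item_names = c("neck", "shoulder",
                                           "upper_back", "low_back"),
                            group_columns = NULL,
                            n_total = 1611L, sim_seed = NULL,
                            missing_rates = 0.02,
                            c_min = 2L, c_max = 4L,
                            em = NULL, alpha = 0.05,
                            mc_seed = NULL, mc_rep = 1e4) {
  if (is.null(fixture) == is.null(input)) {
    stop("exactly one of 'fixture' or 'input' must be given")
  }
  if (is.null(em)) stop("an em_config() is required")
  if (!is.null(fixture) && is.null(sim_seed)) {
    stop("fixture mode requires sim_seed")
  }
  structure(list(fixture = fixture, input = input, item_names = item_names,
                 group_columns = group_columns, n_total = n_total,
                 sim_seed = sim_seed, missing_rates = missing_rates,
                 c_min = c_min, c_max = c_max, em = em, alpha = alpha,
                 mc_seed = if (is.null(mc_seed)) em$seed else mc_seed,
                 mc_rep = mc_rep),
            class = "analysis_config")
}

# Derive gender / age margins from the four gender-age stratum labels.
derive_margins <- function(group) {
  lv <- as.character(group)
  gender <- factor(sub("_(le13|ge14)$", "", lv),
                   levels = unique(sub("_(le13|ge14)$", "", levels(group))))
  age <- factor(sub("^(girl|boy)_", "", lv),
                levels = unique(sub("^(girl|boy)_", "", levels(group))))
  list(gender = gender, age = age)
}

#' Run the full analysis pipeline
#'
#' Executes, deterministically given the config seeds: (1) elimination of
#' records with missing group labels, (2) per-group prevalence descriptives
#' with homogeneity tests and letter displays, (3) class enumeration on the
#' pooled data over the candidate range, (4) for each grouping variable a
#' constrained and free multigroup fit at the selected C plus the
#' measurement-invariance test (the selected C is reused for every grouping,
#' as in the source study), (5) assembly of a report bundle.
#'
#' @param config An [analysis_config()].
#' @return A list of class `report_bundle`: `data_summary`, `descriptives`
#'   (per grouping, per item), `selection` ([select_classes()] report),
#'   `grouped` (per grouping: `fit_constrained`, `fit_free`, `invariance`),
#'   `metadata`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  t0 <- Sys.time()
  if (!is.null(config$fixture)) {
    fx <- load_fixture(config$fixture)
    data <- simulate_lca(fx, n_total = config$n_total,
                         seed = config$sim_seed,
                         missing_rates = config$missing_rates)
    groupings <- list()
    groupings[[config$fixture]] <- data$group
    if (config$fixture == "table5_gender_age") {
      m <- derive_margins(data$group)
      groupings$gender <- m$gender
      groupings$age <- m$age
      groupings$gender_age <- data$group
      groupings[[config$fixture]] <- NULL
    }
    items <- data$items
  } else {
    raw <- utils::read.csv(config$input, na.strings = c("NA", ""),
                           check.names = FALSE)
    missing_cols <- setdiff(c(config$item_names, config$group_columns),
                            names(raw))
    if (length(missing_cols) > 0L) {
      stop("column(s) absent from input: ",
           paste(missing_cols, collapse = ", "))
    }
    items <- as.matrix(raw[config$item_names])
    groupings <- lapply(raw[config$group_columns], factor)
    if (length(groupings) == 0L) stop("at least one group column is required")
  }

  pooled <- response_matrix(items, item_names = config$item_names)
  n_read <- nrow(items)

  # (1)+(2): per grouping, eliminate missing-label records, descriptives
  descriptives <- list()
  grouped_data <- list()
  for (gname in names(groupings)) {
    dat_g <- drop_missing_group(
      response_matrix(items, item_names = config$item_names,
                      group = groupings[[gname]]), quiet = TRUE)
    grouped_data[[gname]] <- dat_g
    descriptives[[gname]] <- descriptives_table(dat_g, alpha = config$alpha,
                                                mc_seed = config$mc_seed,
                                                mc_rep = config$mc_rep)
  }

  # (3) class enumeration on pooled data
  selection <- select_classes(pooled, config$c_min, config$c_max, config$em)
  C_sel <- selection$selected_C

  # (4) multigroup fits + invariance per grouping
  grouped <- list()
  for (gname in names(groupings)) {
    inv <- invariance_test(grouped_data[[gname]], C_sel, config$em)
    grouped[[gname]] <- list(fit_constrained = inv$constrained_fit,
                             fit_free = inv$free_fit,
                             invariance = inv)
  }

  structure(list(
    data_summary = list(n_read = n_read,
                        n_complete = sum(stats::complete.cases(items)),
                        item_names = config$item_names,
                        groupings = lapply(groupings, function(g)
                          table(g, useNA = "ifany"))),
    descriptives = descriptives,
    selection = selection,
    grouped = grouped,
    metadata = list(config = config,
                    package_version = as.character(utils::packageVersion("mglca")),
                    selected_C = C_sel,
                    elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")))
  ), class = "report_bundle")
}

#' Per-group prevalence descriptives for every item
#'
#' For each item: per-group prevalence with Wilson CI, the chi-square
#' homogeneity test across groups (asymptotic and seeded Monte Carlo), and
#' the compact letter display of pairwise column comparisons.
#'
#' @param data A [response_matrix()] with group labels.
#' @param alpha Significance level for the letter display.
#' @param mc_seed,mc_rep Monte Carlo homogeneity settings (`mc_seed = NULL`
#'   skips the Monte Carlo p).
#' @return A data frame, one row per item x group, plus per-item attributes.
#' @export
descriptives_table <- function(data, alpha = 0.05, mc_seed = NULL,
                               mc_rep = 1e4) {
  stopifnot(inherits(data, "response_matrix"))
  if (is.null(data$group)) stop("descriptives need group labels")
  groups <- levels(data$group)
  rows <- list()
  for (j in seq_along(data$item_names)) {
    x <- data$items[, j]
    succ <- tapply(x, data$group, function(v) sum(v == 1L, na.rm = TRUE))
    tot <- tapply(x, data$group, function(v) sum(!is.na(v)))
    gc <- group_counts(groups, succ[groups], tot[groups])
    ht <- homogeneity_test(gc, "asymptotic")
    p_mc <- if (!is.null(mc_seed)) {
      homogeneity_test(gc, "monte_carlo",
                       seed = mc_seed + j, n_rep = mc_rep)$p
    } else NA_real_
    ld <- pairwise_letter_display(gc, alpha = alpha)
    ci <- t(vapply(seq_along(groups), function(g)
      prevalence_with_ci(gc$successes[g], gc$totals[g]), numeric(3)))
    rows[[j]] <- data.frame(
      item = data$item_names[j], group = groups,
      n = gc$successes, total = gc$totals,
      prevalence = ci[, 1L], lower = ci[, 2L], upper = ci[, 3L],
      letters = unname(ld$letters),
      chisq = ht$statistic, p_asymptotic = ht$p, p_monte_carlo = p_mc,
      row.names = NULL
    )
  }
  do.call(rbind, rows)
}

# "0.88" / "< 0.01" probability formatting used by the published tables.
format_prob <- function(x) {
  ifelse(is.na(x), "", ifelse(x < 0.01, "< 0.01", sprintf("%.2f", x)))
}

#' Render a report bundle to delimited and formatted-text tables
#'
#' Writes, under `outdir`: `selection.tsv` (class-enumeration trace),
#' `descriptives_<grouping>.tsv`, `params_<grouping>.tsv` (membership and
#' item-response probabilities per class and group, probabilities formatted
#' with the "< 0.01" convention) with the invariance footnote line, and
#' `metadata.json`.
#'
#' @param bundle A [run_analysis()] result.
#' @param outdir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
render_reports <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) stop("cannot create directory ", outdir)
  }
  written <- character(0)
  w <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
    path
  }
  w(bundle$selection$rule_trace, "selection.tsv")
  for (gname in names(bundle$descriptives)) {
    df <- bundle$descriptives[[gname]]
    df$prevalence_pct <- sprintf("%.1f%%", 100 * df$prevalence)
    df$ci_pct <- sprintf("%.1f-%.1f%%", 100 * df$lower, 100 * df$upper)
    w(df, paste0("descriptives_", gname, ".tsv"))
  }
  for (gname in names(bundle$grouped)) {
    gr <- bundle$grouped[[gname]]
    params <- gr$fit_free$params
    groups <- params$group_names
    cls <- params$class_names
    rows <- list()
    for (g in seq_along(groups)) {
      pg <- group_params(params, g)
      rows[[length(rows) + 1L]] <- data.frame(
        group = groups[g], quantity = "membership",
        t(setNames(sprintf("%.1f%%", 100 * pg$gamma), cls)),
        check.names = FALSE)
      for (j in seq_along(params$item_names)) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = groups[g], quantity = params$item_names[j],
          t(setNames(format_prob(pg$rho[, j]), cls)),
          check.names = FALSE)
      }
    }
    path <- w(do.call(rbind, rows), paste0("params_", gname, ".tsv"))
    inv <- gr$invariance
    cat(sprintf("# invariance: Chi2_dif (%d) = %.2f, p = %.3f\n",
                inv$df_diff, inv$chisq_diff, inv$p_value),
        file = path, append = TRUE)
  }
  meta <- bundle$metadata
  meta$config$em <- unclass(meta$config$em)
  meta$config <- unclass(meta$config)
  path <- file.path(outdir, "metadata.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  written <- c(written, path)
  invisible(written)
}
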