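# Seeded synthetic-data generator. The generative model is the latent class
# likelihood itself: draw a group by the study's stratum fractions, a class
# by that group's membership probabilities, then items independently by the
# class's item-response probabilities, with optional MAR missingness.
# Parameter sets come from packaged fixtures encoding the published tables.

fixture_names <- function() {
  c("table2", "table3_gender", "table4_age", "table5_gender_age")
}

#' Load a packaged parameter fixture
#'
#' Fixtures encode the published membership (gamma) and item-response (rho)
#' probability tables of the three-class model — the general model, the
#' gender-specific, age-specific and gender-age-specific models — exactly as
#' printed, with entries printed as "< 0.01" encoded as 0 and gamma rows
#' renormalized to sum to 1 where printed percentages do not (flagged in
#' `notes`). Items are in the canonical order neck, shoulder, upper back,
#' low back; classes in ascending severity (minor, moderate, major).
#'
#' @param name One of `"table2"`, `"table3_gender"`, `"table4_age"`,
#'   `"table5_gender_age"`.
#' @return An object of class `lca_fixture`: `name`, `params`
#'   ([multigroup_params()]), `group_fractions`, `default_n`,
#'   `invariance_footnote` (published statistic/df/p, when the source table
#'   carries one), `anomaly` (or `NULL`), `notes`.
#' @export
load_fixture <- function(name) {
  if (!name %in% fixture_names()) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixture_names(), collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".json"), package = "mglca",
                      mustWork = TRUE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gamma <- as.matrix(obj$gamma)
  gamma <- gamma / rowSums(gamma)   # printed percentages can sum to 100.1
  G <- length(obj$group_names)
  rho_raw <- obj$rho                # G x C x J array or list of matrices
  rho_list <- if (is.array(rho_raw) && length(dim(rho_raw)) == 3L) {
    lapply(seq_len(G), function(g) matrix(rho_raw[g, , ],
                                          dim(rho_raw)[2L], dim(rho_raw)[3L]))
  } else {
    lapply(rho_raw, as.matrix)
  }
  params <- if (isTRUE(obj$rho_invariant)) {
    multigroup_params(obj$group_names, gamma, rho_list[[1L]],
                      rho_invariant = TRUE, item_names = obj$item_names,
                      class_names = obj$class_names)
  } else {
    multigroup_params(obj$group_names, gamma, rho_list,
                      rho_invariant = FALSE, item_names = obj$item_names,
                      class_names = obj$class_names)
  }
  structure(list(
    name = obj$name, params = params,
    group_fractions = as.numeric(obj$group_fractions),
    default_n = as.integer(obj$default_n),
    invariance_footnote = obj$invariance_footnote,
    anomaly = obj$anomaly, notes = obj$notes
  ), class = "lca_fixture")
}

#' Construct a fixture from explicit parameters
#'
#' Builds the same structure as [load_fixture()] from a parameter set you
#' supply — the route for simulating designed conditions (null models with
#' invariant rho, perturbed-rho power studies, custom strata sizes).
#'
#' @param params A [multigroup_params()] object.
#' @param group_fractions Stratum fractions summing to 1 (default equal).
#' @param default_n Default cohort size for [simulate_lca()].
#' @param name Label carried in the simulated data's metadata.
#' @return An object of class `lca_fixture`.
#' @export
make_fixture <- function(params, group_fractions = NULL,
                         default_n = 1611L, name = "custom") {
  stopifnot(inherits(params, "multigroup_params"))
  G <- length(params$group_names)
  if (is.null(group_fractions)) group_fractions <- rep(1 / G, G)
  if (length(group_fractions) != G ||
      abs(sum(group_fractions) - 1) > 1e-9 || any(group_fractions <= 0)) {
    stop("group_fractions must be positive, one per group, and sum to 1")
  }
  structure(list(name = name, params = params,
                 group_fractions = as.numeric(group_fractions),
                 default_n = as.integer(default_n),
                 invariance_footnote = NULL, anomaly = NULL, notes = NULL),
            class = "lca_fixture")
}

#' @export
print.lca_fixture <- function(x, ...) {
  cat("<lca_fixture> ", x$name, ": ", length(x$params$group_names),
      " group(s), ", ncol(x$params$gamma), " classes, default n = ",
      x$default_n, "\n", sep = "")
  if (!is.null(x$anomaly)) cat("  [anomaly] ", x$anomaly, "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Simulate subject-level data from a fixture
#'
#' Draws `n_total` subjects: group by the fixture's stratum fractions, latent
#' class by the group's gamma, items independently by the class's rho, then
#' item-level MAR missingness at `missing_rates` (applied by
#' [inject_missing_mar()] with seed `seed + 1`). Deterministic given `seed`.
#' The true class of every subject is retained as attribute `true_class` for
#' recovery testing (written out only on request, see
#' [write_subject_table()]).
#'
#' @param fixture An [load_fixture()] result (or compatible list).
#' @param n_total Number of subjects (default the fixture's `default_n`).
#' @param seed Integer seed (mandatory).
#' @param missing_rates Per-item MAR missingness rates in \[0, 1); a scalar
#'   is recycled. Default 0.02, emulating the small item-level nonresponse
#'   visible in the study's per-item denominators.
#' @return A [response_matrix()] with group labels and hidden `true_class`.
#' @export
simulate_lca <- function(fixture, n_total = fixture$default_n, seed,
                         missing_rates = 0.02) {
  stopifnot(inherits(fixture, "lca_fixture"))
  if (missing(seed)) stop("an explicit integer seed is required")
  if (n_total < 1L) stop("n_total must be >= 1")
  params <- fixture$params
  G <- length(params$group_names)
  C <- ncol(params$gamma)
  J <- length(params$item_names)
  missing_rates <- rep_len(missing_rates, J)
  if (any(missing_rates < 0 | missing_rates >= 1)) {
    stop("missing rates must lie in [0, 1)")
  }
  set.seed(as.integer(seed))
  grp <- sample.int(G, n_total, replace = TRUE, prob = fixture$group_fractions)
  cl <- integer(n_total)
  for (g in seq_len(G)) {
    idx <- which(grp == g)
    if (length(idx) > 0L) {
      cl[idx] <- sample.int(C, length(idx), replace = TRUE,
                            prob = params$gamma[g, ])
    }
  }
  p <- matrix(0, n_total, J)
  for (g in seq_len(G)) {
    rho_g <- if (params$rho_invariant) params$rho else params$rho[[g]]
    idx <- grp == g
    p[idx, ] <- rho_g[cl[idx], , drop = FALSE]
  }
  items <- matrix(as.integer(matrix(stats::runif(n_total * J), n_total, J) < p),
                  n_total, J)
  out <- response_matrix(items, item_names = params$item_names,
                         group = factor(params$group_names[grp],
                                        levels = params$group_names))
  if (any(missing_rates > 0)) {
    out <- inject_missing_mar(out, missing_rates, seed = as.integer(seed) + 1L)
  }
  attr(out, "true_class") <- cl
  attr(out, "fixture") <- fixture$name
  out
}

#' Inject item-level MAR missingness
#'
#' Each item cell is independently blanked with its item's rate, regardless
#' of the cell's value or the subject's class (missing completely at random
#' given group, hence MAR for the analysis). Group labels are never blanked.
#' Reproducible given the seed.
#'
#' @param data A [response_matrix()].
#' @param rates Per-item rates in \[0, 1); a scalar is recycled.
#' @param seed Integer seed.
#' @return The `response_matrix` with `NA` cells added.
#' @export
inject_missing_mar <- function(data, rates, seed) {
  stopifnot(inherits(data, "response_matrix"))
  J <- ncol(data$items)
  rates <- rep_len(rates, J)
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)")
  set.seed(as.integer(seed))
  n <- nrow(data$items)
  mask <- matrix(stats::runif(n * J), n, J) <
    matrix(rates, n, J, byrow = TRUE)
  items <- data$items
  items[mask] <- NA_integer_
  out <- response_matrix(items, item_names = data$item_names,
                         group = data$group)
  for (a in c("true_class", "fixture")) {
    if (!is.null(attr(data, a))) attr(out, a) <- attr(data, a)
  }
  out
}
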