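#' Latent class model parameters
#'
#' A C-class latent class model for J binary items: class membership
#' probabilities `gamma` (length C, summing to 1) and item-response
#' probabilities `rho` (C x J, each entry the probability that the item is
#' endorsed given the class).
#'
#' @param gamma Numeric vector of C membership probabilities.
#' @param rho Numeric C x J matrix of item-response probabilities.
#' @param item_names Optional J item labels (defaults to colnames of rho).
#' @param class_names Optional C class labels.
#' @return An object of class `lca_params`.
#' @export
lca_params <- function(gamma, rho, item_names = NULL, class_names = NULL) {
  rho <- as.matrix(rho)
  gamma <- as.numeric(gamma)
  if (length(gamma) != nrow(rho)) {
    stop("gamma length must equal the number of rho rows")
  }
  if (any(gamma < 0) || abs(sum(gamma) - 1) > 1e-10) {
    stop("gamma entries must be non-negative and sum to 1")
  }
  if (any(rho < 0 | rho > 1)) stop("rho entries must lie in [0, 1]")
  if (is.null(item_names)) {
    item_names <- colnames(rho)
    if (is.null(item_names)) item_names <- paste0("item", seq_len(ncol(rho)))
  }
  if (is.null(class_names)) class_names <- paste0("class", seq_along(gamma))
  dimnames(rho) <- list(class_names, item_names)
  names(gamma) <- class_names
  structure(
    list(gamma = gamma, rho = rho, item_names = item_names,
         class_names = class_names),
    class = "lca_params"
  )
}

#' @export
print.lca_params <- function(x, digits = 3, ...) {
  cat("<lca_params> ", length(x$gamma), " classes x ",
      ncol(x$rho), " items\n", sep = "")
  cat("gamma:\n")
  print(round(x$gamma, digits))
  cat("rho:\n")
  print(round(x$rho, digits))
  invisible(x)
}

#' Number of classes / items of a parameter set
#' @param params An `lca_params` object.
#' @return Integer count.
#' @export
n_classes <- function(params) length(params$gamma)

#' @rdname n_classes
#' @export
n_items <- function(params) ncol(params$rho)

#' Model-implied marginal item prevalences
#'
#' The marginal probability of endorsing each item under the mixture:
#' entry j is `sum_c gamma_c * rho_cj`. For the packaged three-class
#' estimates this reproduces the study's overall symptom prevalences
#' (e.g. neck 27.9%).
#'
#' @param params An [lca_params()] object.
#' @return Named numeric vector of length J.
#' @export
model_implied_marginals <- function(params) {
  stopifnot(inherits(params, "lca_params"))
  out <- as.numeric(params$gamma %*% params$rho)
  names(out) <- params$item_names
  out
}

#' Sort classes by severity
#'
#' Reorders classes by ascending mean item-response probability, the
#' convention used for the minor / moderate / major pain labels.
#'
#' @param params An [lca_params()] object.
#' @param class_names Optional labels to attach after sorting (lowest mean
#'   rho first).
#' @return A reordered `lca_params` object.
#' @export
sort_classes <- function(params, class_names = NULL) {
  stopifnot(inherits(params, "lca_params"))
  ord <- order(rowMeans(params$rho))
  out <- lca_params(params$gamma[ord], params$rho[ord, , drop = FALSE],
                    item_names = params$item_names,
                    class_names = if (is.null(class_names))
                      params$class_names[ord] else class_names)
  out
}

# Reporting labels in ascending severity: the three-class convention is
# minor / moderate / major pain.
severity_labels <- function(C) {
  if (C == 3L) c("minor", "moderate", "major") else paste0("class", seq_len(C))
}

# All permutations of 1..n as a matrix (n! rows); n is small (C <= 6).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  dimnames(out) <- NULL
  out
}

#' Align class labels to a reference parameter set
#'
#' Mixture classes are identified only up to permutation (label switching).
#' This permutes the classes of `params` to minimize the total absolute
#' difference between its rho matrix and the reference's, searching all C!
#' permutations (C <= 6). Deterministic; ties broken by permutation order.
#'
#' @param params An [lca_params()] object to relabel.
#' @param reference An [lca_params()] object with the same C and J.
#' @return `params` with classes permuted to match `reference`, carrying the
#'   permutation used as attribute `perm` (new order in terms of old indices).
#' @export
align_classes <- function(params, reference) {
  stopifnot(inherits(params, "lca_params"), inherits(reference, "lca_params"))
  C <- n_classes(params)
  if (C != n_classes(reference) || n_items(params) != n_items(reference)) {
    stop("params and reference dimensions differ")
  }
  if (C > 6L) stop("alignment supports up to 6 classes")
  perms <- all_permutations(C)
  cost <- apply(perms, 1L, function(p) {
    sum(abs(params$rho[p, , drop = FALSE] - reference$rho))
  })
  best <- perms[which.min(cost), ]
  out <- lca_params(params$gamma[best], params$rho[best, , drop = FALSE],
                    item_names = params$item_names,
                    class_names = reference$class_names)
  attr(out, "perm") <- best
  out
}

#' Read / write parameter sets as JSON
#'
#' Parameter sets serialize as `{"gamma": [...], "rho": [[...], ...],
#' "item_names": [...]}` with rho rows indexed by class.
#'
#' @param params An [lca_params()] object.
#' @param path File path.
#' @return `read_params_json` returns an `lca_params`; `write_params_json`
#'   returns `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "lca_params"))
  obj <- list(gamma = unname(params$gamma),
              rho = unname(params$rho),
              item_names = params$item_names,
              class_names = params$class_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lca_params(obj$gamma, obj$rho, item_names = obj$item_names,
             class_names = obj$class_names)
}
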