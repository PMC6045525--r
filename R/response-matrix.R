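#' Subject-level binary response matrix
#'
#' Container for n subjects by J binary symptom indicators, with optional
#' per-subject group labels. Non-missing cells must be exactly 0 or 1;
#' `NA` marks an item-level missing response.
#'
#' @param items Integer or numeric matrix (n x J) of 0/1 values, `NA` allowed.
#' @param item_names Character vector of J item labels. Defaults to the
#'   column names of `items`, or `item1..itemJ`.
#' @param group Optional factor or character vector of length n with the
#'   subject's group label; `NA` marks a missing group label.
#'
#' @return An object of class `response_matrix`: a list with elements
#'   `items`, `item_names` and `group` (a factor or `NULL`).
#' @export
response_matrix <- function(items, item_names = NULL, group = NULL) {
  items <- as.matrix(items)
  if (is.null(item_names)) {
    item_names <- colnames(items)
    if (is.null(item_names)) item_names <- paste0("item", seq_len(ncol(items)))
  }
  if (ncol(items) < 1L) stop("at least one item is required")
  if (length(item_names) != ncol(items)) {
    stop("item_names length (", length(item_names),
         ") does not match number of item columns (", ncol(items), ")")
  }
  storage.mode(items) <- "integer"
  bad <- which(!is.na(items) & items != 0L & items != 1L)
  if (length(bad) > 0L) {
    rows <- unique(((bad[1L] - 1L) %% nrow(items)) + 1L)
    stop("non-binary item value at row ", rows[1L],
         "; items must be 0, 1 or missing")
  }
  dimnames(items) <- list(NULL, item_names)
  if (!is.null(group)) {
    if (length(group) != nrow(items)) {
      stop("group labels must have one entry per record")
    }
    group <- as.factor(group)
  }
  structure(
    list(items = items, item_names = item_names, group = group),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> ", nrow(x$items), " subjects x ",
      ncol(x$items), " items (", paste(x$item_names, collapse = ", "), ")\n",
      sep = "")
  n_miss <- sum(is.na(x$items))
  cat("  missing item cells: ", n_miss, "\n", sep = "")
  if (!is.null(x$group)) {
    tab <- table(x$group, useNA = "ifany")
    cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$items)

#' Subset a response matrix by record index
#'
#' @param data A [response_matrix()].
#' @param idx Integer or logical index over records.
#' @return A `response_matrix` with the selected records.
#' @export
subset_records <- function(data, idx) {
  stopifnot(inherits(data, "response_matrix"))
  response_matrix(
    data$items[idx, , drop = FALSE],
    item_names = data$item_names,
    group = if (is.null(data$group)) NULL else droplevels(data$group[idx])
  )
}

#' Drop records with a missing group label
#'
#' Grouped fits require a group label on every record; records missing the
#' label are eliminated before analysis and the count is reported.
#'
#' @param data A [response_matrix()] with a `group` component.
#' @param quiet Suppress the elimination message.
#' @return A `response_matrix` containing only records with a group label.
#' @export
drop_missing_group <- function(data, quiet = FALSE) {
  stopifnot(inherits(data, "response_matrix"))
  if (is.null(data$group)) stop("data carries no group labels")
  keep <- !is.na(data$group)
  if (!all(keep) && !quiet) {
    message(sum(!keep), " record(s) eliminated for missing group label")
  }
  subset_records(data, keep)
}

#' Read a subject-level table from delimited text
#'
#' Parses a comma-separated file with a header row. Item columns must
#' contain 0, 1, or missing (empty cell or `NA`); any other value is an
#' error naming the offending row.
#'
#' @param path File path.
#' @param item_names Character vector of item column names to read.
#' @param group_name Optional name of a single categorical group column.
#' @return A [response_matrix()].
#' @export
read_subject_table <- function(path, item_names, group_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("NA", ""), check.names = FALSE)
  missing_cols <- setdiff(c(item_names, group_name), names(raw))
  if (length(missing_cols) > 0L) {
    stop("declared column(s) absent from file: ",
         paste(missing_cols, collapse = ", "))
  }
  items <- matrix(NA_integer_, nrow(raw), length(item_names),
                  dimnames = list(NULL, item_names))
  for (j in seq_along(item_names)) {
    v <- raw[[item_names[j]]]
    ok <- is.na(v) | v %in% c("0", "1")
    if (!all(ok)) {
      stop("non-binary value '", v[which(!ok)[1L]], "' in column '",
           item_names[j], "' at data row ", which(!ok)[1L])
    }
    items[, j] <- suppressWarnings(as.integer(v))
  }
  group <- if (!is.null(group_name)) raw[[group_name]] else NULL
  out <- response_matrix(items, item_names = item_names, group = group)
  n_miss_grp <- if (is.null(group)) 0L else sum(is.na(out$group))
  attr(out, "read_log") <- c(read = nrow(raw),
                             retained = nrow(raw) - n_miss_grp,
                             missing_group = n_miss_grp)
  out
}

#' Write a subject-level table as delimited text
#'
#' Inverse of [read_subject_table()]: items written as 0/1 with missing
#' cells empty, plus the group column when present. Hidden simulation-truth
#' columns (true class) are written only when `truth = TRUE`.
#'
#' @param data A [response_matrix()].
#' @param path Output file path.
#' @param truth Include hidden `true_class` column if the data carry one.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(data, path, truth = FALSE) {
  stopifnot(inherits(data, "response_matrix"))
  df <- as.data.frame(data$items)
  if (!is.null(data$group)) df$group <- as.character(data$group)
  if (truth && !is.null(attr(data, "true_class"))) {
    df$true_class <- attr(data, "true_class")
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
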