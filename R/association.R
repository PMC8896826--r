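# Association between a categorical outcome (complementation result) and a
# continuous covariate (patristic distance from the focal/host ortholog).

#' Correlation ratio (eta) between a categorical and a continuous variable
#'
#' eta^2 is the between-group share of the total variance of `values` across
#' the categories in `labels`:
#' eta^2 = sum_c n_c (mean_c - grand mean)^2 / sum_i (y_i - grand mean)^2,
#' and eta is its positive square root. eta = 1 means the categories fully
#' determine the covariate; eta = 0 means identical group means.
#'
#' @param labels Categorical vector (>= 2 observed categories).
#' @param values Numeric vector, same length, with positive total variance.
#' @return An `eta_result`: `eta`, `eta_squared`, per-group n and mean,
#'   grand mean, between-group and total sums of squares.
#' @export
#' @examples
#' correlation_ratio(c("A", "A", "B", "B"), c(1, 2, 3, 5))$eta_squared # ~0.714
correlation_ratio <- function(labels, values) {
  if (length(labels) != length(values)) {
    stop("`labels` and `values` must have equal length", call. = FALSE)
  }
  if (length(values) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (!all(is.finite(values))) stop("`values` must be finite", call. = FALSE)
  labels <- as.character(labels)
  if (dplyr::n_distinct(labels) < 2L) {
    stop("association undefined: only one category present", call. = FALSE)
  }
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  if (ss_total <= 0) {
    stop("association undefined: zero total variance", call. = FALSE)
  }
  groups <- tibble::tibble(label = labels, value = values) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value)) |>
    dplyr::arrange(.data$label)
  ss_between <- sum(groups$n * (groups$mean - grand)^2)
  eta2 <- ss_between / ss_total
  structure(
    list(
      eta = sqrt(eta2), eta_squared = eta2,
      groups = groups, grand_mean = grand,
      ss_between = ss_between, ss_total = ss_total,
      n = length(values), labels = labels, values = values
    ),
    class = "eta_result"
  )
}

#' @export
print.eta_result <- function(x, ...) {
  cat("Correlation ratio: eta = ", signif(x$eta, 4),
      " (eta^2 = ", signif(x$eta_squared, 4), "), n = ", x$n, "\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' Tidy an eta result
#'
#' @param x An `eta_result`.
#' @param ... Unused.
#' @return Per-group tibble: `label`, `n`, `mean`.
#' @export
tidy.eta_result <- function(x, ...) x$groups

#' @export
glance.eta_result <- function(x, ...) {
  tibble::tibble(
    eta = x$eta, eta_squared = x$eta_squared,
    ss_between = x$ss_between, ss_total = x$ss_total,
    n_groups = nrow(x$groups), n = x$n
  )
}

#' Outcome vs patristic-distance association for a screen table
#'
#' Joins a complementation screen table to the tree by leaf label, binarizes
#' the chosen outcome column (positive = `+`, and `partial` when
#' `partial_positive`; negative = `-`; `NT`/`?` rows dropped), and reports
#' both the correlation ratio between outcome and patristic distance from the
#' focal leaf and a two-sided rank-sum test between the distance vectors of
#' the two outcome groups.
#'
#' @param table A screen table ([load_screen_table()]) or any data frame with
#'   a leaf-label key column and an outcome column.
#' @param matrix Patristic matrix or `phylo` tree.
#' @param focal Focal (host) leaf label.
#' @param outcome_column Outcome column name (e.g. `"complement_aerobic"` or
#'   `"complemented_or_recovered"`).
#' @param key_column Column holding the tree leaf label
#'   (default `"species_strain"`).
#' @param include_focal Keep the focal host's own row (distance 0) in the
#'   association, when present in the table. Default `TRUE`.
#' @param partial_positive Count `partial` outcomes as positive. Default
#'   `TRUE`.
#' @param ... Passed to [rank_sum_test()].
#' @return An `outcome_association`: `eta` (an `eta_result`), `rank_test`
#'   (a `rank_sum_test` between positive and negative distances), and the
#'   joined per-leaf `data` tibble.
#' @export
outcome_distance_association <- function(table, matrix, focal,
                                         outcome_column = "complement_aerobic",
                                         key_column = "species_strain",
                                         include_focal = TRUE,
                                         partial_positive = TRUE, ...) {
  if (!key_column %in% names(table)) {
    stop("key column '", key_column, "' not found in table", call. = FALSE)
  }
  if (!outcome_column %in% names(table)) {
    stop("outcome column '", outcome_column, "' not found in table", call. = FALSE)
  }
  m <- as_patristic(matrix)
  d <- distances_from(m, focal)
  if (include_focal) d <- dplyr::bind_rows(d, tibble::tibble(leaf = focal, distance = 0))
  df <- tibble::tibble(
    leaf = table[[key_column]],
    outcome_raw = as.character(table[[outcome_column]])
  )
  if (!include_focal) df <- df[df$leaf != focal, , drop = FALSE]
  unjoined <- setdiff(df$leaf, d$leaf)
  if (length(unjoined)) {
    stop("table rows with no matching tree leaf: ",
         paste(unjoined, collapse = ", "), call. = FALSE)
  }
  positive <- c("+", if (partial_positive) "partial")
  df <- df |>
    dplyr::mutate(outcome = dplyr::case_when(
      .data$outcome_raw %in% positive ~ "positive",
      .data$outcome_raw == "-" ~ "negative",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$outcome)) |>
    dplyr::left_join(d, by = "leaf")
  if (dplyr::n_distinct(df$outcome) < 2L) {
    stop("association undefined: only one outcome category after filtering",
         call. = FALSE)
  }
  eta <- correlation_ratio(df$outcome, df$distance)
  test <- rank_sum_test(df$distance[df$outcome == "positive"],
                        df$distance[df$outcome == "negative"], ...)
  structure(
    list(eta = eta, rank_test = test, data = df, focal = focal,
         outcome_column = outcome_column,
         include_focal = include_focal, partial_positive = partial_positive),
    class = "outcome_association"
  )
}

#' @export
print.outcome_association <- function(x, ...) {
  cat("Outcome (", x$outcome_column, ") vs patristic distance from ",
      x$focal, "\n", sep = "")
  cat("  eta = ", signif(x$eta$eta, 4),
      ", rank-sum p = ", format.pval(x$rank_test$p_value, digits = 4),
      " (", x$rank_test$method, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.outcome_association <- function(x, ...) x$data

#' @export
glance.outcome_association <- function(x, ...) {
  tibble::tibble(
    eta = x$eta$eta, eta_squared = x$eta$eta_squared,
    statistic_u = x$rank_test$U, p_value = x$rank_test$p_value,
    method = x$rank_test$method,
    n_positive = sum(x$data$outcome == "positive"),
    n_negative = sum(x$data$outcome == "negative"),
    include_focal = x$include_focal, partial_positive = x$partial_positive
  )
}

#' Cross-tabulate a host trait against an outcome
#'
#' Counts of a categorical native-host trait (rows) against an outcome column
#' (columns), with missing/unknown values kept as an explicit `"unknown"`
#' category and row/column margins included.
#'
#' @param table A data frame.
#' @param row_trait,col_outcome Column names.
#' @return A tibble in wide form: one row per trait category plus a `total`
#'   margin row; one column per outcome category plus a `total` margin.
#' @export
trait_crosstab <- function(table, row_trait, col_outcome) {
  for (col in c(row_trait, col_outcome)) {
    if (!col %in% names(table)) stop("column '", col, "' not found", call. = FALSE)
  }
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "?" | x == ""] <- "unknown"
    x
  }
  if (nrow(table) == 0L) {
    return(tibble::tibble(!!row_trait := "total", total = 0L))
  }
  df <- tibble::tibble(row = clean(table[[row_trait]]),
                       col = clean(table[[col_outcome]]))
  wide <- df |>
    dplyr::count(.data$row, .data$col) |>
    tidyr::pivot_wider(names_from = "col", values_from = "n", values_fill = 0L) |>
    dplyr::arrange(.data$row)
  value_cols <- setdiff(names(wide), "row")
  wide$total <- rowSums(wide[value_cols])
  margin <- dplyr::summarise(wide, dplyr::across(dplyr::all_of(c(value_cols, "total")), sum))
  out <- dplyr::bind_rows(wide, dplyr::mutate(margin, row = "total"))
  dplyr::rename(out, !!row_trait := "row")
}
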