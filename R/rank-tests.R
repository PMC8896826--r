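# Two-sample rank statistics used to validate that a selected ortholog subset
# is representative of the full set, and to compare outcome groups.

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided two-sample rank test. For small pooled samples
#' (`n1 + n2 <= exact_limit`, default 25) the exact null distribution of the
#' rank sum is computed by complete enumeration over the observed pooled
#' multiset (ties carried as mid-ranks), via a subset-sum convolution that is
#' equivalent to enumerating all choose(N, n1) rank configurations. Larger
#' samples use the normal approximation with tie-corrected variance
#' sigma^2 = (n1 n2 / 12) * ((N + 1) - sum(t^3 - t) / (N (N - 1))) and, by
#' default, a continuity correction of 0.5.
#'
#' @param x,y Numeric vectors (finite, non-empty).
#' @param alternative Only `"two_sided"` is implemented.
#' @param method `"auto"` (exact when n1 + n2 <= `exact_limit`), `"exact"`,
#'   or `"normal"`.
#' @param continuity Apply the 0.5 continuity correction in the normal
#'   approximation (the exact method ignores it).
#' @param exact_limit Pooled-size cutoff for the automatic exact method.
#' @return A `rank_sum_test` object: U and W statistics, z (normal method),
#'   two-sided p-value in (0, 1], method used, tie-group sizes.
#' @export
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4)) # exact two-sided p = 1/3
rank_sum_test <- function(x, y, alternative = "two_sided",
                          method = c("auto", "exact", "normal"),
                          continuity = TRUE, exact_limit = 25) {
  method <- match.arg(method)
  if (!identical(alternative, "two_sided")) {
    stop("only the two-sided alternative is implemented", call. = FALSE)
  }
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty", call. = FALSE)
  if (!all(is.finite(c(x, y)))) stop("samples must be finite", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  ties <- as.integer(table(c(x, y)))
  use_exact <- method == "exact" || (method == "auto" && N <= exact_limit)
  if (use_exact) {
    p <- exact_ranksum_p(r, n1, W)
    z <- NA_real_
    used <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      z <- 0
      p <- 1
    } else {
      cc <- if (continuity) 0.5 * sign(U - mu) else 0
      z <- (U - mu - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    used <- "normal_approx"
  }
  structure(
    list(U = U, W = W, z = z, p_value = p, method = used,
         n1 = n1, n2 = n2, ties = ties[ties > 1L]),
    class = "rank_sum_test"
  )
}

# Exact two-sided p for the rank sum W over all subsets of size n1 of the
# pooled mid-ranks. Mid-ranks are doubled to integers and the distribution is
# built by dynamic-programming convolution; this enumerates the same
# configurations as brute force over choose(N, n1) subsets.
exact_ranksum_p <- function(r, n1, W) {
  ri <- as.integer(round(2 * r))
  N <- length(ri)
  total <- sum(ri)
  # dp[[k]][s+1] = number of k-subsets with doubled-rank sum s
  dp <- vector("list", n1 + 1L)
  dp[[1L]] <- c(1, numeric(total))
  for (k in seq_len(n1)) dp[[k + 1L]] <- numeric(total + 1L)
  for (v in ri) {
    for (k in rev(seq_len(n1))) {
      shifted <- c(numeric(v), dp[[k]][seq_len(total + 1L - v)])
      dp[[k + 1L]] <- dp[[k + 1L]] + shifted
    }
  }
  counts <- dp[[n1 + 1L]]
  n_total <- sum(counts)
  w2 <- as.integer(round(2 * W))
  p_le <- sum(counts[seq_len(w2 + 1L)]) / n_total
  p_ge <- sum(counts[(w2 + 1L):(total + 1L)]) / n_total
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat("Wilcoxon rank-sum test (two-sided, ", x$method, ")\n", sep = "")
  cat("  n1 = ", x$n1, ", n2 = ", x$n2, ", U = ", x$U, ", W = ", x$W,
      if (!is.na(x$z)) paste0(", z = ", signif(x$z, 4)) else "",
      "\n  p = ", format.pval(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble::tibble(
    statistic_u = x$U, statistic_w = x$W, z = x$z,
    p_value = x$p_value, method = x$method, n1 = x$n1, n2 = x$n2
  )
}

#' @export
glance.rank_sum_test <- function(x, ...) tidy.rank_sum_test(x)

#' Kruskal-Wallis rank test across groups
#'
#' Thin, tidy wrapper around [stats::kruskal.test()] (tie-corrected H,
#' chi-square p on groups - 1 df). When every pooled value is identical the
#' tie correction degenerates; the conventional H = 0, p = 1 is reported.
#'
#' @param groups A list of numeric vectors (>= 2 non-empty groups), or a data
#'   frame together with `value`/`group` column names.
#' @param value,group Column names when `groups` is a data frame.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `n`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4))) # H = 2.4
kruskal_wallis <- function(groups, value = "value", group = "group") {
  if (is.data.frame(groups)) {
    groups <- split(groups[[value]], groups[[group]])
  }
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(vals))) stop("group values must be finite", call. = FALSE)
  if (length(unique(vals)) == 1L) {
    return(tibble::tibble(statistic = 0, df = length(groups) - 1L,
                          p_value = 1, n = length(vals)))
  }
  kt <- stats::kruskal.test(groups)
  tibble::tibble(
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value, n = length(vals)
  )
}

#' Representativeness of a selected subset
#'
#' Compares the patristic-distance-from-focal distribution of a selected
#' ortholog subset against that of the full ortholog set (focal excluded from
#' both), mirroring the validation used for the reference screens: the
#' selected set is a subset of the full set, and the two overlapping samples
#' are compared directly with a two-sided rank-sum test. A large p indicates
#' the subsample's distance distribution is indistinguishable from the full
#' set's.
#'
#' @param matrix Patristic matrix or `phylo` tree.
#' @param focal Focal (host) leaf label.
#' @param selected A `representative_set`, a data frame with a `leaf` column,
#'   or a character vector of selected leaves (the focal may be included; it
#'   is dropped from both sets).
#' @param ... Passed to [rank_sum_test()] (e.g. `continuity`, `method`).
#' @return A `representativeness_report`: n_full, n_selected, p, method, and
#'   min/q25/median/q75/max of both distance sets.
#' @export
representativeness_report <- function(matrix, focal, selected, ...) {
  m <- as_patristic(matrix)
  sel <- selected_leaves(selected)
  full <- distances_from(m, focal)
  sel <- setdiff(sel, focal)
  if (length(sel) == 0L) stop("no selected leaves left after excluding focal", call. = FALSE)
  missing <- setdiff(sel, full$leaf)
  if (length(missing)) {
    stop("selected leaves absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d_sel <- full$distance[full$leaf %in% sel]
  test <- rank_sum_test(full$distance, d_sel, ...)
  structure(
    list(
      n_full = nrow(full), n_selected = length(d_sel),
      p_two_sided = test$p_value, method = test$method, test = test,
      quantiles_full = dist_quantiles(full$distance),
      quantiles_selected = dist_quantiles(d_sel),
      focal = focal, full = full$distance, selected = d_sel
    ),
    class = "representativeness_report"
  )
}

selected_leaves <- function(selected) {
  if (is.data.frame(selected)) {
    if (!"leaf" %in% names(selected)) stop("`selected` needs a `leaf` column", call. = FALSE)
    return(selected$leaf)
  }
  as.character(selected)
}

dist_quantiles <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  stats::setNames(q, c("min", "q25", "median", "q75", "max"))
}

#' @export
print.representativeness_report <- function(x, ...) {
  cat("Representativeness of selected subset (focal: ", x$focal, ")\n", sep = "")
  cat("  n_full = ", x$n_full, ", n_selected = ", x$n_selected, "\n", sep = "")
  cat("  two-sided rank-sum p = ", format.pval(x$p_two_sided, digits = 4),
      " (", x$method, ")\n", sep = "")
  q <- rbind(full = x$quantiles_full, selected = x$quantiles_selected)
  print(round(q, 4))
  invisible(x)
}

#' Tidy a representativeness report
#'
#' @param x A `representativeness_report`.
#' @param ... Unused.
#' @return A tibble with one row per set (`full`, `selected`) and the
#'   distance quantiles.
#' @export
tidy.representativeness_report <- function(x, ...) {
  tibble::tibble(
    set = c("full", "selected"),
    n = c(x$n_full, x$n_selected),
    min = c(x$quantiles_full["min"], x$quantiles_selected["min"]),
    q25 = c(x$quantiles_full["q25"], x$quantiles_selected["q25"]),
    median = c(x$quantiles_full["median"], x$quantiles_selected["median"]),
    q75 = c(x$quantiles_full["q75"], x$quantiles_selected["q75"]),
    max = c(x$quantiles_full["max"], x$quantiles_selected["max"])
  )
}

#' @export
glance.representativeness_report <- function(x, ...) {
  tibble::tibble(
    n_full = x$n_full, n_selected = x$n_selected,
    p_two_sided = x$p_two_sided, method = x$method
  )
}

#' Report JSON for a representativeness check
#'
#' @param x A `representativeness_report`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_representativeness_json <- function(x, file) {
  jsonlite::write_json(
    list(
      n_full = x$n_full, n_selected = x$n_selected,
      p_two_sided = x$p_two_sided, method = x$method,
      quantiles_full = as.list(x$quantiles_full),
      quantiles_selected = as.list(x$quantiles_selected)
    ),
    file, auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}
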