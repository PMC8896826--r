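# Structured complementation-screen tables (NadA / IspG schemas) and the
# aggregate counts reported from them. The shipped fixtures are hand
# transcriptions of the published screen tables; the combined
# complemented_or_recovered column is regenerated at load time from the
# individual condition columns rather than trusted.

screen_vocab <- list(
  complement_aerobic = c("+", "-", "partial"),
  complement_bssuf = c("+", "-", "NT"),
  complement_ecsuf = c("+", "-", "NT"),
  complement_etp = c("+", "-", "NT"),
  complement_anaerobic = c("+", "-", "NT"),
  complemented_or_recovered = c("+", "-"),
  sds_page = c("+", "-"),
  ms_detected = c("+", "-", "NT", "detection_NT"),
  o2_tolerance = c("+", "-", "?"),
  temperature_class = c("mesophilic", "thermophilic", "hyperthermophilic", "?")
)

schema_columns <- function(schema) {
  base <- c("phylum", "species_strain", "complement_aerobic")
  cond <- switch(schema,
    nada = c("complement_bssuf", "complement_ecsuf", "complement_anaerobic"),
    ispg = c("complement_etp", "complement_anaerobic")
  )
  flags <- switch(schema, nada = c("is_host_control", "is_suf_donor"),
                  ispg = "is_host_control")
  list(
    required = c(base, cond, "complemented_or_recovered", "tir_log10",
                 "sds_page", "ms_detected", "o2_tolerance",
                 "temperature_class", "fes_system", flags),
    condition = c("complement_aerobic", cond)
  )
}

#' Load and validate a complementation screen table
#'
#' Reads a TSV in the NadA or IspG screen schema, enforces the controlled
#' vocabularies (reporting offending rows), requires unique species keys, and
#' regenerates the `complemented_or_recovered` column as the disjunction of
#' the individual complementation/recovery columns (a `+` or `partial` in any
#' condition), erroring if the stored column disagrees. The predicted
#' translation-initiation-rate column `tir_log10` is numeric with `NT`
#' converted to `NA`.
#'
#' @param file Path to the TSV.
#' @param schema `"nada"` or `"ispg"`.
#' @return A validated `screen_table` tibble (attribute `"schema"` records
#'   the schema).
#' @export
load_screen_table <- function(file, schema = c("nada", "ispg")) {
  schema <- match.arg(schema)
  if (!file.exists(file)) stop("screen table not found: ", file, call. = FALSE)
  if (file.size(file) == 0L) stop("schema error: empty screen table file", call. = FALSE)
  df <- readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  validate_screen_table(df, schema)
}

#' @rdname load_screen_table
#' @param df A data frame already in memory.
#' @export
validate_screen_table <- function(df, schema = c("nada", "ispg")) {
  schema <- match.arg(schema)
  cols <- schema_columns(schema)
  missing <- setdiff(cols$required, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  for (col in intersect(names(screen_vocab), names(df))) {
    bad <- which(!(as.character(df[[col]]) %in% screen_vocab[[col]]))
    if (length(bad)) {
      stop("vocabulary error in column '", col, "' at row(s) ",
           paste(bad, collapse = ", "), ": ",
           paste(unique(df[[col]][bad]), collapse = ", "), call. = FALSE)
    }
  }
  dup <- unique(df$species_strain[duplicated(df$species_strain)])
  if (length(dup)) {
    stop("duplicate species_strain: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  tir <- as.character(df$tir_log10)
  tir[tir %in% c("NT", "N.T.", "NA", "")] <- NA
  df$tir_log10 <- as.numeric(tir)
  for (flag in intersect(c("is_host_control", "is_suf_donor"), names(df))) {
    df[[flag]] <- as.logical(df[[flag]])
    if (anyNA(df[[flag]])) stop("flag column '", flag, "' must be TRUE/FALSE", call. = FALSE)
  }
  # regenerate the combined outcome column; never trust the stored one
  regen <- apply(df[cols$condition], 1L,
                 function(r) any(r %in% c("+", "partial")))
  regen <- ifelse(regen, "+", "-")
  stored <- as.character(df$complemented_or_recovered)
  bad <- which(stored != regen)
  if (length(bad)) {
    stop("complemented_or_recovered inconsistent with condition columns at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df$complemented_or_recovered <- regen
  attr(df, "schema") <- schema
  class(df) <- c("screen_table", class(df))
  df
}

#' Shipped screen-table fixtures
#'
#' Transcriptions of the published NadA and IspG complementation screens
#' (47 heterologous orthologs plus the E. coli host row each), used for the
#' headline counts and as join fixtures. See
#' `system.file("extdata", "transcription_notes.md", package = "orthosample")`
#' for transcription conventions.
#'
#' @return A validated `screen_table`.
#' @export
screen_nada <- function() {
  load_screen_table(orthosample_extdata("table1_nada.tsv"), "nada")
}

#' @rdname screen_nada
#' @export
screen_ispg <- function() {
  load_screen_table(orthosample_extdata("table2_ispg.tsv"), "ispg")
}

orthosample_extdata <- function(name) {
  path <- system.file("extdata", name, package = "orthosample")
  if (!nzchar(path)) stop("shipped fixture not found: ", name, call. = FALSE)
  path
}

screen_schema <- function(table) {
  s <- attr(table, "schema")
  if (is.null(s)) stop("not a validated screen_table; use load_screen_table()",
                       call. = FALSE)
  s
}

summary_row <- function(count, value, filter_expression) {
  tibble::tibble(count = count, value = as.integer(value),
                 filter_expression = filter_expression)
}

#' Headline counts for the NadA screen
#'
#' All counts exclude the E. coli host-control row; `additional` recovery
#' counts are restricted to orthologs negative in the aerobic assay, and the
#' B. subtilis SUF-donor row is excluded from `bssuf_additional` (it is the
#' anchor already known to work with its own SUF).
#'
#' @param table A `screen_table` with the NadA schema.
#' @return A tibble with columns `count`, `value`, `filter_expression`.
#' @export
summarize_nada <- function(table) {
  if (screen_schema(table) != "nada") stop("expected NadA schema", call. = FALSE)
  t <- table[!table$is_host_control, , drop = FALSE]
  aerneg <- t$complement_aerobic == "-"
  dplyr::bind_rows(
    summary_row("aerobic_positive",
                sum(t$complement_aerobic == "+"),
                "complement_aerobic == '+'"),
    summary_row("anaerobic_additional",
                sum(aerneg & t$complement_anaerobic == "+"),
                "complement_aerobic == '-' & complement_anaerobic == '+'"),
    summary_row("anaerobic_additional_obligate_anaerobes",
                sum(aerneg & t$complement_anaerobic == "+" & t$o2_tolerance == "-"),
                "complement_aerobic == '-' & complement_anaerobic == '+' & o2_tolerance == '-'"),
    summary_row("bssuf_additional",
                sum(aerneg & t$complement_bssuf == "+" & !t$is_suf_donor),
                "complement_aerobic == '-' & complement_bssuf == '+' & !is_suf_donor"),
    summary_row("ecsuf_positive",
                sum(t$complement_ecsuf == "+"),
                "complement_ecsuf == '+'"),
    summary_row("bssuf_and_anaerobic",
                sum(aerneg & t$complement_bssuf == "+" & t$complement_anaerobic == "+"),
                "complement_aerobic == '-' & complement_bssuf == '+' & complement_anaerobic == '+'"),
    summary_row("suf_rule_violations",
                sum((t$complement_bssuf == "+" | t$complement_ecsuf == "+") &
                      !grepl("SufBD", t$fes_system, fixed = TRUE)),
                "(complement_bssuf == '+' | complement_ecsuf == '+') & !grepl('SufBD', fes_system)")
  )
}

#' Headline counts for the IspG screen
#'
#' `partial` aerobic complementation counts as positive; counts exclude the
#' E. coli host-control row.
#'
#' @param table A `screen_table` with the IspG schema.
#' @return A tibble with columns `count`, `value`, `filter_expression`.
#' @export
summarize_ispg <- function(table) {
  if (screen_schema(table) != "ispg") stop("expected IspG schema", call. = FALSE)
  t <- table[!table$is_host_control, , drop = FALSE]
  aerneg <- t$complement_aerobic == "-"
  dplyr::bind_rows(
    summary_row("aerobic_positive",
                sum(t$complement_aerobic %in% c("+", "partial")),
                "complement_aerobic %in% c('+','partial')"),
    summary_row("anaerobic_additional",
                sum(aerneg & t$complement_anaerobic == "+"),
                "complement_aerobic == '-' & complement_anaerobic == '+'"),
    summary_row("etp_recovered",
                sum(aerneg & t$complement_etp == "+"),
                "complement_aerobic == '-' & complement_etp == '+'")
  )
}

#' Mass-spectrometry detection counts
#'
#' Orthologs with an attempted MS detection (`+` or `-`), those detected, and
#' those detected despite never complementing or recovering in any assay.
#' Host-control row excluded; works for either schema.
#'
#' @param table A `screen_table`.
#' @return A tibble with columns `count`, `value`, `filter_expression`.
#' @export
detection_summary <- function(table) {
  screen_schema(table)
  t <- table[!table$is_host_control, , drop = FALSE]
  analyzed <- t$ms_detected %in% c("+", "-")
  dplyr::bind_rows(
    summary_row("ms_analyzed", sum(analyzed), "ms_detected %in% c('+','-')"),
    summary_row("ms_detected_positive", sum(t$ms_detected == "+"),
                "ms_detected == '+'"),
    summary_row("ms_detected_among_unrecovered",
                sum(t$ms_detected == "+" & t$complemented_or_recovered == "-"),
                "ms_detected == '+' & complemented_or_recovered == '-'")
  )
}

#' Screen counts as a named JSON report
#'
#' @param summary A summary tibble from [summarize_nada()],
#'   [summarize_ispg()] or [detection_summary()] (or several row-bound).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_screen_counts_json <- function(summary, file) {
  out <- stats::setNames(
    lapply(seq_len(nrow(summary)), function(i) {
      list(value = summary$value[i], filter_expression = summary$filter_expression[i])
    }),
    summary$count
  )
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
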