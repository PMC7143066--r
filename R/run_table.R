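RUN_TABLE_COLUMNS <- c("run_order", "frr", "tfr", "frr_coded", "tfr_coded",
                       "z_average_nm", "pdi", "zeta_mv")
RESPONSE_COLUMNS <- c("z_average_nm", "pdi", "zeta_mv")

#' Run tables
#'
#' A run table is a data frame with one row per experimental run: the run
#' order, factor settings in natural units (`frr`, `tfr`) and coded units
#' (`frr_coded`, `tfr_coded`), and the three responses `z_average_nm`, `pdi`
#' and `zeta_mv`, which stay `NA` until measured or simulated.
#' `as_run_table()` validates and classes an existing data frame.
#'
#' @param df a data frame carrying the run-table columns.
#' @param factors character vector of the natural-unit factor column names.
#' @return A data frame of class `run_table`.
#' @export
as_run_table <- function(df, factors = c("frr", "tfr")) {
  stopifnot(is.data.frame(df))
  if (!"run_order" %in% names(df)) df$run_order <- seq_len(nrow(df))
  missing_cols <- setdiff(factors, names(df))
  if (length(missing_cols)) {
    stop_invalid("run table lacks factor column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  for (col in intersect(c("run_order", factors, paste0(factors, "_coded"),
                          RESPONSE_COLUMNS), names(df))) {
    if (!is.numeric(df[[col]])) {
      stop_invalid("run table column '", col, "' is not numeric")
    }
  }
  if (anyNA(df[factors])) stop_invalid("factor settings contain missing values")
  class(df) <- unique(c("run_table", class(df)))
  attr(df, "factors") <- factors
  df
}

#' @export
print.run_table <- function(x, ...) {
  cat(sprintf("Run table: %d run(s), %d distinct condition(s)\n",
              nrow(x), nrow(unique(x[attr(x, "factors")]))))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read and write run tables as delimited text
#'
#' The on-disk format is comma-separated text with header
#' `run_order, frr, tfr, frr_coded, tfr_coded, z_average_nm, pdi, zeta_mv`;
#' response cells may be empty. Leading `#` lines are treated as comments. A
#' non-numeric cell raises a parse error naming its row and column;
#' `save_run_table()` followed by `load_run_table()` is the identity.
#'
#' @param path file path.
#' @return `load_run_table()` returns a [as_run_table()] data frame.
#' @export
load_run_table <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  raw <- read.csv(path, comment.char = "#", colClasses = "character",
                  check.names = FALSE, strip.white = TRUE)
  unknown <- setdiff(names(raw), RUN_TABLE_COLUMNS)
  if (length(unknown)) {
    stop_invalid("unknown run-table column(s): ", paste(unknown, collapse = ", "))
  }
  needed <- setdiff(RUN_TABLE_COLUMNS, RESPONSE_COLUMNS)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop_invalid("run-table file lacks column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  out <- raw
  for (col in names(raw)) {
    vals <- raw[[col]]
    vals[!nzchar(vals)] <- NA_character_
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num))
    if (length(bad)) {
      stop_invalid("cannot parse '", raw[[col]][bad[1]], "' as a number at row ",
                   bad[1], ", column '", col, "' of ", path)
    }
    if (col %in% needed && anyNA(num)) {
      stop_invalid("missing value in required column '", col, "' of ", path)
    }
    out[[col]] <- num
  }
  as_run_table(out)
}

#' @rdname load_run_table
#' @param table a run table.
#' @export
save_run_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  cols <- intersect(RUN_TABLE_COLUMNS, names(table))
  write.csv(as.data.frame(table)[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' The packaged measured run table
#'
#' Loads the packaged 29-run measured data set for the periodic-disturbance
#' micromixer (9 distinct conditions; Z-average in nm, PDI dimensionless, zeta
#' potential in mV). Two transcription corrections relative to the published
#' table are documented in the fixture header.
#'
#' @return A [as_run_table()] data frame with 29 rows.
#' @export
pdm_runs <- function() {
  load_run_table(system.file("extdata", "pdm_cccr_runs.csv", package = "pdmix",
                             mustWork = TRUE))
}

#' Distinct design conditions of a run table
#'
#' @param table a run table.
#' @param response optional response column to summarise per condition.
#' @return A data frame with one row per distinct factor setting, its
#'   replicate count and (if requested) the replicate mean and SD.
#' @export
run_conditions <- function(table, response = NULL) {
  stopifnot(is.data.frame(table))
  factors <- attr(table, "factors")
  if (is.null(factors)) factors <- c("frr", "tfr")
  key <- interaction(table[factors], drop = TRUE, lex.order = TRUE)
  out <- unique(table[factors])
  out <- out[order(out[[1]], out[[2]]), , drop = FALSE]
  okey <- interaction(out[factors], drop = TRUE, lex.order = TRUE)
  out$n <- as.integer(table(key)[as.character(okey)])
  if (!is.null(response)) {
    if (!response %in% names(table)) {
      stop_invalid("no response column '", response, "'")
    }
    out$mean <- tapply(table[[response]], key, mean)[as.character(okey)]
    out$sd <- tapply(table[[response]], key, sd)[as.character(okey)]
  }
  rownames(out) <- NULL
  out
}
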