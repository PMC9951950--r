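# Subset evaluation pipeline: all diets / without Leucaena / with Leucaena,
# reported in the standard 13-row layout.

REPORT_ROWS <- c("Mean S/O ratio",
                 "Slope",
                 "Mean bias (%)",
                 "Coefficient of variation of S/O ratio (%)",
                 "R^2",
                 "Model efficiency",
                 "Mean square prediction error",
                 "Bias (%)",
                 "Slope (%)",
                 "Random (%)",
                 "Concordance correlation coefficient",
                 "Ca",
                 "R")

# metric_set field behind each report row, in row order
REPORT_FIELDS <- c("msor", "slope", "mb_pct", "cv_so_pct", "r2", "me",
                   "mspe", "bias_pct", "slope_pct", "random_pct",
                   "ccc", "ca", "r")

# percentage rows display with 1 decimal, ratio-like rows with 3
REPORT_PCT <- REPORT_FIELDS %in%
  c("mb_pct", "cv_so_pct", "bias_pct", "slope_pct", "random_pct")

#' Run the subset evaluation pipeline
#'
#' Builds the paired series for one variable, optionally splits it by the
#' Leucaena flag of each record's diet, evaluates every agreement descriptor
#' on each subset, and returns a report holding one descriptor column per
#' subset ("all", and with \code{split_by_group}, "without_leucaena" and
#' "with_leucaena"). A subset with fewer than 3 records is dropped with a
#' warning rather than failing the run.
#'
#' @param records an \code{\link{animal_records}} table.
#' @param diets a \code{\link{diet_compositions}} table.
#' @param variable \code{"dmi"} or \code{"ch4"}.
#' @param split_by_group also evaluate the without/with-Leucaena subsets.
#' @param mode slope parameterization, see \code{\link{regression_fit}}.
#' @return an object of class \code{evaluation_report}: \code{variable},
#'   \code{columns} (named list of \code{metric_set}), \code{metadata}.
#' @export
run_evaluation <- function(records, diets, variable = c("dmi", "ch4"),
                           split_by_group = FALSE,
                           mode = c("moment", "origin")) {
  variable <- match.arg(variable)
  mode <- match.arg(mode)
  p <- to_paired(records, variable, diets)
  subsets <- list(all = rep(TRUE, length(p$o)))
  if (split_by_group) {
    subsets$without_leucaena <- !p$group
    subsets$with_leucaena <- p$group
  }
  columns <- list()
  for (label in names(subsets)) {
    keep <- subsets[[label]]
    if (sum(keep) < 3L) {
      warning("subset '", label, "' has fewer than 3 records (",
              sum(keep), "); column omitted", call. = FALSE)
      next
    }
    sub <- paired_series(p$o[keep], p$s[keep], p$group[keep],
                         variable = variable, units = p$units)
    columns[[label]] <- evaluate(sub, mode)
  }
  if (length(columns) == 0L) stop("no subset had 3 or more records",
                                  call. = FALSE)
  structure(list(variable = variable,
                 columns = columns,
                 metadata = list(mode = mode,
                                 n_records = nrow(records),
                                 timestamp = format(Sys.time(),
                                                    "%Y-%m-%dT%H:%M:%S%z"),
                                 package_version =
                                   as.character(utils::packageVersion("rumeval")))),
            class = "evaluation_report")
}

#' Lay an evaluation report out as a data.frame
#'
#' @param x an \code{evaluation_report}.
#' @param row.names,optional,... ignored (S3 signature).
#' @param rounded round to display precision (3 decimals for ratio-like
#'   rows, 1 for percentage rows) instead of full precision.
#' @return data.frame with a \code{Descriptor} column, one column per
#'   subset, and an \code{N} first row.
#' @export
as.data.frame.evaluation_report <- function(x, row.names = NULL,
                                            optional = FALSE, ...,
                                            rounded = FALSE) {
  out <- data.frame(Descriptor = c("N", REPORT_ROWS),
                    stringsAsFactors = FALSE)
  for (label in names(x$columns)) {
    ms <- x$columns[[label]]
    vals <- vapply(REPORT_FIELDS, function(f) ms[[f]], numeric(1))
    if (rounded) vals <- round(vals, ifelse(REPORT_PCT, 1, 3))
    out[[label]] <- c(ms$n, vals)
  }
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:", x$variable, "(slope mode:", x$metadata$mode,
      ")\n")
  df <- as.data.frame(x, rounded = TRUE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Row labels and order follow the standard descriptor-table layout; values
#' are rounded for display (3 decimals for ratios, 1 for percentages). Use
#' \code{\link{as.data.frame.evaluation_report}} with \code{rounded = FALSE}
#' for full precision.
#'
#' @param report an \code{evaluation_report}.
#' @param path output path.
#' @param format \code{"csv"} or \code{"markdown"}.
#' @export
write_report <- function(report, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  df <- as.data.frame(report, rounded = TRUE)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    cols <- names(df)
    fmt_row <- function(cells) paste0("| ", paste(cells, collapse = " | "),
                                      " |")
    lines <- c(paste0("# Evaluation report: ", report$variable),
               "",
               fmt_row(cols),
               fmt_row(rep("---", length(cols))))
    for (i in seq_len(nrow(df))) {
      cells <- vapply(df[i, ], function(v) {
        if (is.numeric(v)) formatC(v, format = "g", digits = 15) else
          as.character(v)
      }, character(1))
      lines <- c(lines, fmt_row(cells))
    }
    ok <- tryCatch({
      writeLines(lines, path); TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("failed to write report to '", path, "': ",
                          conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}
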