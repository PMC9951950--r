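# canonical record columns; dialect maps these names onto file columns
RECORD_COLS <- c("animal_id", "diet_id", "period", "bw_kg",
                 "dmi_obs", "dmi_sim", "ch4_obs", "ch4_sim")
MEASUREMENT_COLS <- c("dmi_obs", "dmi_sim", "ch4_obs", "ch4_sim")
DIET_COLS <- c("diet_id", "cp", "ndf", "nsc", "ee", "ash", "ivdmd", "leucaena")

# rounding slack (percentage points) tolerated between a printed NSC value and
# the one derived from the other printed fractions, and on the sum-to-100 check
NSC_TOLERANCE <- 0.15

#' Validate a table of animal records
#'
#' An animal-record table has one row per animal-within-diet with observed and
#' simulated dry matter intake (DMI, kg DM/animal/day) and methane emission
#' (L/animal/day). Measurement columns may be \code{NA} (the record is then
#' usable only for the other variable), but any value present must be strictly
#' positive, body weights must be positive, and (animal_id, diet_id) pairs must
#' be unique.
#'
#' @param df data.frame with columns \code{animal_id}, \code{diet_id},
#'   \code{period}, \code{bw_kg}, \code{dmi_obs}, \code{dmi_sim},
#'   \code{ch4_obs}, \code{ch4_sim}.
#' @return the validated data.frame with class \code{animal_records}.
#' @export
animal_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(RECORD_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("bw_kg", MEASUREMENT_COLS)) {
    if (!is.numeric(df[[col]])) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
  }
  bad_bw <- which(!is.finite(df$bw_kg) | df$bw_kg <= 0)
  if (length(bad_bw) > 0L) {
    stop("bw_kg must be strictly positive; offending row(s): ",
         paste(bad_bw, collapse = ", "), call. = FALSE)
  }
  for (col in MEASUREMENT_COLS) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad) > 0L) {
      stop("column '", col, "' must be strictly positive when present; ",
           "offending row(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  key <- paste(df$animal_id, df$diet_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicate (animal_id, diet_id) pair(s) at row(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  class(df) <- unique(c("animal_records", class(df)))
  df
}

#' Read animal records from a CSV file
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param dialect optional named character vector mapping canonical column
#'   names (e.g. \code{dmi_obs}) to the names used in the file. Unmapped
#'   columns are looked up under their canonical names.
#' @return an \code{\link{animal_records}} table, row order preserved.
#' @export
read_records <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- resolve_dialect(raw, dialect)
  for (col in c("bw_kg", MEASUREMENT_COLS)) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(num <- as.numeric(df[[col]]))
      bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(num))
      if (length(bad) > 0L) {
        stop("non-numeric value in column '", col, "' at row(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      df[[col]] <- num
    }
  }
  animal_records(df)
}

resolve_dialect <- function(raw, dialect) {
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (col in RECORD_COLS) {
    src <- if (!is.null(dialect) && col %in% names(dialect)) dialect[[col]] else col
    if (!src %in% names(raw)) {
      stop("required column '", col, "' not found in file",
           if (!identical(src, col)) paste0(" (mapped to '", src, "')"),
           call. = FALSE)
    }
    out[[col]] <- raw[[src]]
  }
  out
}

#' Write animal records to CSV
#'
#' Values are written at full precision so that a read/write round trip
#' preserves every field.
#'
#' @param records an \code{\link{animal_records}} table.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  df <- as.data.frame(records)[RECORD_COLS]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive non-structural carbohydrate content by difference
#'
#' NSC is computed as organic matter minus the assayed fractions:
#' \code{NSC = (100 - ash) - cp - ndf - ee}, all as \% of dry matter. The
#' identity \code{nsc + cp + ndf + ee + ash = 100} holds exactly.
#'
#' @param cp crude protein, \% DM.
#' @param ndf neutral detergent fiber, \% DM.
#' @param ee ether extract (fat), \% DM.
#' @param ash ash, \% DM.
#' @return NSC, \% DM. Vectorized.
#' @export
derive_nsc <- function(cp, ndf, ee, ash) {
  for (v in list(cp = cp, ndf = ndf, ee = ee, ash = ash)) {
    if (any(!is.finite(v) | v <= 0 | v >= 100)) {
      stop("composition fractions must lie in (0, 100)", call. = FALSE)
    }
  }
  nsc <- 100 - ash - cp - ndf - ee
  if (any(nsc <= 0)) {
    stop("derived NSC is not positive: composition is inconsistent ",
         "(cp + ndf + ee + ash >= 100)", call. = FALSE)
  }
  nsc
}

#' Validate a table of diet compositions
#'
#' One row per forage diet: crude protein (cp), neutral detergent fiber (ndf),
#' non-structural carbohydrates (nsc), ether extract (ee), ash, all as \% of
#' DM; in vitro DM digestibility (ivdmd, \%); and a logical \code{leucaena}
#' flag marking diets containing any Leucaena species. Printed compositions
#' are rounded, so the sum check and the NSC-by-difference cross-check both
#' allow 0.15 percentage points of slack.
#'
#' @param df data.frame with the columns above (optionally
#'   \code{leucaena_species}).
#' @return the validated data.frame with class \code{diet_compositions}.
#' @export
diet_compositions <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(DIET_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required diet column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$diet_id)) stop("duplicate diet_id", call. = FALSE)
  df$leucaena <- as.logical(df$leucaena)
  for (col in c("cp", "ndf", "nsc", "ee", "ash", "ivdmd")) {
    v <- df[[col]]
    if (any(!is.finite(v) | v <= 0 | v >= 100)) {
      stop("diet column '", col, "' must lie in (0, 100)", call. = FALSE)
    }
  }
  tot <- df$cp + df$ndf + df$nsc + df$ee + df$ash
  if (any(tot > 100 + NSC_TOLERANCE)) {
    stop("cp + ndf + nsc + ee + ash exceeds 100 beyond rounding tolerance ",
         "for diet(s): ",
         paste(df$diet_id[tot > 100 + NSC_TOLERANCE], collapse = ", "),
         call. = FALSE)
  }
  derived <- 100 - df$ash - df$cp - df$ndf - df$ee
  off <- abs(derived - df$nsc) > NSC_TOLERANCE
  if (any(off)) {
    stop("nsc inconsistent with NSC-by-difference beyond tolerance for ",
         "diet(s): ", paste(df$diet_id[off], collapse = ", "), call. = FALSE)
  }
  class(df) <- unique(c("diet_compositions", class(df)))
  df
}

#' Read diet compositions from CSV
#'
#' @param path path to a CSV with the \code{\link{diet_compositions}} columns.
#' @return a validated \code{diet_compositions} table.
#' @export
read_diets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  diet_compositions(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' The packaged six tropical forage diets
#'
#' Nutritional composition of the six forage diets of the study design:
#' three grass/grass-legume diets without Leucaena and three with Leucaena
#' (\emph{L. diversifolia} or \emph{L. leucocephala}).
#'
#' @return a \code{\link{diet_compositions}} table with 6 rows.
#' @export
default_diets <- function() {
  path <- system.file("extdata", "forage_diets.csv", package = "rumeval",
                      mustWork = TRUE)
  read_diets(path)
}

#' Construct a paired observed/simulated series
#'
#' The container every evaluation statistic consumes: aligned observed
#' (\code{o}) and simulated (\code{s}) vectors with a group label per pair.
#' Observed values must be strictly positive so that S/O ratios are defined.
#'
#' @param o observed values.
#' @param s simulated values.
#' @param group group labels (default: single group \code{"all"}).
#' @param variable \code{"dmi"} or \code{"ch4"}.
#' @param units unit string; defaulted from \code{variable} when \code{NULL}.
#' @return an object of class \code{paired_series}.
#' @export
paired_series <- function(o, s, group = NULL,
                          variable = c("dmi", "ch4"), units = NULL) {
  variable <- match.arg(variable)
  o <- as.numeric(o)
  s <- as.numeric(s)
  if (length(o) < 1L) stop("paired series must be non-empty", call. = FALSE)
  if (length(o) != length(s)) stop("o and s lengths differ", call. = FALSE)
  if (is.null(group)) group <- rep("all", length(o))
  if (length(group) != length(o)) stop("group length differs", call. = FALSE)
  if (any(!is.finite(o)) || any(!is.finite(s))) {
    stop("o and s must be finite", call. = FALSE)
  }
  bad <- which(o <= 0)
  if (length(bad) > 0L) {
    stop("observed values must be strictly positive (S/O undefined) at ",
         "index(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(units)) {
    units <- if (variable == "dmi") "kg DM/d" else "L/d"
  }
  structure(list(o = o, s = s, group = group,
                 variable = variable, units = units),
            class = "paired_series")
}

#' @export
length.paired_series <- function(x) length(x$o)

#' @export
print.paired_series <- function(x, ...) {
  cat("paired_series:", length(x$o), "pairs of", x$variable,
      paste0("(", x$units, ")"), "\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$group)),
                                 table(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Extract a paired series from animal records
#'
#' Pairs the observed and simulated values of one variable and labels each
#' pair with the Leucaena flag of the record's diet. Records with a missing
#' observed or simulated value for the requested variable are rejected.
#'
#' @param records an \code{\link{animal_records}} table.
#' @param variable \code{"dmi"} or \code{"ch4"}.
#' @param diets a \code{\link{diet_compositions}} table covering every
#'   \code{diet_id} in \code{records}.
#' @return a \code{\link{paired_series}} with logical Leucaena group labels.
#' @export
to_paired <- function(records, variable = c("dmi", "ch4"), diets) {
  variable <- match.arg(variable)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  unknown <- setdiff(unique(records$diet_id), diets$diet_id)
  if (length(unknown) > 0L) {
    stop("diet_id not found in diet table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  o <- records[[paste0(variable, "_obs")]]
  s <- records[[paste0(variable, "_sim")]]
  if (anyNA(o) || anyNA(s)) {
    stop("variable '", variable, "' missing in row(s): ",
         paste(which(is.na(o) | is.na(s)), collapse = ", "), call. = FALSE)
  }
  leuc <- diets$leucaena[match(records$diet_id, diets$diet_id)]
  paired_series(o, s, group = leuc, variable = variable)
}
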