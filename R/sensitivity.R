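# One-at-a-time (OAT) forage-quality sensitivity analysis: substitute each
# quality variable with levels spanning its range across the diet table, one
# variable at a time with each diet as base, and summarize the direction of
# the methane response plus a PCA of the run matrix.

QUALITY_VARS <- c("ndf", "nsc", "ee", "ash", "cp", "ivdmd")

#' Build a one-at-a-time substitution design
#'
#' For each base diet and each quality variable, the variable is replaced by
#' \code{levels_per_variable} values evenly spaced between the minimum and
#' maximum recorded across the diet table (the default 2 levels are exactly
#' min and max), all other variables held at the base diet's values. NSC is
#' substituted as an independent input, not re-derived by difference.
#'
#' @param diets a \code{\link{diet_compositions}} table with >= 2 diets.
#' @param levels_per_variable number of substitution levels (>= 2).
#' @param include_baseline also include each unmodified base diet as a run.
#' @return an object of class \code{oat_design}: \code{bases},
#'   \code{variables}, \code{levels} (named list), \code{include_baseline},
#'   \code{n_runs}.
#' @export
build_oat_design <- function(diets, levels_per_variable = 2L,
                             include_baseline = TRUE) {
  if (nrow(diets) < 2L) {
    stop("need at least 2 diets to span a min/max range", call. = FALSE)
  }
  if (levels_per_variable < 2L) stop("levels_per_variable must be >= 2",
                                     call. = FALSE)
  levels <- list()
  vars <- character(0)
  for (v in QUALITY_VARS) {
    rng <- range(diets[[v]])
    if (rng[1] == rng[2]) {
      warning("variable '", v, "' is constant across diets; skipped",
              call. = FALSE)
      next
    }
    levels[[v]] <- seq(rng[1], rng[2], length.out = levels_per_variable)
    vars <- c(vars, v)
  }
  if (length(vars) == 0L) stop("no variable has a non-degenerate range",
                               call. = FALSE)
  n_runs <- nrow(diets) * length(vars) * levels_per_variable +
    if (include_baseline) nrow(diets) else 0L
  structure(list(bases = diets, variables = vars, levels = levels,
                 include_baseline = include_baseline, n_runs = n_runs),
            class = "oat_design")
}

#' Run a sensitivity analysis over an OAT design
#'
#' Executes the predictor on every design run, derives a consensus influence
#' sign per variable (the min-to-max methane difference must agree across
#' every base diet; disagreement is reported as \code{"mixed"}), and
#' summarizes the run matrix by PCA. The PCA input is the standardized
#' matrix of the six quality-variable values actually used in each run plus
#' the predicted methane; substitution runs only.
#'
#' @param design an \code{\link{build_oat_design}} result.
#' @param model a \code{predictor_model}.
#' @param bw_kg body weight used for every prediction, kg.
#' @param seed optional; only consulted if the model is stochastic (the stub
#'   is deterministic).
#' @return an object of class \code{sensitivity_result}: \code{runs}
#'   (data.frame: base_diet, variable, value, dmi_pred, ch4_pred, failed),
#'   \code{signs} (named character: "+", "-", "0" or "mixed"), \code{pca}
#'   (list: loadings, explained_variance, degenerate), \code{n_failed}.
#' @export
run_sensitivity <- function(design, model, bw_kg = 206, seed = NULL) {
  stopifnot(inherits(design, "oat_design"))
  if (!is.null(seed)) set.seed(seed)
  bases <- design$bases
  rows <- list()
  for (i in seq_len(nrow(bases))) {
    base <- as.list(bases[i, , drop = FALSE])
    if (design$include_baseline) {
      rows[[length(rows) + 1L]] <-
        one_run(model, base, bw_kg, base$diet_id, "baseline", NA_real_)
    }
    for (v in design$variables) {
      for (val in design$levels[[v]]) {
        mod <- base
        mod[[v]] <- val
        rows[[length(rows) + 1L]] <-
          one_run(model, mod, bw_kg, base$diet_id, v, val)
      }
    }
  }
  runs <- do.call(rbind, rows)
  n_failed <- sum(runs$failed)
  if (n_failed > 0L) {
    warning(n_failed, " run(s) failed and are excluded from summaries",
            call. = FALSE)
  }
  ok <- runs[!runs$failed, , drop = FALSE]
  signs <- consensus_signs(ok, design)
  pca <- run_pca(ok, bases, design$variables)
  structure(list(runs = runs, signs = signs, pca = pca,
                 n_failed = n_failed),
            class = "sensitivity_result")
}

one_run <- function(model, diet, bw_kg, base_id, variable, value) {
  pred <- tryCatch(model$predict(diet, bw_kg), error = function(e) NULL)
  failed <- is.null(pred) || !is.finite(pred$ch4_pred) ||
    !is.finite(pred$dmi_pred)
  data.frame(base_diet = base_id, variable = variable, value = value,
             dmi_pred = if (failed) NA_real_ else pred$dmi_pred,
             ch4_pred = if (failed) NA_real_ else pred$ch4_pred,
             failed = failed, stringsAsFactors = FALSE)
}

# unanimity across bases; any disagreement is "mixed", per-base zero stays 0
consensus_signs <- function(runs, design) {
  out <- character(0)
  for (v in design$variables) {
    sub <- runs[runs$variable == v, , drop = FALSE]
    per_base <- vapply(unique(sub$base_diet), function(b) {
      bb <- sub[sub$base_diet == b, , drop = FALSE]
      bb <- bb[order(bb$value), , drop = FALSE]
      if (nrow(bb) < 2L) return(NA_integer_)
      as.integer(sign(bb$ch4_pred[nrow(bb)] - bb$ch4_pred[1L]))
    }, integer(1))
    per_base <- per_base[!is.na(per_base)]
    out[[v]] <- if (length(per_base) == 0L) {
      "mixed"
    } else if (all(per_base == per_base[1L])) {
      c(`-1` = "-", `0` = "0", `1` = "+")[[as.character(per_base[1L])]]
    } else {
      "mixed"
    }
  }
  out
}

run_pca <- function(runs, bases, variables) {
  sub <- runs[runs$variable != "baseline", , drop = FALSE]
  # reconstruct the full input vector of each run: base values with the
  # varied variable substituted
  mat <- vapply(QUALITY_VARS, function(v) {
    base_vals <- bases[[v]][match(sub$base_diet, bases$diet_id)]
    ifelse(sub$variable == v, sub$value, base_vals)
  }, numeric(nrow(sub)))
  mat <- cbind(mat, ch4_pred = sub$ch4_pred)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    return(list(loadings = NULL, explained_variance = NULL,
                degenerate = TRUE))
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  list(loadings = pc$rotation,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2),
       degenerate = FALSE)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("sensitivity_result:", nrow(x$runs), "runs",
      if (x$n_failed > 0) paste0("(", x$n_failed, " failed)"), "\n")
  cat("  methane influence signs:\n")
  for (v in names(x$signs)) cat(sprintf("    %-6s %s\n", v, x$signs[[v]]))
  if (!isTRUE(x$pca$degenerate)) {
    cat("  PCA explained variance:",
        paste(sprintf("%.1f%%", 100 * x$pca$explained_variance[1:3]),
              collapse = ", "), "(first 3 components)\n")
  }
  invisible(x)
}
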