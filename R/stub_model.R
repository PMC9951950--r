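# Pluggable predictor interface and a stoichiometric stub model.
#
# The stub is NOT the dynamic rumen fermentation model it stands in for: it
# is a minimal Wolin-type stoichiometry whose response directions to forage
# quality are the normative contract (CH4 decreasing in NDF, NSC, fat, ash;
# increasing in CP and IVDMD). The constants are calibration, not science.

#' Parameters of the stub intake/methane predictor
#'
#' Intake: \code{dmi = c_i * bw^0.75 * (ndf_ref / ndf)^theta} — metabolic
#' body size times an NDF fill constraint. Methane: fermentable substrate
#' mass (digestible fiber inhibited by the non-structural carbohydrate share
#' \code{phi = nsc / (nsc + ndf)}, plus digestible NSC, scaled by protein
#' sufficiency, fat and ash penalties) is converted to CH4 through a
#' hexose-based yield \code{y0 - y1 * phi} (mol CH4 per mol hexose) and the
#' molar volume of an ideal gas.
#'
#' @param c_i intake scale, kg DM per kg^0.75 per day.
#' @param theta NDF fill exponent.
#' @param ndf_ref reference NDF, \% DM.
#' @param gamma inhibition of fiber digestion by the NSC share.
#' @param d_s NSC digestibility.
#' @param k_cp crude-protein half-saturation, \% DM.
#' @param kappa_ee fat penalty per unit EE fraction.
#' @param lambda_ash ash penalty per unit ash fraction.
#' @param y0,y1 methane-yield intercept and slope, mol CH4 per mol hexose.
#' @param c_m calibration scale for methane output.
#' @param hexose_mm hexose molar mass, g/mol.
#' @param molar_vol molar gas volume, L/mol.
#' @return named list of class \code{stub_params}.
#' @export
stub_params <- function(c_i = 0.095, theta = 1.25, ndf_ref = 65,
                        gamma = 0.8, d_s = 0.9, k_cp = 4,
                        kappa_ee = 2, lambda_ash = 0.5,
                        y0 = 0.44, y1 = 0.60, c_m = 1.6,
                        hexose_mm = 162, molar_vol = 22.4) {
  params <- list(c_i = c_i, theta = theta, ndf_ref = ndf_ref, gamma = gamma,
                 d_s = d_s, k_cp = k_cp, kappa_ee = kappa_ee,
                 lambda_ash = lambda_ash, y0 = y0, y1 = y1, c_m = c_m,
                 hexose_mm = hexose_mm, molar_vol = molar_vol)
  if (any(vapply(params, function(v) !is.finite(v) || v <= 0, logical(1)))) {
    stop("all stub parameters must be positive and finite", call. = FALSE)
  }
  # the yield must stay positive over the realistic NSC-share range
  if (y0 - y1 * 0.35 <= 0) {
    stop("methane yield y0 - y1*phi must be positive over phi in [0, 0.35]",
         call. = FALSE)
  }
  structure(params, class = "stub_params")
}

#' Stub prediction of intake and methane for one diet
#'
#' @param diet a single diet: one row of a \code{\link{diet_compositions}}
#'   table (or a named list with \code{cp}, \code{ndf}, \code{nsc},
#'   \code{ee}, \code{ash}, \code{ivdmd}).
#' @param bw_kg body weight, kg.
#' @param params a \code{\link{stub_params}} object.
#' @return list with \code{dmi_pred} (kg DM/animal/day) and \code{ch4_pred}
#'   (L/animal/day).
#' @export
stub_predict <- function(diet, bw_kg, params = stub_params()) {
  if (is.data.frame(diet)) {
    if (nrow(diet) != 1L) stop("stub_predict takes a single diet",
                               call. = FALSE)
    diet <- as.list(diet)
  }
  if (!is.finite(bw_kg) || bw_kg <= 0) stop("bw_kg must be positive",
                                            call. = FALSE)
  with(c(diet, unclass(params)), {
    dmi <- c_i * bw_kg^0.75 * (ndf_ref / ndf)^theta
    phi <- nsc / (nsc + ndf)
    if (!is.finite(phi) || phi < 0 || phi >= 1) {
      stop("NSC share phi = nsc/(nsc+ndf) outside [0, 1)", call. = FALSE)
    }
    yield <- y0 - y1 * phi
    if (yield <= 0) stop("negative methane yield at phi = ", round(phi, 3),
                         call. = FALSE)
    fermentable <- dmi * 1000 *
      ((ndf / 100) * (ivdmd / 100) * (1 - gamma * phi) +
         (nsc / 100) * d_s) *
      (cp / (cp + k_cp)) *
      (1 - kappa_ee * ee / 100) *
      (1 - lambda_ash * ash / 100)
    list(dmi_pred = dmi,
         ch4_pred = c_m * (fermentable / hexose_mm) * yield * molar_vol)
  })
}

# registry so a genuine mechanistic model can be dropped in by name
predictor_registry <- new.env(parent = emptyenv())

#' Register a predictor model under a name
#'
#' A predictor model is a \code{predict} function with signature
#' \code{(diet, bw_kg)} returning a list with \code{dmi_pred} and
#' \code{ch4_pred}, both strictly positive for valid inputs.
#'
#' @param name registry key.
#' @param predict the prediction function.
#' @param parameters named constants stored with the model.
#' @return the registered \code{predictor_model}, invisibly.
#' @export
register_predictor <- function(name, predict, parameters = list()) {
  stopifnot(is.character(name), length(name) == 1L, is.function(predict))
  model <- structure(list(name = name, predict = predict,
                          parameters = parameters),
                     class = "predictor_model")
  assign(name, model, envir = predictor_registry)
  invisible(model)
}

#' Look up a registered predictor model
#'
#' @param name registry key; \code{"stub"} is always available.
#' @return a \code{predictor_model}.
#' @export
get_predictor <- function(name) {
  if (!exists(name, envir = predictor_registry, inherits = FALSE)) {
    stop("no predictor registered under '", name, "'; available: ",
         paste(ls(predictor_registry), collapse = ", "), call. = FALSE)
  }
  get(name, envir = predictor_registry, inherits = FALSE)
}

.onLoad <- function(libname, pkgname) {
  params <- stub_params()
  register_predictor("stub",
                     function(diet, bw_kg) stub_predict(diet, bw_kg, params),
                     parameters = unclass(params))
}

#' Sign of the methane response to each forage-quality variable
#'
#' For each variable, predicts methane at the range minimum and maximum with
#' every other variable held at the diet's value and returns
#' \code{sign(ch4(max) - ch4(min))}.
#'
#' @param model a \code{predictor_model} (see \code{\link{get_predictor}}).
#' @param diet the base diet (single row or named list).
#' @param bw_kg body weight, kg.
#' @param var_ranges named list of \code{c(min, max)} per variable.
#' @return named integer vector of signs (-1, 0, +1).
#' @export
finite_difference_signs <- function(model, diet, bw_kg, var_ranges) {
  if (is.data.frame(diet)) diet <- as.list(diet)
  vapply(names(var_ranges), function(v) {
    rng <- var_ranges[[v]]
    lo <- diet; lo[[v]] <- rng[1]
    hi <- diet; hi[[v]] <- rng[2]
    ch4 <- vapply(list(lo, hi), function(d) {
      out <- model$predict(d, bw_kg)$ch4_pred
      if (!is.finite(out)) stop("non-finite methane prediction while ",
                                "varying '", v, "'", call. = FALSE)
      out
    }, numeric(1))
    as.integer(sign(ch4[2] - ch4[1]))
  }, integer(1))
}
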