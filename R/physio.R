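# Derived coronary hemodynamic and metabolic quantities. All operations are
# elementwise and vectorized over per-timepoint panels. Sign conventions:
# lactate flux positive = consumption; PCO2 gradient is veno-arterial (v - a).

#' Coronary perfusion pressure
#'
#' CPP = mean aortic pressure minus mean right atrial pressure, the gradient
#' driving coronary flow during resuscitation. Negative values are returned
#' as-is.
#'
#' @param map_mmHg Mean aortic pressure (mmHg).
#' @param rap_mmHg Mean right atrial pressure (mmHg).
#' @return CPP in mmHg.
#' @export
coronary_perfusion_pressure <- function(map_mmHg, rap_mmHg) {
  stopifnot(all(is.finite(map_mmHg)), all(is.finite(rap_mmHg)))
  map_mmHg - rap_mmHg
}

#' Fick myocardial oxygen delivery, consumption and extraction
#'
#' MDO2 = flow x arterial O2 content; MVO2 = flow x arteriovenous O2 content
#' difference; extraction = (CaO2 - CvO2)/CaO2. When flow is expressed as
#' percent of baseline, MDO2/MVO2 are meaningful only relative to their own
#' baseline values (see [percent_of_baseline()]).
#'
#' @param lad_flow LAD coronary flow (native units or % of baseline), >= 0.
#' @param cao2_mldl Arterial O2 content (ml/dl).
#' @param cvo2_mldl Great-cardiac-vein O2 content (ml/dl).
#' @param extraction Compute the extraction fraction (default `TRUE`);
#'   requires `cao2_mldl > 0`.
#' @return A data frame with columns `mdo2`, `mvo2`, and (if requested)
#'   `extraction_fraction`.
#' @export
fick_o2 <- function(lad_flow, cao2_mldl, cvo2_mldl, extraction = TRUE) {
  stopifnot(all(lad_flow >= 0), all(cao2_mldl >= 0), all(cvo2_mldl >= 0))
  out <- data.frame(mdo2 = lad_flow * cao2_mldl,
                    mvo2 = lad_flow * (cao2_mldl - cvo2_mldl))
  if (extraction) {
    if (any(cao2_mldl == 0)) {
      stop("extraction fraction undefined where arterial O2 content is 0")
    }
    out$extraction_fraction <- (cao2_mldl - cvo2_mldl) / cao2_mldl
  }
  out
}

#' Myocardial lactate flux
#'
#' Flow times the arteriovenous lactate difference. Positive values indicate
#' net consumption, negative net production.
#'
#' @param lad_flow LAD coronary flow.
#' @param lac_a_mM Arterial lactate (mmol/l).
#' @param lac_v_mM Great-cardiac-vein lactate (mmol/l).
#' @return Lactate flux (flow units x mmol/l); attribute `sign_convention`
#'   states the direction.
#' @export
lactate_flux <- function(lad_flow, lac_a_mM, lac_v_mM) {
  stopifnot(all(is.finite(lad_flow)), all(is.finite(lac_a_mM)),
            all(is.finite(lac_v_mM)))
  structure(lad_flow * (lac_a_mM - lac_v_mM),
            sign_convention = "positive = consumption, negative = production")
}

#' Veno-arterial coronary PCO2 gradient
#'
#' Great-cardiac-vein PCO2 minus arterial PCO2; rises with anaerobic
#' myocardial metabolism.
#'
#' @param pvco2_mmHg Great-cardiac-vein PCO2 (mmHg).
#' @param paco2_mmHg Arterial PCO2 (mmHg).
#' @return Gradient in mmHg (veno-arterial, v - a).
#' @export
pco2_gradient <- function(pvco2_mmHg, paco2_mmHg) {
  stopifnot(all(is.finite(pvco2_mmHg)), all(is.finite(paco2_mmHg)))
  pvco2_mmHg - paco2_mmHg
}

#' Express a value as percent of its baseline
#'
#' @param value Measured value(s).
#' @param baseline Baseline value (nonzero).
#' @return `100 * value / baseline`.
#' @export
percent_of_baseline <- function(value, baseline) {
  if (any(baseline == 0)) stop("baseline must be nonzero")
  100 * value / baseline
}

#' Derive the full physiological panel for a table of samples
#'
#' Applies all derived quantities elementwise to a table with one row per
#' (subject, timepoint): CPP, Fick MDO2/MVO2/extraction, lactate flux, and
#' the veno-arterial PCO2 gradient. Columns absent from the input yield
#' absent outputs rather than errors.
#'
#' @param panel Data frame with (any of) columns `map_mmHg`, `rap_mmHg`,
#'   `lad_flow`, `cao2_mldl`, `cvo2_mldl`, `lac_a_mM`, `lac_v_mM`,
#'   `paco2_mmHg`, `pvco2_mmHg`, plus identifier columns that are carried
#'   through.
#' @return The input data frame with derived columns `cpp_mmHg`, `mdo2`,
#'   `mvo2`, `extraction_fraction`, `lactate_flux`, `pco2_gradient_mmHg`
#'   appended where computable.
#' @export
derive_physio <- function(panel) {
  has <- function(...) all(c(...) %in% names(panel))
  out <- panel
  if (has("map_mmHg", "rap_mmHg")) {
    out$cpp_mmHg <- coronary_perfusion_pressure(panel$map_mmHg, panel$rap_mmHg)
  }
  if (has("lad_flow", "cao2_mldl", "cvo2_mldl")) {
    fick <- fick_o2(panel$lad_flow, panel$cao2_mldl, panel$cvo2_mldl)
    out$mdo2 <- fick$mdo2
    out$mvo2 <- fick$mvo2
    out$extraction_fraction <- fick$extraction_fraction
  }
  if (has("lad_flow", "lac_a_mM", "lac_v_mM")) {
    out$lactate_flux <- as.numeric(
      lactate_flux(panel$lad_flow, panel$lac_a_mM, panel$lac_v_mM))
  }
  if (has("pvco2_mmHg", "paco2_mmHg")) {
    out$pco2_gradient_mmHg <- pco2_gradient(panel$pvco2_mmHg, panel$paco2_mmHg)
  }
  out
}
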