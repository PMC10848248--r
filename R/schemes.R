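# Nelsen four-point reorganization-energy arithmetic and the two prediction
# schemes: dual IP/EA models, and direct lambda prediction from cheap
# conformers.

#' Four-point energy quadruple
#'
#' The four total energies of the Nelsen four-point method: each redox state
#' (neutral superscript, cation superscript) evaluated at each state's
#' optimized geometry (subscript). All values in eV.
#'
#' All four fields accept equal-length vectors, in which case the object
#' represents one quadruple per element and the derived quantities are
#' vectorized.
#'
#' @param e_neutral_at_neutral Neutral-state energy at the neutral geometry.
#' @param e_neutral_at_cation Neutral-state energy at the cation geometry.
#' @param e_cation_at_neutral Cation-state energy at the neutral geometry.
#' @param e_cation_at_cation Cation-state energy at the cation geometry.
#' @return An `energy_quadruple`.
#' @export
energy_quadruple <- function(e_neutral_at_neutral, e_neutral_at_cation,
                             e_cation_at_neutral, e_cation_at_cation) {
  q <- structure(
    list(
      e_neutral_at_neutral = as.numeric(e_neutral_at_neutral),
      e_neutral_at_cation = as.numeric(e_neutral_at_cation),
      e_cation_at_neutral = as.numeric(e_cation_at_neutral),
      e_cation_at_cation = as.numeric(e_cation_at_cation)
    ),
    class = "energy_quadruple"
  )
  if (length(unique(lengths(unclass(q)))) != 1L) {
    stop("energy quadruple fields must have equal length")
  }
  vals <- unlist(q, use.names = FALSE)
  if (!all(is.finite(vals))) stop("energy quadruple contains non-finite values")
  q
}

#' Vertical ionization potential from a quadruple
#'
#' IP evaluated at the neutral geometry without relaxation:
#' `E^+_neutral - E^0_neutral`.
#'
#' @param q An `energy_quadruple`.
#' @return Vertical IP in eV (non-negative for physically consistent surfaces).
#' @export
vertical_ip <- function(q) {
  stopifnot(inherits(q, "energy_quadruple"))
  q$e_cation_at_neutral - q$e_neutral_at_neutral
}

#' Vertical electron affinity (of the cation) from a quadruple
#'
#' EA of the cation evaluated at the cation geometry:
#' `E^+_cation - E^0_cation`.
#'
#' @param q An `energy_quadruple`.
#' @return Vertical EA in eV.
#' @export
vertical_ea <- function(q) {
  stopifnot(inherits(q, "energy_quadruple"))
  q$e_cation_at_cation - q$e_neutral_at_cation
}

#' Nelsen four-point reorganization energy
#'
#' The sum of the two relaxation terms,
#' `(E^+_neutral - E^+_cation) + (E^0_cation - E^0_neutral)`, algebraically
#' equal to `vertical_ip(q) - vertical_ea(q)`. Negative values are possible
#' for unphysical inputs (e.g. model predictions) and are reported with a
#' warning, never clipped: they are a useful diagnostic of poor
#' generalization.
#'
#' @param q An `energy_quadruple`.
#' @return Reorganization energy lambda in eV.
#' @export
four_point_lambda <- function(q) {
  stopifnot(inherits(q, "energy_quadruple"))
  lam <- (q$e_cation_at_neutral - q$e_cation_at_cation) +
    (q$e_neutral_at_cation - q$e_neutral_at_neutral)
  if (any(lam < 0)) {
    warning(
      "negative reorganization energy (min ",
      format(min(lam), digits = 4), " eV)"
    )
  }
  lam
}

group_by_molecule <- function(records) {
  ids <- vapply(records, function(r) r$molecule_id, character(1))
  split(records, factor(ids, levels = unique(ids)))
}

#' Dual-model reorganization energy prediction
#'
#' The dual scheme of separate vertical-IP and vertical-EA regressors:
#' lambda-hat = mean over neutral conformers of the IP model's output minus
#' mean over cation conformers of the EA model's output.
#'
#' @param ip_model `reorg_model` trained on task `"vertical_ip"`.
#' @param ea_model `reorg_model` trained on task `"vertical_ea"`.
#' @param neutral_records Featurized records of neutral-state conformers.
#' @param cation_records Featurized records of cation-state conformers.
#' @return data.frame: molecule_id, ip_pred_eV, ea_pred_eV, lambda_pred_eV,
#'   n_neutral, n_cation.
#' @export
predict_lambda_dual <- function(ip_model, ea_model, neutral_records, cation_records) {
  if (!identical(ip_model$featurization_version, ea_model$featurization_version)) {
    stop("IP and EA models use different featurization versions")
  }
  neu <- group_by_molecule(neutral_records)
  cat_ <- group_by_molecule(cation_records)
  ids <- union(names(neu), names(cat_))
  missing_n <- setdiff(ids, names(neu))
  missing_c <- setdiff(ids, names(cat_))
  if (length(missing_n) || length(missing_c)) {
    stop(
      "molecules missing a conformer state: ",
      paste(unique(c(missing_n, missing_c)), collapse = ", ")
    )
  }
  ip <- vapply(neu[ids], function(rs) mean(predict_records(ip_model, rs)), numeric(1))
  ea <- vapply(cat_[ids], function(rs) mean(predict_records(ea_model, rs)), numeric(1))
  data.frame(
    molecule_id = ids,
    ip_pred_eV = unname(ip),
    ea_pred_eV = unname(ea),
    lambda_pred_eV = unname(ip - ea),
    n_neutral = unname(lengths(neu[ids])),
    n_cation = unname(lengths(cat_[ids])),
    row.names = NULL
  )
}

#' Direct reorganization energy prediction from cheap conformers
#'
#' lambda-hat per molecule is the arithmetic mean of the model's outputs over
#' the supplied conformers; the across-conformer population variance is
#' returned alongside as the robustness diagnostic.
#'
#' @param model `reorg_model` trained on task `"lambda_direct"`.
#' @param records Featurized conformer records (>= 1 per molecule).
#' @return data.frame: molecule_id, lambda_pred_eV, conformer_variance_eV2,
#'   n_conformers.
#' @export
predict_lambda_direct <- function(model, records) {
  if (length(records) == 0L) stop("no conformer records supplied")
  groups <- group_by_molecule(records)
  preds <- lapply(groups, function(rs) predict_records(model, rs))
  data.frame(
    molecule_id = names(groups),
    lambda_pred_eV = vapply(preds, mean, numeric(1)),
    conformer_variance_eV2 = vapply(preds, pop_var, numeric(1)),
    n_conformers = unname(lengths(groups)),
    row.names = NULL
  )
}

# Population variance (divide by n, not n - 1): the convention used for the
# cross-conformer prediction-variance diagnostic.
pop_var <- function(x) {
  mean((x - mean(x))^2)
}
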