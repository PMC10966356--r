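# Closeness metrics between experimental and modeled CD spectra, and
# the absolute-mass normalization of model spectra against experiment.
# Mismatched grids are resampled by linear interpolation onto the
# overlapping interval; no extrapolation.

#' Normalized absolute deviation (NAD) between two spectra
#'
#' `sum_i |theta_exp_i - theta_mod_i| / sum_i |theta_exp_i|` over the M
#' overlapping grid points. 0 is a perfect match; 0.1 means a 10%
#' deviation relative to the experimental curve. Chosen over quadratic
#' metrics for robustness to outlying points.
#'
#' @param exp,mod [cd_spectrum()] objects (experimental, model).
#' @return Non-negative scalar.
#' @export
nad <- function(exp, mod) {
  cg <- common_grid(exp, mod)
  denom <- sum(abs(cg$exp))
  if (denom <= 0) stop("undefined metric: experimental spectrum has zero absolute mass")
  sum(abs(cg$exp - cg$mod)) / denom
}

#' Normalized root-mean-square deviation (NRMSD) between two spectra
#'
#' `sqrt(sum_i (theta_exp_i - theta_mod_i)^2 / sum_i theta_exp_i^2)`,
#' the quadratic analogue of [nad()].
#'
#' @inheritParams nad
#' @return Non-negative scalar.
#' @export
nrmsd <- function(exp, mod) {
  cg <- common_grid(exp, mod)
  denom <- sum(cg$exp^2)
  if (denom <= 0) stop("undefined metric: experimental spectrum has zero norm")
  sqrt(sum((cg$exp - cg$mod)^2) / denom)
}

#' Normalize a model spectrum against an experimental one
#'
#' Rescales the model by the single positive factor
#' `sum |theta_exp| / sum |theta_mod|`, so both spectra carry the same
#' absolute mass; the model's shape and signs are preserved. This is
#' the absolute-value-mass convention, not a least-squares fit.
#'
#' @inheritParams nad
#' @return The model as a [cd_spectrum()] on the overlapping grid,
#'   rescaled; the factor is attached as attribute `"factor"`.
#' @export
normalize_model <- function(exp, mod) {
  cg <- common_grid(exp, mod)
  me <- sum(abs(cg$exp)); mm <- sum(abs(cg$mod))
  if (me <= 0) stop("undefined normalization: experimental spectrum has zero absolute mass")
  if (mm <= 0) stop("undefined normalization: model spectrum has zero absolute mass")
  f <- me / mm
  out <- cd_spectrum(cg$grid, f * cg$mod,
                     per_residue = isTRUE(mod$meta$per_residue),
                     source = mod$meta$source)
  attr(out, "factor") <- f
  out
}
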