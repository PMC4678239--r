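#' Representative fold changes for the experiment presets
#'
#' The fold magnitude used to generate each abnormal condition's clinical
#' data: strong regulation for the steady-state demo (x1000 rates, x100 /
#' x0.01 molecules) and the oscillator's characteristic magnitudes (x100 /
#' x0.0001 rates, x10 / x0.01 molecules).
#'
#' @param model a `kin_model` (one of the demo models).
#' @param kind fault kind.
#' @return a single fold value.
#' @export
representative_fold <- function(model, kind) {
  kind <- match.arg(kind, FAULT_KINDS)
  folds <- if (model$oscillatory)
    c(rate_up = 100, rate_down = 1e-4, molecule_up = 10, molecule_down = 0.01)
  else
    c(rate_up = 1000, rate_down = 1e-3, molecule_up = 100, molecule_down = 0.01)
  unname(folds[kind])
}

#' Representative perturbation for an abnormal condition
#'
#' The experiment preset for one of the four abnormal conditions: the
#' candidate whose noise-free profile at the representative fold differs
#' most (lowest similarity S) from the normal profile. This is the ground
#' truth used by the noise- and density-robustness experiments.
#'
#' @param model a demo `kin_model`.
#' @param kind fault kind.
#' @param spec optional sampling grid for the selection comparison.
#' @return a `kin_perturbation`.
#' @export
representative_perturbation <- function(model, kind, spec = NULL) {
  select_representative(model, kind, representative_fold(model, kind), spec)
}
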