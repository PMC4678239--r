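#' The four fault kinds
#'
#' Single-target fault taxonomy: up/downregulation of one reaction rate
#' constant, or excess/deficiency of one preexisting molecule.
#' @export
FAULT_KINDS <- c("rate_up", "rate_down", "molecule_up", "molecule_down")

#' Define a single-target perturbation
#'
#' A fault hypothesis: one reaction rate constant or one preexisting
#' molecule's initial concentration, multiplied by a positive fold change.
#'
#' @param kind one of `"rate_up"`, `"rate_down"`, `"molecule_up"`,
#'   `"molecule_down"`.
#' @param target a rate-constant name (for `rate_*`) or the name of a state
#'   with nonzero initial concentration (for `molecule_*`).
#' @param fold positive multiplier; `> 1` for `*_up`, `< 1` for `*_down`
#'   (`fold = 1` is allowed as the degenerate identity).
#' @return an object of class `kin_perturbation`.
#' @export
perturbation <- function(kind, target, fold) {
  kind <- match.arg(kind, FAULT_KINDS)
  stopifnot(is.character(target), length(target) == 1L)
  if (!is.numeric(fold) || length(fold) != 1L || fold <= 0)
    stop("fold must be a single positive number")
  if (fold != 1) {
    up <- grepl("_up$", kind)
    if (up && fold < 1)
      stop("fold must be > 1 for ", kind)
    if (!up && fold > 1)
      stop("fold must be < 1 for ", kind)
  }
  structure(list(kind = kind, target = target, fold = fold),
            class = "kin_perturbation")
}

#' Apply a perturbation to a model
#'
#' Returns a copy of the model in which exactly one number changed: the
#' targeted rate constant (for `rate_*` kinds) or the targeted preexisting
#' initial concentration (for `molecule_*` kinds), multiplied by the fold.
#'
#' @param model a `kin_model`.
#' @param p a `kin_perturbation`.
#' @return the perturbed `kin_model`.
#' @export
apply_perturbation <- function(model, p) {
  stopifnot(inherits(model, "kin_model"), inherits(p, "kin_perturbation"))
  if (p$kind %in% c("rate_up", "rate_down")) {
    j <- match(p$target, model$rate_constant_names)
    if (is.na(j))
      stop("unknown rate constant target: ", p$target)
    model$rate_constants[j] <- model$rate_constants[j] * p$fold
    model$reactions[[j]]$k <- model$reactions[[j]]$k * p$fold
  } else {
    i <- match(p$target, model$state_names)
    if (is.na(i))
      stop("unknown molecule target: ", p$target)
    if (model$initial_state[i] <= 0)
      stop("molecule target ", p$target, " has zero initial concentration; ",
           "only preexisting molecules (nonzero before stimulation) can be ",
           "perturbed")
    model$initial_state[i] <- model$initial_state[i] * p$fold
  }
  model
}

#' @export
print.kin_perturbation <- function(x, ...) {
  cat(sprintf("<perturbation> %s %s x%g\n", x$kind, x$target, x$fold))
  invisible(x)
}
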