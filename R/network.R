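#' @useDynLib kinfault
#' @importFrom stats rnorm setNames median
#' @importFrom utils read.csv write.csv
NULL

KIN_PACKLEN <- 4096L

#' Construct a kinetic model from a mass-action reaction network
#'
#' A model is a list of irreversible mass-action reactions over named species,
#' driven by a constant extracellular stimulus switched on at t = 0. Each
#' reaction has a nonnegative rate constant; its flux is the rate constant
#' times the product of its reactant concentrations (to their kinetic orders),
#' optionally times the stimulus concentration. Species with nonzero initial
#' concentration are "preexisting": they are present before stimulation and
#' are the candidate targets for molecule-level faults.
#'
#' @param name model identifier.
#' @param initial_state named numeric vector of initial concentrations (nM),
#'   one per species; the names define the state ordering.
#' @param reactions list of reactions; each a list with elements `id`
#'   (unique reaction identifier), `k` (nonnegative rate constant),
#'   `reactants` (named numeric vector of kinetic orders over species; may be
#'   empty), `stoich` (named numeric vector of net stoichiometric change),
#'   and optional `stim` (stimulus kinetic order, default 0).
#' @param stimulus constant input concentration (nM) applied from t = 0.
#' @param stimulus_name identifier for the input species.
#' @param output_names character vector naming the measured output species
#'   (a nonempty subset of the state names).
#' @param oscillatory logical; whether the model's outputs are oscillatory,
#'   which enables R/A oscillation-feature confirmation during fault scans.
#' @param default_horizon_h default simulation horizon in hours.
#' @param rest_tol tolerance (nM/s) for the rest-point check: with the
#'   stimulus at zero the initial state must be an equilibrium.
#' @return an object of class `kin_model`.
#' @export
kinetic_model <- function(name, initial_state, reactions, stimulus,
                          stimulus_name = "u", output_names,
                          oscillatory = FALSE, default_horizon_h = 10,
                          rest_tol = 1e-9) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(names(initial_state)) || anyDuplicated(names(initial_state)))
    stop("initial_state must be a uniquely named numeric vector")
  if (any(initial_state < 0)) stop("initial concentrations must be nonnegative")
  state_names <- names(initial_state)

  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate reaction ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  k <- vapply(reactions, function(r) r$k, numeric(1))
  if (any(k < 0)) stop("rate constants must be nonnegative")
  names(k) <- ids

  for (r in reactions) {
    sp <- union(names(r$reactants), names(r$stoich))
    bad <- setdiff(sp, state_names)
    if (length(bad))
      stop("reaction ", r$id, " references unknown species: ",
           paste(bad, collapse = ", "))
    if (length(r$reactants) > 2L)
      stop("reaction ", r$id, ": at most two distinct reactant species supported")
  }

  model <- structure(list(
    name = name,
    state_names = state_names,
    initial_state = initial_state,
    rate_constant_names = ids,
    rate_constants = k,
    reactions = lapply(reactions, function(r) {
      r$stim <- if (is.null(r$stim)) 0 else r$stim
      r
    }),
    stimulus = stimulus,
    stimulus_name = stimulus_name,
    output_names = output_names,
    oscillatory = isTRUE(oscillatory),
    default_horizon_h = default_horizon_h,
    rest_tol = rest_tol
  ), class = "kin_model")

  validate_kin_model(model)
  model
}

#' Validate a kinetic model
#'
#' Checks the structural invariants: consistent lengths, nonnegative
#' concentrations and rate constants, resolvable unique outputs, and the
#' rest-point property (with stimulus 0 the initial state is an equilibrium
#' to within `rest_tol`), so that all post-stimulation dynamics are
#' attributable to the stimulus.
#'
#' @param model a `kin_model`.
#' @return the model, invisibly; errors describe the violated invariant.
#' @export
validate_kin_model <- function(model) {
  stopifnot(inherits(model, "kin_model"))
  if (length(model$initial_state) != length(model$state_names))
    stop("initial_state/state_names length mismatch")
  if (length(model$rate_constants) != length(model$rate_constant_names))
    stop("rate_constants/rate_constant_names length mismatch")
  if (any(model$initial_state < 0) || any(model$rate_constants < 0))
    stop("negative concentrations or rate constants")
  if (length(model$output_names) == 0L)
    stop("output_names must be nonempty")
  idx <- match(model$output_names, model$state_names)
  if (anyNA(idx) || anyDuplicated(idx))
    stop("output_names must resolve to unique states")
  d <- kin_rhs(model, model$initial_state, u = 0)
  if (max(abs(d)) > model$rest_tol)
    stop(sprintf(paste0("initial state is not a rest point at zero stimulus ",
                        "(max |dx/dt| = %.3g nM/s > %.3g)"),
                 max(abs(d)), model$rest_tol))
  invisible(model)
}

#' Evaluate the model right-hand side
#'
#' Pure-R evaluation of dx/dt at a given state and stimulus; used for
#' validation and as an independent check on the compiled integrator kernel.
#'
#' @param model a `kin_model`.
#' @param x named or ordered numeric state vector (nM).
#' @param u stimulus concentration (nM); defaults to the model's.
#' @return numeric vector of time derivatives (nM/s), named by state.
#' @export
kin_rhs <- function(model, x, u = model$stimulus) {
  x <- if (is.null(names(x))) setNames(as.numeric(x), model$state_names)
       else x[model$state_names]
  dx <- setNames(numeric(length(x)), model$state_names)
  for (r in model$reactions) {
    f <- r$k
    if (r$stim > 0) f <- f * u^r$stim
    if (length(r$reactants))
      f <- f * prod(x[names(r$reactants)]^r$reactants)
    dx[names(r$stoich)] <- dx[names(r$stoich)] + r$stoich * f
  }
  dx
}

#' Preexisting molecules of a model
#'
#' Species with strictly positive initial concentration: those present before
#' stimulation. They form the candidate universe for molecule-level faults.
#'
#' @param model a `kin_model`.
#' @return character vector of state names with `initial_state > 0`.
#' @export
preexisting_molecules <- function(model) {
  model$state_names[model$initial_state > 0]
}

# Pack the network into the fixed-length parameter vector consumed by the
# compiled RHS (layout documented in src/massaction.c).
pack_network <- function(model, u = model$stimulus) {
  ns <- length(model$state_names)
  nr <- length(model$reactions)
  p <- numeric(KIN_PACKLEN)
  p[1] <- ns; p[2] <- nr; p[3] <- u
  k <- vapply(model$reactions, function(r) r$k, numeric(1))
  stim <- vapply(model$reactions, function(r) r$stim, numeric(1))
  p[3 + seq_len(nr)] <- k
  p[3 + nr + seq_len(nr)] <- stim
  rx <- numeric(4 * nr)
  trip <- list()
  for (j in seq_len(nr)) {
    r <- model$reactions[[j]]
    if (length(r$reactants)) {
      idx <- match(names(r$reactants), model$state_names)
      for (m in seq_along(idx)) {
        rx[4 * (j - 1) + 2 * m - 1] <- idx[m]
        rx[4 * (j - 1) + 2 * m] <- r$reactants[m]
      }
    }
    si <- match(names(r$stoich), model$state_names)
    trip[[j]] <- rbind(si, j, as.numeric(r$stoich))
  }
  p[3 + 2 * nr + seq_len(4 * nr)] <- rx
  tr <- do.call(cbind, trip)
  nt <- ncol(tr)
  p[4 + 6 * nr] <- nt
  p[4 + 6 * nr + seq_len(3 * nt)] <- as.numeric(tr)
  p
}

#' Summarise a model as JSON
#'
#' Writes (or returns) a JSON summary: state names and initial values, rate
#' constant names and values, stimulus, outputs, and the preexisting set.
#'
#' @param model a `kin_model`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
model_summary_json <- function(model, path = NULL) {
  s <- list(
    name = model$name,
    states = as.list(model$initial_state),
    rate_constants = as.list(model$rate_constants),
    stimulus = setNames(list(model$stimulus), model$stimulus_name),
    outputs = model$output_names,
    preexisting = preexisting_molecules(model),
    oscillatory = model$oscillatory
  )
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @export
print.kin_model <- function(x, ...) {
  cat(sprintf("<kin_model> %s: %d states, %d reactions, stimulus %s = %g nM\n",
              x$name, length(x$state_names), length(x$reactions),
              x$stimulus_name, x$stimulus))
  cat("  outputs:", paste(x$output_names, collapse = ", "), "\n")
  cat("  preexisting:", paste(preexisting_molecules(x), collapse = ", "), "\n")
  invisible(x)
}
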