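#' Stack output profiles into a single column vector
#'
#' Concatenates the sampled profiles of each declared output, in a fixed
#' order, into one column vector. Multi-output comparisons (e.g. nuclear
#' dimer plus inhibitor) are scored on this stacked vector, so all profiles
#' must share one time grid.
#'
#' @param traj a `kin_trajectory`.
#' @param order character vector giving the output order; must cover the
#'   trajectory's outputs exactly once. Defaults to the trajectory's order.
#' @return an object of class `kin_stacked`: `values` (numeric vector),
#'   `labels` (the order used), `n_per_output` (samples per output).
#' @export
stack_profiles <- function(traj, order = traj$output_names) {
  stopifnot(inherits(traj, "kin_trajectory"))
  if (!setequal(order, traj$output_names) || anyDuplicated(order))
    stop("order must cover each declared output exactly once")
  v <- as.numeric(traj$values[, order])
  structure(list(values = v, labels = order,
                 n_per_output = nrow(traj$values), times = traj$times),
            class = "kin_stacked")
}

check_same_grid <- function(a, b) {
  if (length(a$values) != length(b$values) ||
      a$n_per_output != b$n_per_output)
    stop(sprintf("profile grids differ: %d vs %d samples per output",
                 a$n_per_output, b$n_per_output))
  if (!isTRUE(all.equal(a$times, b$times, tolerance = 1e-9)))
    stop("profile sample times differ")
  if (!identical(a$labels, b$labels))
    stop("profile output order differs: ", paste(a$labels, collapse = ","),
         " vs ", paste(b$labels, collapse = ","))
  invisible(TRUE)
}

#' Similarity score between clinical and model profiles
#'
#' The score S is the product of a shape term and a magnitude term.
#' The shape term is the normalized inner product (cosine) of the two
#' stacked profile vectors; the magnitude term is the reciprocal of the
#' symmetrised mean ratio, `2 m_c m_m / (m_c^2 + m_m^2)` where `m_c`, `m_m`
#' are the two profile means. Both terms are 1 for identical profiles and
#' S lies in \[0, 1\] for nonnegative profiles; it is symmetric in its
#' arguments. Degenerate inputs (zero norm or nonpositive mean) raise an
#' error rather than returning 0, so modelling bugs are not silently hidden.
#'
#' @param clinical,model `kin_stacked` profiles on the same grid, or plain
#'   numeric vectors of equal length.
#' @return an object of class `kin_similarity` with elements `S`,
#'   `shape_term`, `magnitude_term`, `mean_clinical`, `mean_model`.
#' @export
similarity_score <- function(clinical, model) {
  if (inherits(clinical, "kin_stacked") && inherits(model, "kin_stacked")) {
    check_same_grid(clinical, model)
    yc <- clinical$values; ym <- model$values
  } else {
    yc <- as.numeric(if (inherits(clinical, "kin_stacked")) clinical$values else clinical)
    ym <- as.numeric(if (inherits(model, "kin_stacked")) model$values else model)
    if (length(yc) != length(ym))
      stop(sprintf("profile lengths differ: %d vs %d", length(yc), length(ym)))
  }
  nc <- sqrt(sum(yc^2)); nm <- sqrt(sum(ym^2))
  mc <- mean(yc); mm <- mean(ym)
  if (nc == 0 || nm == 0 || mc <= 0 || mm <= 0)
    stop("similarity undefined: profile with zero norm or nonpositive mean")
  # identical vectors score exactly 1 in both terms (the cosine of a vector
  # with itself is 1 by identity, not by floating-point cancellation)
  shape <- if (identical(yc, ym)) 1 else sum(yc * ym) / (nc * nm)
  magnitude <- if (mc == mm) 1 else 1 / ((mc / mm + mm / mc) / 2)
  structure(list(S = shape * magnitude, shape_term = shape,
                 magnitude_term = magnitude,
                 mean_clinical = mc, mean_model = mm),
            class = "kin_similarity")
}

#' @export
print.kin_similarity <- function(x, ...) {
  cat(sprintf("S = %.6f (shape %.6f x magnitude %.6f)\n",
              x$S, x$shape_term, x$magnitude_term))
  invisible(x)
}

# Per-output S values for a pair of trajectories, plus the combined score.
# Errors in any single comparison propagate (callers that rank map them).
per_output_similarity <- function(clin_traj, model_traj, order) {
  combined <- similarity_score(stack_profiles(clin_traj, order),
                               stack_profiles(model_traj, order))
  per <- vapply(order, function(nm) {
    similarity_score(clin_traj$values[, nm], model_traj$values[, nm])$S
  }, numeric(1))
  list(combined = combined, per_output = per)
}
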