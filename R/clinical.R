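# Run code with a local, seeded RNG without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Add signal-proportional Gaussian noise to a trajectory
#'
#' Each sampled value is independently replaced by a draw from a Gaussian
#' whose mean is the clean value and whose standard deviation is
#' `noise_fraction` times that value (so zero-valued points stay exactly
#' zero). Draws are clamped at zero by default, since concentrations are
#' nonnegative; the unclamped variant is available via `clamp = FALSE`.
#' Results are reproducible for a given seed.
#'
#' @param traj a `kin_trajectory` of clean (noise-free) values.
#' @param noise_fraction nonnegative sd-to-mean ratio (e.g. `0.2` for 20%).
#' @param seed RNG seed.
#' @param clamp clamp negative draws to zero (default `TRUE`).
#' @return a `kin_trajectory` of noisy values on the same grid.
#' @export
add_noise <- function(traj, noise_fraction, seed, clamp = TRUE) {
  stopifnot(inherits(traj, "kin_trajectory"))
  if (!is.numeric(noise_fraction) || noise_fraction < 0)
    stop("noise_fraction must be nonnegative")
  if (noise_fraction == 0) return(traj)
  vals <- traj$values
  noisy <- with_seed(seed, {
    matrix(rnorm(length(vals), mean = as.numeric(vals),
                 sd = noise_fraction * as.numeric(vals)),
           nrow = nrow(vals))
  })
  noisy[vals == 0] <- 0
  if (clamp) noisy[noisy < 0] <- 0
  new_trajectory(traj$times, noisy, traj$output_names)
}

new_clinical <- function(trajectory, noise_fraction, seed, truth,
                         source_model, density, clamp = TRUE) {
  structure(list(trajectory = trajectory, noise_fraction = noise_fraction,
                 seed = seed, truth = truth, source_model = source_model,
                 density = density, clamp = clamp),
            class = "kin_clinical")
}

#' Generate an artificial clinical dataset
#'
#' Applies the ground-truth perturbation to the model, simulates it on the
#' sampling grid, and adds signal-proportional Gaussian noise: the clean
#' value at each time point is the mean of the Gaussian and
#' `noise_fraction` of that value is its standard deviation. The ground
#' truth and generation metadata are recorded with the dataset.
#'
#' @param model a `kin_model`.
#' @param truth a `kin_perturbation` (the ground-truth fault), or `NULL`
#'   for normal (unperturbed) data.
#' @param noise_fraction sd as a fraction of the per-point mean
#'   (default `0.2`).
#' @param spec a `kin_sampling`; default: model's default horizon at 6/h.
#' @param seed RNG seed.
#' @param clamp clamp negative noisy draws at zero (default `TRUE`).
#' @return an object of class `kin_clinical`.
#' @export
generate_clinical <- function(model, truth, noise_fraction = 0.2,
                              spec = NULL, seed = 1, clamp = TRUE) {
  stopifnot(inherits(model, "kin_model"))
  if (is.null(spec)) spec <- sampling_spec(model$default_horizon_h, 6)
  m <- if (is.null(truth)) model else apply_perturbation(model, truth)
  clean <- simulate_model(m, spec)
  noisy <- add_noise(clean, noise_fraction, seed, clamp = clamp)
  new_clinical(noisy, noise_fraction, seed, truth, model$name, spec$density,
               clamp = clamp)
}

#' Select the representative perturbation for a fault kind
#'
#' Scans every candidate of the given kind over the fold grid and returns
#' the perturbation whose noise-free output profile is most dissimilar
#' (lowest similarity S) to the normal, unperturbed profile. This is the
#' perturbation whose clinical data is used in the experiment presets.
#' Ties are broken by candidate order, then by smaller fold.
#'
#' @param model a `kin_model`.
#' @param kind one of the four fault kinds.
#' @param fold_grid positive numeric vector of folds to test.
#' @param spec sampling grid for the comparison (default: model default).
#' @return the selected `kin_perturbation`, with the attained similarity
#'   attached as attribute `"S_vs_normal"`.
#' @export
select_representative <- function(model, kind, fold_grid, spec = NULL) {
  kind <- match.arg(kind, FAULT_KINDS)
  if (!length(fold_grid)) stop("fold_grid must be nonempty")
  if (is.null(spec)) spec <- sampling_spec(model$default_horizon_h, 6)
  normal <- stack_profiles(simulate_model(model, spec))
  cands <- candidate_universe(model, kind)
  best <- NULL; best_S <- Inf
  for (cand in cands) {
    for (fold in sort(fold_grid)) {
      p <- perturbation(kind, cand, fold)
      S <- tryCatch({
        traj <- simulate_model(apply_perturbation(model, p), spec)
        similarity_score(stack_profiles(traj), normal)$S
      }, error = function(e) NA_real_)
      if (!is.na(S) && S < best_S) { best_S <- S; best <- p }
    }
  }
  if (is.null(best))
    stop("no candidate produced a comparable profile")
  attr(best, "S_vs_normal") <- best_S
  best
}

#' Thin a clinical dataset to a lower sampling density
#'
#' Keeps the samples that fall on the coarser regular grid (t0 is retained
#' when present); no interpolation is performed, so the new density must
#' divide the original one.
#'
#' @param dataset a `kin_clinical`.
#' @param new_density target samples per hour.
#' @return the thinned `kin_clinical` with updated metadata.
#' @export
thin_dataset <- function(dataset, new_density) {
  stopifnot(inherits(dataset, "kin_clinical"))
  d0 <- dataset$density
  ratio <- d0 / new_density
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("new density %g does not divide original density %g; %s",
                 new_density, d0, "thinning never interpolates"))
  ratio <- round(ratio)
  if (ratio == 1) return(dataset)
  traj <- dataset$trajectory
  k <- traj$times * d0            # integer sample index on the fine grid
  keep <- abs(k / ratio - round(k / ratio)) < 1e-9
  dataset$trajectory <- new_trajectory(traj$times[keep],
                                       traj$values[keep, , drop = FALSE],
                                       traj$output_names)
  dataset$density <- new_density
  dataset
}

#' @export
print.kin_clinical <- function(x, ...) {
  cat(sprintf("<kin_clinical> %s: %d samples @ %g/h, noise sd = %g x mean\n",
              x$source_model, length(x$trajectory$times), x$density,
              x$noise_fraction))
  if (!is.null(x$truth))
    cat(sprintf("  truth: %s %s x%g\n", x$truth$kind, x$truth$target,
                x$truth$fold))
  invisible(x)
}

#' Write a clinical dataset (CSV plus JSON sidecar)
#'
#' The trajectory goes to `path` in the trajectory CSV dialect; generation
#' metadata (model, truth, noise fraction, density, seed) goes to
#' `<path>.json`.
#'
#' @param dataset a `kin_clinical`.
#' @param path CSV output path.
#' @export
write_clinical <- function(dataset, path) {
  write_trajectory(dataset$trajectory, path)
  meta <- list(
    model = dataset$source_model,
    truth = if (is.null(dataset$truth)) NULL else
      list(kind = dataset$truth$kind, target = dataset$truth$target,
           fold = dataset$truth$fold),
    noise_fraction = dataset$noise_fraction,
    density_per_hour = dataset$density,
    seed = dataset$seed,
    clamped = dataset$clamp
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a clinical dataset written by [write_clinical()]
#' @param path CSV path (the `<path>.json` sidecar must exist).
#' @return a `kin_clinical`.
#' @export
read_clinical <- function(path) {
  traj <- read_trajectory(path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing metadata sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  truth <- if (is.null(meta$truth)) NULL else
    perturbation(meta$truth$kind, meta$truth$target, meta$truth$fold)
  new_clinical(traj, meta$noise_fraction, meta$seed, truth, meta$model,
               meta$density_per_hour,
               clamp = isTRUE(meta$clamped))
}
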