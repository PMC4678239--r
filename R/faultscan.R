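#' Default fold-change grid
#'
#' Upregulation folds 5 to 100 in steps of 5, then 200 to 1000 in steps of
#' 100; downregulation folds are their reciprocals together with the decade
#' folds 1e-1 to 1e-4.
#'
#' @return a list with sorted numeric elements `up` (all > 1) and `down`
#'   (all < 1).
#' @export
default_fold_grid <- function() {
  up <- c(seq(5, 100, by = 5), seq(200, 1000, by = 100))
  down <- sort(unique(c(1 / up, 10^-(1:4))))
  list(up = up, down = down)
}

grid_side <- function(grid, kind) {
  side <- if (grepl("_up$", kind)) grid$up else grid$down
  if (!length(side))
    stop("fold grid has no folds for kind ", kind)
  if (grepl("_up$", kind) && any(side <= 1)) stop("up folds must be > 1")
  if (grepl("_down$", kind) && any(side >= 1)) stop("down folds must be < 1")
  sort(side)
}

#' Candidate universe for a fault kind
#'
#' All reaction rate constants for `rate_*` kinds; the preexisting molecules
#' (nonzero initial concentration) for `molecule_*` kinds.
#'
#' @param model a `kin_model`.
#' @param kind one of the four fault kinds.
#' @return character vector of candidate targets (possibly empty, with a
#'   warning, for a model without preexisting molecules).
#' @export
candidate_universe <- function(model, kind) {
  kind <- match.arg(kind, FAULT_KINDS)
  if (kind %in% c("rate_up", "rate_down"))
    return(model$rate_constant_names)
  pre <- preexisting_molecules(model)
  if (!length(pre))
    warning("model ", model$name, " has no preexisting molecules; ",
            "empty candidate universe for ", kind)
  pre
}

spec_from_clinical <- function(dataset) {
  t <- dataset$trajectory$times
  sampling_spec(max(t), dataset$density, include_t0 = t[1] == 0)
}

clinical_oscillation <- function(dataset, output,
                                 prominence_fraction = 0.05,
                                 smooth_window = 5) {
  profile_oscillation(dataset$trajectory, output,
                      prominence_fraction = prominence_fraction,
                      smooth_window = smooth_window)
}

ra_distance <- function(R_model, A_model, R_clin, A_clin, eps = 1e-12) {
  abs(R_model - R_clin) / max(R_clin, eps) +
    abs(A_model - A_clin) / max(A_clin, eps)
}

# Order rows by descending S; chains of near-ties (consecutive |dS| <
# tie_epsilon) are re-ordered by ascending RA_distance, then candidate id.
# Without R/A information (non-oscillatory models) plain descending S with
# lexicographic tie-break applies: there is nothing to re-order ties by.
rank_order <- function(S, RA_dist, candidate, tie_epsilon) {
  o <- order(-S, candidate)
  if (all(is.na(RA_dist))) return(o)
  if (length(o) > 1L) {
    Ss <- S[o]
    new_grp <- c(TRUE, abs(diff(Ss)) >= tie_epsilon)
    grp <- cumsum(new_grp)
    d <- RA_dist[o]
    d[is.na(d)] <- 0
    o <- o[order(grp, d, candidate[o])]
  }
  o
}

#' Scan candidate faults against a clinical dataset
#'
#' The core inference: for every candidate target of the given kind and
#' every fold in the grid, apply the perturbation, simulate the model on
#' the clinical sampling grid, and score the stacked output profiles
#' against the clinical data with the similarity S. Each candidate keeps
#' the fold maximising S. Candidates are ranked by descending S; for
#' oscillatory models, near-ties (|dS| below `tie_epsilon`) are resolved by
#' closeness of the oscillation factors R and A to those of the clinical
#' profile. Undefined similarities and failed integrations are scored 0
#' with a warning rather than aborting the scan.
#'
#' @param model the normal (unperturbed) `kin_model`.
#' @param clinical a `kin_clinical` sampled on a regular grid.
#' @param kind fault kind to scan (one of [FAULT_KINDS]).
#' @param grid fold grid as from [default_fold_grid()].
#' @param tie_epsilon S difference below which two candidates count as tied
#'   (default `0.01`).
#' @param prominence_fraction,smooth_window peak-detection settings for the
#'   clinical profile's R/A features; model profiles are clean and use no
#'   smoothing. The default window (`NULL`) smooths noisy data over 3
#'   samples and leaves noise-free data unsmoothed, so clean clinical data
#'   yields features identical to the generating model profile's; wider
#'   windows flatten spike-like oscillation peaks at clinical sampling
#'   densities and bias H downwards.
#' @return a `kin_ranktable`: a data frame with one row per candidate
#'   (`rank`, `candidate`, `kind`, `best_fold`, `S`, per-output S columns,
#'   `R`, `A`, `RA_distance`), sorted by the ranking rule, with clinical
#'   metadata attached as attributes.
#' @export
scan_faults <- function(model, clinical, kind, grid = default_fold_grid(),
                        tie_epsilon = 0.01, prominence_fraction = 0.05,
                        smooth_window = NULL) {
  stopifnot(inherits(model, "kin_model"), inherits(clinical, "kin_clinical"))
  if (is.null(smooth_window))
    smooth_window <- if (clinical$noise_fraction > 0) 3 else 1
  kind <- match.arg(kind, FAULT_KINDS)
  folds <- grid_side(grid, kind)
  spec <- spec_from_clinical(clinical)
  if (!setequal(clinical$trajectory$output_names, model$output_names))
    stop("clinical outputs do not match the model's declared outputs")
  order_out <- model$output_names
  clin_stacked <- stack_profiles(clinical$trajectory, order_out)
  cands <- candidate_universe(model, kind)
  osc <- model$oscillatory
  clin_feat <- if (osc)
    clinical_oscillation(clinical, order_out[1],
                         prominence_fraction, smooth_window)
  else NULL

  n <- length(cands)
  best_fold <- numeric(n); S <- numeric(n)
  perS <- matrix(NA_real_, n, length(order_out),
                 dimnames = list(NULL, paste0("S_", order_out)))
  R_model <- rep(NA_real_, n); A_model <- rep(NA_real_, n)
  RA_dist <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    bS <- -Inf; bfold <- folds[1]; btraj <- NULL
    for (fold in folds) {
      p <- perturbation(kind, cands[i], fold)
      res <- tryCatch({
        traj <- simulate_model(apply_perturbation(model, p), spec)
        list(S = similarity_score(clin_stacked,
                                  stack_profiles(traj, order_out))$S,
             traj = traj)
      }, error = function(e) {
        warning(sprintf("%s %s x%g scored 0: %s", kind, cands[i], fold,
                        conditionMessage(e)), call. = FALSE)
        list(S = 0, traj = NULL)
      })
      if (res$S > bS) { bS <- res$S; bfold <- fold; btraj <- res$traj }
    }
    best_fold[i] <- bfold; S[i] <- bS
    if (!is.null(btraj)) {
      perS[i, ] <- vapply(order_out, function(nm) {
        tryCatch(similarity_score(clinical$trajectory$values[, nm],
                                  btraj$values[, nm])$S,
                 error = function(e) 0)
      }, numeric(1))
      if (osc) {
        f <- profile_oscillation(btraj, order_out[1],
                                 prominence_fraction, smooth_window = 1)
        R_model[i] <- f$R; A_model[i] <- f$A
        RA_dist[i] <- ra_distance(f$R, f$A, clin_feat$R, clin_feat$A)
      }
    }
  }

  o <- rank_order(S, RA_dist, cands, tie_epsilon)
  tab <- data.frame(rank = seq_len(n), candidate = cands[o], kind = kind,
                    best_fold = best_fold[o], S = S[o],
                    perS[o, , drop = FALSE],
                    R = R_model[o], A = A_model[o], RA_distance = RA_dist[o],
                    stringsAsFactors = FALSE, check.names = FALSE)
  structure(tab, class = c("kin_ranktable", "data.frame"),
            tie_epsilon = tie_epsilon,
            clinical_meta = list(model = clinical$source_model,
                                 noise_fraction = clinical$noise_fraction,
                                 density = clinical$density,
                                 seed = clinical$seed,
                                 truth = clinical$truth),
            R_clin = if (osc) clin_feat$R else NA_real_,
            A_clin = if (osc) clin_feat$A else NA_real_)
}

#' Confirm near-tied candidates with the R/A oscillation factors
#'
#' Within the top `top_k` rows of a rank table, re-orders chains of
#' S-near-ties (|dS| < the table's `tie_epsilon`) by ascending R/A distance
#' to the clinical profile, then candidate id. A row whose S exceeds
#' another's by at least `tie_epsilon` is never demoted below it. Rows
#' outside the top `top_k` keep their order.
#'
#' @param table a `kin_ranktable` from a scan of an oscillatory model.
#' @param top_k number of leading rows to consider (default 5).
#' @return the re-ordered `kin_ranktable`.
#' @export
confirm_with_ra <- function(table, top_k = 5) {
  stopifnot(inherits(table, "kin_ranktable"))
  k <- min(top_k, nrow(table))
  if (k < 2L) return(table)
  eps <- attr(table, "tie_epsilon")
  head_idx <- seq_len(k)
  o <- rank_order(table$S[head_idx], table$RA_distance[head_idx],
                  table$candidate[head_idx], eps)
  idx <- c(head_idx[o], setdiff(seq_len(nrow(table)), head_idx))
  out <- table[idx, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = class(table), tie_epsilon = eps,
            clinical_meta = attr(table, "clinical_meta"),
            R_clin = attr(table, "R_clin"), A_clin = attr(table, "A_clin"))
}

truth_row <- function(table, truth) {
  which(table$candidate == truth$target & table$kind == truth$kind)
}

#' Noise-robustness sweep
#'
#' For each noise fraction and seed, generates a clinical dataset from the
#' ground-truth perturbation and scans it; reports the truth's rank and S
#' per run plus per-fraction aggregates (median S of the truth, fraction of
#' seeds in which it ranks first).
#'
#' @param model a `kin_model`.
#' @param truth the ground-truth `kin_perturbation`.
#' @param fractions noise fractions to test (e.g. `c(0.2, 0.4, 0.6, 0.8)`).
#' @param seeds integer vector of RNG seeds (one clinical replicate each).
#' @param grid fold grid; `spec` sampling grid (default: model default).
#' @param spec a `kin_sampling` or `NULL`.
#' @param ... passed on to [scan_faults()].
#' @return a list of class `kin_sweep`: `runs` (fraction, seed, rank, S)
#'   and `summary` (fraction, median_S, rank1_fraction).
#' @export
noise_sweep <- function(model, truth, fractions = c(0.2, 0.4, 0.6, 0.8),
                        seeds = 1:10, grid = default_fold_grid(),
                        spec = NULL, ...) {
  if (!length(fractions)) stop("fractions must be nonempty")
  runs <- do.call(rbind, lapply(fractions, function(fr) {
    do.call(rbind, lapply(seeds, function(s) {
      clin <- generate_clinical(model, truth, noise_fraction = fr,
                                spec = spec, seed = s)
      tab <- scan_faults(model, clin, truth$kind, grid = grid, ...)
      i <- truth_row(tab, truth)
      data.frame(fraction = fr, seed = s, rank = tab$rank[i], S = tab$S[i])
    }))
  }))
  summary <- do.call(rbind, lapply(split(runs, runs$fraction), function(d) {
    data.frame(fraction = d$fraction[1], median_S = median(d$S),
               rank1_fraction = mean(d$rank == 1))
  }))
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary, truth = truth),
            class = "kin_sweep")
}

#' Data-density sweep
#'
#' Generates one clinical dataset at the base density, then thins it to
#' each requested density and scans; reports the truth's rank, S and (for
#' oscillatory models) R and A at each density.
#'
#' @param model a `kin_model`.
#' @param truth the ground-truth `kin_perturbation`.
#' @param densities samples per hour; each must divide the base density.
#' @param seed RNG seed for the single clinical realisation.
#' @param noise_fraction noise level of the clinical data.
#' @param grid fold grid; `spec` base sampling grid (default: model default
#'   horizon at 6/h).
#' @param spec a `kin_sampling` or `NULL`.
#' @param ... passed on to [scan_faults()].
#' @return data frame (density, rank, S, R, A) of class `kin_sweep_density`.
#' @export
density_sweep <- function(model, truth, densities = c(6, 1), seed = 1,
                          noise_fraction = 0.2, grid = default_fold_grid(),
                          spec = NULL, ...) {
  base <- generate_clinical(model, truth, noise_fraction = noise_fraction,
                            spec = spec, seed = seed)
  out <- do.call(rbind, lapply(densities, function(d) {
    clin <- thin_dataset(base, d)
    tab <- scan_faults(model, clin, truth$kind, grid = grid, ...)
    i <- truth_row(tab, truth)
    data.frame(density = d, rank = tab$rank[i], S = tab$S[i],
               R = tab$R[i], A = tab$A[i])
  }))
  structure(out, class = c("kin_sweep_density", "data.frame"), truth = truth)
}

#' Scan all four fault kinds and merge by S
#'
#' Convenience mode: runs [scan_faults()] for each kind and merges the rows
#' into a single table re-ranked by the same rule.
#'
#' @inheritParams scan_faults
#' @return a merged `kin_ranktable`.
#' @export
scan_all_kinds <- function(model, clinical, grid = default_fold_grid(),
                           tie_epsilon = 0.01, ...) {
  tabs <- lapply(FAULT_KINDS, function(k)
    scan_faults(model, clinical, k, grid = grid,
                tie_epsilon = tie_epsilon, ...))
  all <- do.call(rbind, lapply(tabs, as.data.frame))
  o <- rank_order(all$S, all$RA_distance,
                  paste(all$kind, all$candidate), tie_epsilon)
  all <- all[o, , drop = FALSE]
  all$rank <- seq_len(nrow(all))
  rownames(all) <- NULL
  structure(all, class = c("kin_ranktable", "data.frame"),
            tie_epsilon = tie_epsilon,
            clinical_meta = attr(tabs[[1]], "clinical_meta"),
            R_clin = attr(tabs[[1]], "R_clin"),
            A_clin = attr(tabs[[1]], "A_clin"))
}

#' Write a rank table as TSV
#' @param table a `kin_ranktable`.
#' @param path output TSV path.
#' @export
write_rank_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.kin_ranktable <- function(x, n = 10, ...) {
  meta <- attr(x, "clinical_meta")
  cat(sprintf("<kin_ranktable> %s, kind %s, %d candidates (noise %g, seed %s)\n",
              meta$model, x$kind[1], nrow(x), meta$noise_fraction,
              meta$seed))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}
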