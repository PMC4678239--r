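test_that("zero noise returns the trajectory unchanged", {
  tr <- simulate_model(demo_steady, sampling_spec(2, 6))
  expect_identical(add_noise(tr, 0, seed = 1)$values, tr$values)
  expect_error(add_noise(tr, -0.1, seed = 1), "nonnegative")
})

test_that("noise is seeded and reproducible", {
  tr <- simulate_model(demo_steady, sampling_spec(2, 6))
  a <- add_noise(tr, 0.2, seed = 42)
  b <- add_noise(tr, 0.2, seed = 42)
  expect_identical(a$values, b$values)
  c <- add_noise(tr, 0.2, seed = 43)
  expect_false(identical(a$values, c$values))
})

test_that("noise sampling follows the stated Gaussian law", {
  n <- 10000
  tr <- make_traj(seq_len(n), rep(10, n))
  noisy <- add_noise(tr, 0.2, seed = 7, clamp = FALSE)
  x <- noisy$values[, 1]
  expect_lt(abs(mean(x) - 10), 0.1)
  expect_lt(abs(sd(x) - 2), 0.1)
  # zero-valued points stay exactly zero
  tz <- make_traj(1:50, rep(0, 50))
  expect_identical(add_noise(tz, 0.2, seed = 1)$values, tz$values)
})

test_that("noisy deviations have the expected Gaussian coverage", {
  truth <- perturbation("rate_up", "r_dephos", 1000)
  clean <- simulate_model(apply_perturbation(demo_steady, truth),
                          sampling_spec(10, 6))
  pos <- clean$values > 1e-6
  cover <- mean(vapply(1:10, function(s) {
    noisy <- add_noise(clean, 0.2, seed = s)
    mean((abs(noisy$values - clean$values) <= 0.2 * clean$values)[pos])
  }, numeric(1)))
  expect_gt(cover, 0.65)
  expect_lt(cover, 0.72)
})

test_that("per-point sd scales linearly with the noise fraction", {
  n <- 4000
  tr <- make_traj(seq_len(n), rep(50, n))
  sds <- vapply(c(0.2, 0.4, 0.6, 0.8), function(fr)
    sd(add_noise(tr, fr, seed = 5, clamp = FALSE)$values[, 1]),
    numeric(1))
  fit <- lm(sds ~ 0 + c(0.2, 0.4, 0.6, 0.8))
  expect_equal(unname(coef(fit)), 50, tolerance = 0.05)
  rel <- sds / (50 * c(0.2, 0.4, 0.6, 0.8))
  expect_true(all(abs(rel - 1) < 0.06))
})

test_that("averaging many noisy replicates recovers the clean profile", {
  clean <- simulate_model(demo_steady, sampling_spec(5, 2))
  reps <- vapply(1:200, function(s)
    add_noise(clean, 0.2, seed = s)$values[, "DimN"],
    numeric(length(clean$times)))
  avg <- rowMeans(reps)
  se <- apply(reps, 1, sd) / sqrt(200)
  pos <- clean$values[, "DimN"] > 1e-3
  expect_true(all((abs(avg - clean$values[, "DimN"]) <= 3 * se + 1e-12)[pos]))
})

test_that("generated datasets record truth and metadata", {
  truth <- perturbation("molecule_up", "NIc", 10)
  ds <- generate_clinical(demo_osc, truth, 0.2,
                          sampling_spec(15, 6), seed = 7)
  expect_length(ds$trajectory$times, 91)
  expect_identical(ds$truth$target, "NIc")
  expect_identical(ds$seed, 7)
  expect_identical(ds$source_model, "demo_oscillator")
  expect_true(all(ds$trajectory$values >= 0))
  # zero-noise dataset equals the perturbed clean simulation exactly
  d0 <- generate_clinical(demo_osc, truth, 0, sampling_spec(15, 6), seed = 1)
  clean <- simulate_model(apply_perturbation(demo_osc, truth),
                          sampling_spec(15, 6))
  expect_identical(d0$trajectory$values, clean$values)
})

test_that("representative selection minimises S against the normal profile", {
  spec <- sampling_spec(10, 6)
  grid <- c(10, 100)
  rep_p <- select_representative(demo_steady, "rate_up", grid, spec)
  normal <- stack_profiles(simulate_model(demo_steady, spec))
  S_all <- sapply(candidate_universe(demo_steady, "rate_up"), function(cand)
    sapply(grid, function(f) {
      tr <- simulate_model(
        apply_perturbation(demo_steady, perturbation("rate_up", cand, f)),
        spec)
      similarity_score(stack_profiles(tr), normal)$S
    }))
  expect_equal(attr(rep_p, "S_vs_normal"), min(S_all), tolerance = 1e-12)
  best <- which(S_all == min(S_all), arr.ind = TRUE)
  expect_identical(rep_p$target,
                   candidate_universe(demo_steady, "rate_up")[best[1, 2]])
})

test_that("identity folds make representative selection degenerate but deterministic", {
  p <- select_representative(demo_osc, "molecule_up", 1)
  expect_identical(p$fold, 1)
  # tie broken by candidate order: first preexisting molecule
  expect_identical(p$target, preexisting_molecules(demo_osc)[1])
  expect_equal(attr(p, "S_vs_normal"), 1, tolerance = 1e-12)
})

test_that("thinning keeps the coarse grid and refuses non-divisors", {
  truth <- perturbation("molecule_up", "NIc", 10)
  ds <- generate_clinical(demo_osc, truth, 0.2, sampling_spec(15, 6), seed = 1)
  expect_identical(thin_dataset(ds, 6), ds)
  th <- thin_dataset(ds, 1)
  expect_length(th$trajectory$times, 16)
  expect_identical(th$trajectory$times, as.numeric(0:15))
  expect_identical(th$density, 1)
  expect_error(thin_dataset(ds, 4), "does not divide")
  # thinning composes
  expect_identical(thin_dataset(thin_dataset(ds, 3), 1)$trajectory$values,
                   thin_dataset(ds, 1)$trajectory$values)
})

test_that("clinical CSV + sidecar round-trips", {
  truth <- perturbation("rate_down", "r_phos", 0.001)
  ds <- generate_clinical(demo_steady, truth, 0.2, sampling_spec(5, 6),
                          seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_clinical(ds, f)
  rt <- read_clinical(f)
  expect_equal(rt$trajectory$values, ds$trajectory$values, tolerance = 1e-15)
  expect_identical(rt$truth$kind, "rate_down")
  expect_identical(rt$truth$fold, 0.001)
  expect_equal(rt$noise_fraction, 0.2)
  expect_equal(rt$density, 6)
})
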