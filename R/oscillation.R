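#' Centered moving-average smoother
#'
#' Simple centered moving average with shrinking windows at the series ends,
#' used to suppress noise ripples before peak detection on noisy clinical
#' series.
#'
#' @param v numeric vector.
#' @param window odd window length in samples; `1` disables smoothing.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_ma <- function(v, window = 5) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(v)
  h <- (window - 1) / 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    mean(v[lo:hi])
  }, numeric(1))
}

new_peaklist <- function(time, value, type, window) {
  structure(data.frame(time = time, value = value, type = type,
                       stringsAsFactors = FALSE),
            class = c("kin_peaks", "data.frame"), window = window)
}

#' Detect oscillation peaks (maxima and minima)
#'
#' Finds interior strict local extrema of a sampled single-output series.
#' Plateaus of equal consecutive values yield one extremum at the plateau
#' midpoint; endpoints are never peaks. Low-amplitude ripples are removed by
#' iteratively deleting the adjacent max/min pair with the smallest value gap
#' until every adjacent pair differs by at least
#' `prominence_fraction * (global max - global min)` of the series. The
#' surviving extrema alternate in type by construction.
#'
#' @param traj a `kin_trajectory`.
#' @param output name of the output column to analyse (default: first).
#' @param prominence_fraction minimum retained peak-to-trough gap as a
#'   fraction of the series' global range.
#' @param smooth_window odd moving-average window (samples) applied before
#'   detection; `1` (default) for clean model output, wider for noisy data.
#' @return a `kin_peaks` data frame with columns `time` (hours), `value`
#'   (nM) and `type` (`"max"`/`"min"`).
#' @export
detect_peaks <- function(traj, output = traj$output_names[1],
                         prominence_fraction = 0.05, smooth_window = 1) {
  stopifnot(inherits(traj, "kin_trajectory"))
  v <- traj$values[, output]
  t <- traj$times
  if (length(v) < 3L) stop("peak detection needs at least 3 samples")
  v <- smooth_ma(v, smooth_window)

  # compress plateaus to their midpoint
  keep <- c(TRUE, diff(v) != 0)
  grp <- cumsum(keep)
  tc <- tapply(t, grp, function(z) (min(z) + max(z)) / 2)
  vc <- tapply(v, grp, `[`, 1L)
  tc <- as.numeric(tc); vc <- as.numeric(vc)

  m <- length(vc)
  if (m < 3L)
    return(new_peaklist(numeric(0), numeric(0), character(0),
                        range(traj$times)))
  i <- 2:(m - 1)
  is_max <- vc[i] > vc[i - 1] & vc[i] > vc[i + 1]
  is_min <- vc[i] < vc[i - 1] & vc[i] < vc[i + 1]
  idx <- i[is_max | is_min]
  type <- ifelse(is_max[match(idx, i)], "max", "min")
  time <- tc[idx]; value <- vc[idx]

  thr <- prominence_fraction * (max(v) - min(v))
  while (length(value) >= 2L) {
    gaps <- abs(diff(value))
    j <- which.min(gaps)
    if (gaps[j] >= thr) break
    drop <- c(j, j + 1L)
    time <- time[-drop]; value <- value[-drop]; type <- type[-drop]
  }
  new_peaklist(time, value, type, range(traj$times))
}

#' Trim boundary-dependent peaks
#'
#' Removes the window artifacts from a peak list: a leading minimum (a
#' first minimum occurring before any maximum) and a trailing maximum (a
#' last maximum occurring after the last minimum). These extrema depend on
#' the chosen analysis window and do not belong to complete peak-pairs.
#' Since detected extrema alternate, this amounts to dropping the first
#' entry when it is a minimum and the last entry when it is a maximum; all
#' other entries are kept unchanged.
#'
#' @param peaks a `kin_peaks`.
#' @return the trimmed `kin_peaks`.
#' @export
trim_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "kin_peaks"))
  n <- nrow(peaks)
  drop <- integer(0)
  if (n >= 1L && peaks$type[1] == "min") drop <- c(drop, 1L)
  if (n >= 1L && peaks$type[n] == "max") drop <- c(drop, n)
  out <- if (length(drop)) peaks[-drop, , drop = FALSE] else peaks
  structure(out, class = c("kin_peaks", "data.frame"),
            window = attr(peaks, "window"))
}

zero_oscfeatures <- function() {
  structure(list(H = 0, P = 0, N = 0L, R = 0, A = 0, A_raw = 0,
                 defined = FALSE), class = "kin_oscfeatures")
}

#' Oscillation features H, P, N, R, A from a trimmed peak list
#'
#' Computes the mean amplitude `H` (mean of maxima minus mean of minima,
#' nM), the mean period `P` (average of the mean gap between adjacent maxima
#' and the mean gap between adjacent minima, reported in seconds), the
#' number `N` of complete (max, min) peak-pairs among the surviving entries,
#' and the derived factors `R = 2H/P` (nM/s, the overall steepness of the
#' oscillation) and `A = H*P*N` (reported in units of nM.s.1e6, the
#' aggregate peak-pair area; the raw product is kept in `A_raw`). When fewer
#' than two maxima or two minima survive, the period is not estimable and a
#' zeroed record with `defined = FALSE` is returned.
#'
#' @param peaks a trimmed `kin_peaks` (see [trim_peaks()]).
#' @return an object of class `kin_oscfeatures`.
#' @export
oscillation_features <- function(peaks) {
  stopifnot(inherits(peaks, "kin_peaks"))
  mv <- peaks$value[peaks$type == "max"]
  mt <- peaks$time[peaks$type == "max"]
  nv <- peaks$value[peaks$type == "min"]
  nt <- peaks$time[peaks$type == "min"]
  if (length(mv) < 2L || length(nv) < 2L) return(zero_oscfeatures())
  H <- mean(mv) - mean(nv)
  P_h <- (mean(diff(mt)) + mean(diff(nt))) / 2
  P <- P_h * SECONDS_PER_HOUR
  n <- nrow(peaks)
  N <- sum(peaks$type[-n] == "max" & peaks$type[-1] == "min")
  A_raw <- H * P * N
  structure(list(H = H, P = P, N = as.integer(N), R = 2 * H / P,
                 A = A_raw / 1e6, A_raw = A_raw, defined = TRUE),
            class = "kin_oscfeatures")
}

#' Detect, trim and featurise in one call
#'
#' Convenience wrapper: [detect_peaks()], [trim_peaks()],
#' [oscillation_features()].
#'
#' @inheritParams detect_peaks
#' @return a `kin_oscfeatures`.
#' @export
profile_oscillation <- function(traj, output = traj$output_names[1],
                                prominence_fraction = 0.05,
                                smooth_window = 1) {
  oscillation_features(trim_peaks(detect_peaks(
    traj, output, prominence_fraction, smooth_window)))
}

#' @export
print.kin_oscfeatures <- function(x, ...) {
  if (!x$defined) {
    cat("<oscillation> undefined (fewer than 2 maxima and 2 minima)\n")
  } else {
    cat(sprintf("<oscillation> H=%.4g nM  P=%.4g s  N=%d  R=%.4g nM/s  A=%.4g nM.s.1e6\n",
                x$H, x$P, x$N, x$R, x$A))
  }
  invisible(x)
}
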