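#' Histogram reaction times into fixed-width bins
#'
#' Bins RTs into contiguous half-open bins `[0, w), [w, 2w), ...` starting at
#' zero. Optionally drops the leading bins — used on the longest duration to
#' exclude early opt-out responses (the first two 200 ms bins, i.e. 400 ms)
#' from the Gaussian fit.
#'
#' @param rts Reaction times (ms on the wait clock).
#' @param bin_width Bin width in ms (default 200).
#' @param exclude_leading_bins Number of leading bins to drop (default 0).
#' @return List with `counts`, `centers` (ms), `breaks`, `excluded_bins`.
#' @export
histogram_rts <- function(rts, bin_width = 200, exclude_leading_bins = 0) {
  if (length(rts) == 0) stop("empty RT list")
  if (bin_width <= 0) stop("`bin_width` must be positive")
  if (any(rts < 0)) stop("negative RTs")
  n_bins <- floor(max(rts) / bin_width) + 1L
  idx <- floor(rts / bin_width) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  centers <- (seq_len(n_bins) - 0.5) * bin_width
  keep <- seq_len(n_bins) > exclude_leading_bins
  list(counts = counts[keep], centers = centers[keep],
       breaks = seq(exclude_leading_bins * bin_width, n_bins * bin_width,
                    by = bin_width),
       excluded_bins = as.integer(exclude_leading_bins))
}

#' Fit a fixed-center Gaussian to an RT histogram
#'
#' The Gaussian's center is fixed at the center of the modal bin (ties broken
#' to the earliest bin, with a warning), which stabilises the fit against
#' early low-frequency responses; amplitude and sigma are then fit by least
#' squares on the raw counts. `r_squared = 1 - SS_res / SS_tot`.
#'
#' @param hist Output of [histogram_rts()].
#' @param duration Optional target duration (ms), carried through for
#'   bookkeeping.
#' @return An object of class `rt_fit`: list with `gauss_mean` (the fixed
#'   center, ms), `gauss_sigma` (ms), `amplitude`, `r_squared`, `duration`,
#'   `excluded_bins`.
#' @export
fit_rt_gaussian <- function(hist, duration = NA_real_) {
  counts <- hist$counts; centers <- hist$centers
  if (sum(counts > 0) < 3) stop("need at least 3 nonzero bins")
  mx <- max(counts)
  modal <- which(counts == mx)
  if (length(modal) > 1) {
    warning("modal-bin tie broken to the earliest bin")
    modal <- modal[1]
  }
  cen <- centers[modal]

  sse <- function(par) {  # par = (amplitude, log sigma)
    a <- par[1]; s <- exp(par[2])
    sum((counts - a * exp(-(centers - cen)^2 / (2 * s^2)))^2)
  }
  # multi-start: log-quadratic regression on the positive counts, the
  # weighted SD around the fixed center, and two scale-based guesses; sparse
  # jagged histograms otherwise trap the optimiser in a zero-width spike
  bw <- centers[2] - centers[1]
  pos <- counts > 0
  z <- log(counts[pos]); q <- (centers[pos] - cen)^2
  sl <- if (length(unique(q)) > 1) stats::coef(stats::lm(z ~ q))[2] else NA
  starts <- c(
    if (is.finite(sl) && sl < 0) sqrt(-1 / (2 * sl)),
    sqrt(sum(counts * (centers - cen)^2) / sum(counts)),
    bw, diff(range(centers)) / 4)
  fit <- NULL
  for (s0 in unique(pmax(starts, bw / 4))) {
    f <- stats::optim(c(mx, log(s0)), sse, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    f <- stats::optim(f$par, sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-15))
    if (is.null(fit) || f$value < fit$value) fit <- f
  }
  ss_tot <- sum((counts - mean(counts))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - fit$value / ss_tot
  structure(list(
    duration = duration,
    gauss_mean = cen,
    gauss_sigma = exp(fit$par[2]),
    amplitude = fit$par[1],
    r_squared = r2,
    excluded_bins = hist$excluded_bins,
    counts = counts, centers = centers
  ), class = "rt_fit")
}

#' Behavioral RT fits for a whole session
#'
#' Convenience wrapper: histograms and fits the RTs of each target duration.
#' The leading-bin exclusion (2 bins = 400 ms by default) applies only to the
#' longest duration, where early opt-outs contaminate the distribution.
#'
#' @param rts data.frame with `duration` and `rt_ms` columns (e.g. from
#'   [generate_behavioral_rts()] or a session's trial table).
#' @param bin_width Histogram bin width (ms).
#' @param exclude_leading_bins_longest Leading bins excluded on the longest
#'   duration (default 2).
#' @return List of `rt_fit`, one per duration (named by duration).
#' @export
fit_session_rts <- function(rts, bin_width = 200,
                            exclude_leading_bins_longest = 2) {
  durs <- sort(unique(rts$duration))
  fits <- lapply(durs, function(d) {
    ex <- if (d == max(durs)) exclude_leading_bins_longest else 0
    h <- histogram_rts(rts$rt_ms[rts$duration == d], bin_width, ex)
    fit_rt_gaussian(h, duration = d)
  })
  stats::setNames(fits, as.character(durs))
}

#' Summarise the scalar property across durations
#'
#' Collects the fitted Gaussian centers and sigmas, sorted by duration, and
#' flags whether sigma increases strictly with the center — the behavioral
#' signature of scalar expectancy (constant Weber fraction).
#'
#' @param fits List of `rt_fit` objects (at least 2).
#' @return List with `table` (data.frame: duration, center, sigma,
#'   sigma_over_center) and `monotonic` (logical).
#' @export
scalar_summary <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits")
  tab <- data.frame(
    duration = vapply(fits, function(f) as.numeric(f$duration), numeric(1)),
    center = vapply(fits, function(f) f$gauss_mean, numeric(1)),
    sigma = vapply(fits, function(f) f$gauss_sigma, numeric(1))
  )
  tab <- tab[order(tab$duration), , drop = FALSE]
  rownames(tab) <- NULL
  tab$sigma_over_center <- tab$sigma / tab$center
  ord <- order(tab$center)
  list(table = tab, monotonic = all(diff(tab$sigma[ord]) > 0))
}
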