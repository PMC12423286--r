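#' Two-way ANOVA on per-trial firing rates
#'
#' Full factorial decomposition with target duration and stimulus protocol as
#' factors. For unbalanced designs (trial counts differ across cells after
#' delayed retries) Type II sums of squares are used: each main effect is
#' tested adjusted for the other main effect, and the interaction adjusted for
#' both, via nested linear-model residual sums of squares. In the balanced
#' case this reduces to the classical decomposition
#' `SS_duration + SS_protocol + SS_interaction + SS_error = SS_total`.
#'
#' A neuron is classified `time` iff the duration main effect is significant
#' at `alpha` while neither the protocol effect nor the interaction is;
#' `protocol` and `interaction` symmetrically; anything else significant is
#' `mixed`; nothing significant is `none`.
#'
#' @param rates Per-trial mean firing rates (numeric).
#' @param duration Per-trial target duration labels.
#' @param protocol Per-trial protocol labels.
#' @param alpha Significance threshold (default 0.01).
#' @return An object of class `anova_result`: list with `ss` (named: duration,
#'   protocol, interaction, error, total), `df`, `F`, `p`, `ms_error`,
#'   `classification`, `duration_means`, `alpha`, `n`.
#' @export
two_way_anova <- function(rates, duration, protocol, alpha = 0.01) {
  y <- as.numeric(rates)
  fd <- factor(duration)
  fp <- factor(protocol)
  tab <- table(fd, fp)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: duration=", levels(fd)[bad[1]],
         ", protocol=", levels(fp)[bad[2]])
  }
  if (any(tab < 2)) stop("need >= 2 trials in every duration x protocol cell")

  rss <- function(form) sum(stats::lm.fit(stats::model.matrix(form),
                                          y)$residuals^2)
  r_full <- rss(~ fd * fp)
  r_add <- rss(~ fd + fp)
  r_d <- rss(~ fd)       # duration only
  r_p <- rss(~ fp)       # protocol only

  ss <- c(duration = max(r_p - r_add, 0),
          protocol = max(r_d - r_add, 0),
          interaction = max(r_add - r_full, 0),
          error = r_full,
          total = sum((y - mean(y))^2))
  df <- c(duration = nlevels(fd) - 1L,
          protocol = nlevels(fp) - 1L,
          interaction = (nlevels(fd) - 1L) * (nlevels(fp) - 1L),
          error = length(y) - nlevels(fd) * nlevels(fp))
  ms_error <- ss[["error"]] / df[["error"]]

  terms <- c("duration", "protocol", "interaction")
  tol <- 1e-12 * max(ss[["total"]], 1)
  Fv <- pv <- stats::setNames(numeric(3), terms)
  for (tm in terms) {
    if (ss[[tm]] <= tol) {           # no variance attributable to the term
      Fv[tm] <- 0; pv[tm] <- 1
    } else if (ms_error <= tol) {    # perfect separation, no residual noise
      Fv[tm] <- Inf; pv[tm] <- 0
    } else {
      Fv[tm] <- (ss[[tm]] / df[[tm]]) / ms_error
      pv[tm] <- stats::pf(Fv[tm], df[[tm]], df[["error"]], lower.tail = FALSE)
    }
  }
  sig <- pv < alpha
  classification <- if (!any(sig)) "none"
    else if (sig[["duration"]] && !sig[["protocol"]] && !sig[["interaction"]]) "time"
    else if (sig[["protocol"]] && !sig[["duration"]] && !sig[["interaction"]]) "protocol"
    else if (sig[["interaction"]] && !sig[["duration"]] && !sig[["protocol"]]) "interaction"
    else "mixed"

  structure(list(
    ss = ss, df = df, F = Fv, p = pv, ms_error = ms_error,
    classification = classification,
    duration_means = tapply(y, fd, mean),
    alpha = alpha, n = length(y)
  ), class = "anova_result")
}

#' Balanced two-way sums of squares, vectorised over columns
#'
#' Closed-form decomposition for balanced designs (equal trial counts in
#' every duration x protocol cell), computed simultaneously for every column
#' of `Y`. This is the fast path behind the sliding-window percent-explained-
#' variance analysis; it agrees with [two_way_anova()] on balanced data.
#'
#' @param Y Numeric matrix, trials x windows (or any set of response columns).
#' @param duration,protocol Per-row factor labels; the design must be
#'   balanced.
#' @return List of numeric vectors (one entry per column): `ss_duration`,
#'   `ss_protocol`, `ss_interaction`, `ss_error`, `ss_total`, `ms_error`, and
#'   scalar `df` (named vector as in [two_way_anova()]).
#' @export
balanced_anova_ss <- function(Y, duration, protocol) {
  Y <- as.matrix(Y)
  fd <- factor(duration); fp <- factor(protocol)
  cell <- interaction(fd, fp, drop = FALSE)
  n_cell <- table(cell)
  if (length(unique(as.integer(n_cell))) != 1 || any(n_cell == 0)) {
    stop("design is not balanced")
  }
  N <- nrow(Y)
  gm <- colMeans(Y)
  ctr <- sweep(Y, 2, gm)
  ss_total <- colSums(ctr^2)

  mean_by <- function(f) {
    s <- rowsum(ctr, f, reorder = TRUE)
    cnt <- as.integer(table(f))
    list(m = s / cnt, cnt = cnt)
  }
  a <- mean_by(fd); b <- mean_by(fp); ab <- mean_by(cell)
  ss_d <- colSums(a$m^2 * a$cnt)
  ss_p <- colSums(b$m^2 * b$cnt)
  ss_cells <- colSums(ab$m^2 * ab$cnt)
  ss_i <- pmax(ss_cells - ss_d - ss_p, 0)
  ss_e <- pmax(ss_total - ss_cells, 0)
  df <- c(duration = nlevels(fd) - 1L,
          protocol = nlevels(fp) - 1L,
          interaction = (nlevels(fd) - 1L) * (nlevels(fp) - 1L),
          error = N - nlevels(fd) * nlevels(fp))
  list(ss_duration = ss_d, ss_protocol = ss_p, ss_interaction = ss_i,
       ss_error = ss_e, ss_total = ss_total,
       ms_error = ss_e / df[["error"]], df = df)
}

#' Omega-squared percent explained variance
#'
#' Bias-corrected ANOVA effect size, expressed as a percentage:
#' `omega^2 = (SS_term - df_term * MS_error) / (SS_total + MS_error) * 100`.
#' Values can dip below zero under the null (that is the bias correction at
#' work); they are not floored. When `MS_error = 0` the expression reduces to
#' `SS_term / SS_total * 100`.
#'
#' @param ss_term Sum of squares of the factor of interest.
#' @param df_term Its degrees of freedom.
#' @param ss_total Total sum of squares.
#' @param ms_error Mean squared error.
#' @return Numeric (vectorised), in percent.
#' @export
omega_squared <- function(ss_term, df_term, ss_total, ms_error) {
  denom <- ss_total + ms_error
  out <- ifelse(denom > 0, (ss_term - df_term * ms_error) / denom * 100, 0)
  as.numeric(out)
}

#' @rdname omega_squared
#' @param x An `anova_result`.
#' @param term One of `"duration"`, `"protocol"`, `"interaction"`.
#' @export
omega_squared_term <- function(x, term = c("duration", "protocol",
                                           "interaction")) {
  term <- match.arg(term)
  omega_squared(x$ss[[term]], x$df[[term]], x$ss[["total"]], x$ms_error)
}
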