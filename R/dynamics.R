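#' State-membership time series for one subject
#'
#' Restricts the per-sample state label sets to one subject and an optional
#' time window, orders them by time, and computes the occupancy weights
#' `f'_x(t) = f_x(t) / p(t)` where `p(t)` is the number of distinct labels
#' (including `"unassigned"`) carried by the sample at time t. Weights are
#' therefore 1, 1/2, 1/3, ...
#'
#' @param labels named list mapping sample IDs to character label vectors
#'   (output of [sample_states()]), or a character vector of single labels.
#' @param meta data frame with `sample_id`, `subject`, `time`.
#' @param subject subject/site ID to extract.
#' @param window optional numeric length-2 `(t_min, t_max)`, inclusive.
#' @return An object of class `membership_series`: list with `subject`,
#'   `time` (sorted), `labels` (list of label sets per time), `p` (integer),
#'   and `weights` (list of named numeric `f'` per label).
#' @export
membership_series <- function(labels, meta, subject, window = NULL) {
  if (is.character(labels)) labels <- as.list(labels)
  keep <- meta$subject == subject
  if (!is.null(window))
    keep <- keep & meta$time >= window[1] & meta$time <= window[2]
  meta <- meta[keep, , drop = FALSE]
  meta <- meta[meta$sample_id %in% names(labels), , drop = FALSE]
  if (nrow(meta) < 2)
    stop("subject '", subject, "' has fewer than 2 samples in the window")
  ord <- order(meta$time)
  meta <- meta[ord, , drop = FALSE]
  labs <- lapply(meta$sample_id, function(id) sort(unique(labels[[id]])))
  p <- vapply(labs, length, integer(1))
  weights <- Map(function(l, pp) stats::setNames(rep(1 / pp, length(l)), l),
                 labs, p)
  structure(list(subject = subject, time = meta$time, labels = labs,
                 p = p, weights = weights),
            class = "membership_series")
}

#' @export
print.membership_series <- function(x, ...) {
  cat("membership_series: subject '", x$subject, "', ", length(x$time),
      " time points, states {",
      paste(sort(unique(unlist(x$labels))), collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}

# weight of label x at series position i (0 if absent)
.fprime <- function(s, i, x) {
  w <- s$weights[[i]][x]
  if (is.na(w)) 0 else unname(w)
}

#' Temporal correlation function of state occupancy
#'
#' For a state x, every ordered pair of sample times (t, t + tau) with
#' `x` among the labels at t contributes the raw value `f'_x(t + tau)`;
#' tau is the exact empirical time difference (tau = 0 pairs each sample
#' with itself). The correlation `corr_x(tau)` is the mean of the raw
#' values at each distinct tau — the probability that a system in state x
#' at t is still (or again) associated with x at t + tau. Monotone decay
#' of `corr_x` indicates transient occupancy; non-monotone behaviour
#' indicates recurrence.
#'
#' @param s a [membership_series()].
#' @param x state label (character; `"unassigned"` is allowed).
#' @return An object of class `correlation_series`: list with `state`,
#'   `raw` (data frame `tau`, `value`), and `summary` (data frame `tau`,
#'   `n_pairs`, `mean`, `sem`; `sem` is `NA` for single-pair tau).
#' @export
temporal_correlation <- function(s, x) {
  stopifnot(inherits(s, "membership_series"))
  x <- as.character(x)
  visited <- any(vapply(s$labels, function(l) x %in% l, logical(1)))
  if (!visited) stop("state '", x, "' never visited by subject '",
                     s$subject, "'")
  n <- length(s$time)
  taus <- c(); vals <- c()
  for (i in seq_len(n)) {
    if (!(x %in% s$labels[[i]])) next
    for (j in i:n) {
      taus <- c(taus, s$time[j] - s$time[i])
      vals <- c(vals, .fprime(s, j, x))
    }
  }
  raw <- data.frame(tau = taus, value = vals)
  raw <- raw[order(raw$tau), , drop = FALSE]
  rownames(raw) <- NULL
  by_tau <- split(raw$value, raw$tau)
  summ <- data.frame(
    tau = as.numeric(names(by_tau)),
    n_pairs = vapply(by_tau, length, integer(1)),
    mean = vapply(by_tau, mean, numeric(1)),
    sem = vapply(by_tau, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)),
    row.names = NULL)
  structure(list(state = x, subject = s$subject, raw = raw,
                 summary = summ),
            class = "correlation_series")
}

#' @export
print.correlation_series <- function(x, ...) {
  cat("correlation_series: state '", x$state, "', ", nrow(x$summary),
      " distinct tau, ", nrow(x$raw), " raw pairs\n", sep = "")
  print(utils::head(x$summary, 10))
  invisible(x)
}

#' Moving-average smoothing of a correlation series
#'
#' Smooths the per-tau means with a simple moving average: the smoothed
#' value at tau is the mean of all per-tau means within
#' `tau +/- bandwidth / 2`. The raw pairs are never altered.
#'
#' @param c a [temporal_correlation()] result.
#' @param bandwidth window width in the series' time units (> 0).
#' @return data frame `tau`, `smoothed`.
#' @export
smooth_correlation <- function(c, bandwidth) {
  stopifnot(inherits(c, "correlation_series"))
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (nrow(c$summary) < 2) stop("need at least 2 distinct tau to smooth")
  tau <- c$summary$tau; m <- c$summary$mean
  sm <- vapply(tau, function(t0)
    mean(m[abs(tau - t0) <= bandwidth / 2]), numeric(1))
  data.frame(tau = tau, smoothed = sm)
}

#' Monotonicity index of a correlation series
#'
#' Spearman rank correlation between tau and `corr_x(tau)`. Values near -1
#' indicate monotone decay (transient, metastable occupancy); values near 0
#' or above indicate recurrence (the subject revisits the state).
#'
#' @param c a [temporal_correlation()] result with >= 3 distinct tau.
#' @return scalar in \[-1, 1\], with attribute `n_tau`.
#' @export
monotonicity_index <- function(c) {
  stopifnot(inherits(c, "correlation_series"))
  if (nrow(c$summary) < 3) stop("need >= 3 distinct tau")
  r <- stats::cor(c$summary$tau, c$summary$mean, method = "spearman")
  attr(r, "n_tau") <- nrow(c$summary)
  r
}

#' Write a correlation series as TSV
#'
#' Columns: subject, state, tau, n_pairs, mean, sem. With `raw = TRUE` a
#' long-format raw-pair table (subject, state, tau, value) is written
#' instead.
#'
#' @param c a `correlation_series`.
#' @param path output file.
#' @param raw write raw pairs instead of the per-tau summary.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(c, path, raw = FALSE) {
  df <- if (raw)
    data.frame(subject = c$subject, state = c$state, c$raw)
  else
    data.frame(subject = c$subject, state = c$state, c$summary)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a correlation series
#'
#' Dots: raw `f'` values per pair. Line: (optionally smoothed) mean.
#' Ribbon: +/- 1 SEM around the mean.
#'
#' @param x a `correlation_series`.
#' @param bandwidth optional smoothing bandwidth passed to
#'   [smooth_correlation()].
#' @param ... further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.correlation_series <- function(x, bandwidth = NULL, ...) {
  s <- x$summary
  graphics::plot(x$raw$tau, x$raw$value, pch = 16,
                 col = grDevices::adjustcolor("grey40", 0.5),
                 xlab = expression(tau), ylab = expression(corr[x](tau)),
                 ylim = c(0, 1),
                 main = paste0("state ", x$state, " (", x$subject, ")"), ...)
  ok <- !is.na(s$sem)
  if (any(ok))
    graphics::polygon(c(s$tau[ok], rev(s$tau[ok])),
                      c(pmin(s$mean[ok] + s$sem[ok], 1),
                        rev(pmax(s$mean[ok] - s$sem[ok], 0))),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
  line_y <- if (!is.null(bandwidth) && nrow(s) >= 2)
    smooth_correlation(x, bandwidth)$smoothed else s$mean
  graphics::lines(s$tau, line_y, col = "steelblue", lwd = 2)
  invisible(x)
}
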