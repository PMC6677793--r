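#' A thermal-unfolding curve
#'
#' @param temperature strictly increasing grid, degrees C.
#' @param signal ellipticity (or normalized fraction unfolded).
#' @param condition,replicate optional labels.
#' @param normalized logical flag.
#' @return a `melt_curve` object (data.frame-backed).
#' @export
melt_curve <- function(temperature, signal, condition = NA_character_,
                       replicate = NA_integer_, normalized = FALSE) {
  if (length(temperature) != length(signal))
    stop("temperature and signal lengths differ", call. = FALSE)
  if (length(temperature) < 10)
    stop("melt curve needs >= 10 points", call. = FALSE)
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing", call. = FALSE)
  structure(list(temperature = as.numeric(temperature),
                 signal = as.numeric(signal),
                 condition = condition, replicate = replicate,
                 normalized = normalized),
            class = "melt_curve")
}

#' Average replicate melt curves onto a common grid
#'
#' Linear interpolation onto the intersection of the temperature ranges,
#' using the first curve's grid restricted to that range.
#'
#' @param curves list of [melt_curve()] objects.
#' @return a single averaged [melt_curve()].
#' @export
average_replicates <- function(curves) {
  stopifnot(length(curves) >= 1)
  if (length(curves) == 1) return(curves[[1]])
  lo <- max(vapply(curves, function(c) min(c$temperature), numeric(1)))
  hi <- min(vapply(curves, function(c) max(c$temperature), numeric(1)))
  if (lo >= hi) stop("replicate temperature ranges do not overlap", call. = FALSE)
  grid <- curves[[1]]$temperature
  grid <- grid[grid >= lo & grid <= hi]
  sig <- rowMeans(sapply(curves, function(c)
    stats::approx(c$temperature, c$signal, xout = grid)$y))
  melt_curve(grid, sig, condition = curves[[1]]$condition,
             normalized = curves[[1]]$normalized)
}

#' Normalize a melt curve to fraction unfolded
#'
#' Default `"baseline"` mode fits linear pre- and post-transition baselines
#' over the first and last `baseline_frac` of points and reports
#' f(T) = (signal - folded(T)) / (unfolded(T) - folded(T)), clipped to
#' [-0.05, 1.05]. `"minmax"` mode rescales by the signal extremes.
#'
#' @param curve a [melt_curve()].
#' @param method `"baseline"` or `"minmax"`.
#' @param baseline_frac fraction of points in each end window.
#' @return normalized [melt_curve()].
#' @export
normalize_melt <- function(curve, method = c("baseline", "minmax"),
                           baseline_frac = 0.1) {
  stopifnot(inherits(curve, "melt_curve"))
  method <- match.arg(method)
  T <- curve$temperature; y <- curve$signal
  n <- length(T)
  if (method == "minmax") {
    rng <- range(y)
    if (diff(rng) < 1e-12)
      stop("normalization error: flat signal", call. = FALSE)
    f <- (y - rng[1]) / diff(rng)
    if (y[1] > y[n]) f <- 1 - f   # descending raw signal
  } else {
    k <- max(2L, floor(n * baseline_frac))
    if (2 * k >= n)
      stop("normalization error: baseline windows overlap", call. = FALSE)
    pre <- stats::lm(y ~ T, data = data.frame(T = T[1:k], y = y[1:k]))
    post <- stats::lm(y ~ T, data = data.frame(T = T[(n - k + 1):n],
                                               y = y[(n - k + 1):n]))
    folded <- stats::predict(pre, data.frame(T = T))
    unfolded <- stats::predict(post, data.frame(T = T))
    span <- unfolded - folded
    mid <- span[which.min(abs(T - stats::median(T)))]
    if (abs(mid) < 1e-6 * max(abs(y) + 1e-12))
      stop("normalization error: baselines indistinguishable", call. = FALSE)
    f <- (y - folded) / span
  }
  f <- pmin(pmax(f, -0.05), 1.05)
  melt_curve(T, f, condition = curve$condition, replicate = curve$replicate,
             normalized = TRUE)
}

#' Savitzky-Golay smoothing followed by differentiation
#'
#' Smooths the signal with a Savitzky-Golay filter (default 5-point window,
#' polynomial order 2) and differentiates with respect to temperature by
#' central differences at interior points and one-sided differences at the
#' ends. With polynomial order >= 2 and a uniform grid the derivative of a
#' quadratic is reproduced exactly at interior points.
#'
#' @param curve a [melt_curve()].
#' @param window odd filter length (>= polyorder + 2, <= n points).
#' @param polyorder polynomial order.
#' @return a [melt_curve()] whose `signal` is df/dT (per degree C).
#' @export
smooth_derivative <- function(curve, window = 5, polyorder = 2) {
  stopifnot(inherits(curve, "melt_curve"))
  n <- length(curve$temperature)
  if (window %% 2 == 0 || window < polyorder + 2 || window > n)
    stop("parameter error: window must be odd, >= polyorder + 2 and <= n",
         call. = FALSE)
  ys <- signal::sgolayfilt(curve$signal, p = polyorder, n = window)
  T <- curve$temperature
  d <- numeric(n)
  d[1] <- (ys[2] - ys[1]) / (T[2] - T[1])
  d[n] <- (ys[n] - ys[n - 1]) / (T[n] - T[n - 1])
  i <- 2:(n - 1)
  d[i] <- (ys[i + 1] - ys[i - 1]) / (T[i + 1] - T[i - 1])
  out <- melt_curve(T, d, condition = curve$condition,
                    replicate = curve$replicate)
  out$derivative <- TRUE
  out
}

.gauss_sum <- function(T, pars, k) {
  y <- rep(pars[["c0"]], length(T))
  for (j in seq_len(k))
    y <- y + pars[[paste0("a", j)]] *
      exp(-0.5 * ((T - pars[[paste0("m", j)]]) / pars[[paste0("s", j)]])^2)
  y
}

#' Fit Gaussian components to a derivative melt curve
#'
#' Nonlinear least squares of a sum of `n_components` Gaussians plus a
#' constant baseline to df/dT; the component centers are the melting
#' temperatures. Initial centers default to the `n_components` largest
#' local maxima of the derivative.
#'
#' @param dcurve derivative curve from [smooth_derivative()].
#' @param n_components number of Gaussian components (>= 1).
#' @param init optional list with numeric vectors `centers`, `amplitudes`,
#'   `widths` overriding the automatic initialization.
#' @return object of class `peak_fit`: `components` data.frame (amplitude,
#'   center, width, se_center) sorted by center, `baseline`, `rss`,
#'   `n_components`; a `degenerate` attribute flags centers closer than
#'   0.5 degrees C.
#' @export
fit_peaks <- function(dcurve, n_components = 1, init = NULL) {
  stopifnot(inherits(dcurve, "melt_curve"))
  k <- as.integer(n_components)
  if (k < 1) stop("n_components must be >= 1", call. = FALSE)
  T <- dcurve$temperature; y <- dcurve$signal
  if (length(T) < 5 * k)
    stop("fit error: need >= ", 5 * k, " points for ", k, " components",
         call. = FALSE)

  if (is.null(init)) {
    interior <- 2:(length(y) - 1)
    loc <- interior[y[interior] > y[interior - 1] & y[interior] >= y[interior + 1]]
    span <- max(y) - min(y)
    loc <- loc[y[loc] - stats::median(y) > 0.05 * max(span, 1e-12)]
    if (!length(loc) || span < 1e-10 * max(abs(y), 1))
      stop("fit error: no peak found in derivative curve", call. = FALSE)
    if (length(loc) < k) {
      # fall back: seed extra components across the range
      extra <- seq(min(T), max(T), length.out = k + 2)[2:(k + 1)]
      centers <- c(T[loc], extra)[seq_len(k)]
      amps <- rep(max(y[loc]) - stats::median(y), k)
    } else {
      loc <- loc[order(y[loc], decreasing = TRUE)][seq_len(k)]
      centers <- T[loc]
      amps <- y[loc] - stats::median(y)
    }
    widths <- rep(diff(range(T)) / (6 * k), k)
  } else {
    centers <- init$centers; amps <- init$amplitudes; widths <- init$widths
    stopifnot(length(centers) == k, length(amps) == k, length(widths) == k)
  }

  start <- c(list(c0 = stats::median(y)),
             stats::setNames(as.list(amps), paste0("a", seq_len(k))),
             stats::setNames(as.list(centers), paste0("m", seq_len(k))),
             stats::setNames(as.list(widths), paste0("s", seq_len(k))))
  lower <- c(-Inf, rep(0, k), rep(min(T), k), rep(0.05, k))
  upper <- c(Inf, rep(Inf, k), rep(max(T), k), rep(diff(range(T)), k))
  form <- stats::as.formula(paste(
    "y ~ c0 +",
    paste(sprintf("a%d * exp(-0.5 * ((T - m%d) / s%d)^2)",
                  seq_len(k), seq_len(k), seq_len(k)), collapse = " + ")))
  dat <- data.frame(T = T, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("fit error: peak fit did not converge (",
                             conditionMessage(e), ")", call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  comp <- data.frame(amplitude = cf[paste0("a", seq_len(k))],
                     center = cf[paste0("m", seq_len(k))],
                     width = cf[paste0("s", seq_len(k))],
                     se_center = se[paste0("m", seq_len(k))])
  comp <- comp[order(comp$center), ]
  rownames(comp) <- NULL
  degenerate <- k > 1 && any(diff(comp$center) < 0.5)
  if (degenerate)
    warning("degeneracy warning: Gaussian centers within 0.5 degrees C",
            call. = FALSE)
  structure(list(components = comp, baseline = unname(cf["c0"]),
                 rss = sum(stats::resid(fit)^2), n_components = k,
                 degenerate = degenerate),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat("Gaussian peak fit:", x$n_components, "component(s), rss",
      format(x$rss, digits = 4), "\n")
  print(x$components, digits = 4)
  invisible(x)
}

#' Melting-temperature shift between two conditions
#'
#' @param control_fit,treated_fit [fit_peaks()] results.
#' @param component 1-based index into the center-sorted components.
#' @return list with `delta_tm` (treated - control, degrees C) and `se`
#'   (propagated from the two fitted center uncertainties).
#' @export
delta_tm <- function(control_fit, treated_fit, component = 1) {
  for (f in list(control_fit, treated_fit))
    if (component < 1 || component > f$n_components)
      stop("index error: component ", component, " out of range", call. = FALSE)
  d <- treated_fit$components$center[component] -
    control_fit$components$center[component]
  se <- sqrt(sum(c(treated_fit$components$se_center[component],
                   control_fit$components$se_center[component])^2,
                 na.rm = TRUE))
  list(delta_tm = d, se = se)
}

#' Full melt pipeline: normalize, smooth, differentiate, fit
#'
#' @param curves a [melt_curve()] or list of replicates (averaged first).
#' @param n_components Gaussian components.
#' @param normalize_method passed to [normalize_melt()].
#' @param window,polyorder passed to [smooth_derivative()].
#' @return a `peak_fit`.
#' @export
melt_pipeline <- function(curves, n_components = 1,
                          normalize_method = "baseline",
                          window = 5, polyorder = 2) {
  curve <- if (inherits(curves, "melt_curve")) curves else
    average_replicates(curves)
  norm <- normalize_melt(curve, method = normalize_method)
  der <- smooth_derivative(norm, window = window, polyorder = polyorder)
  fit_peaks(der, n_components = n_components)
}

#' Read melt curves from a CSV/TSV table
#'
#' Expected columns: `temperature_C`, `signal`, optional `condition` and
#' `replicate`. Returns one [melt_curve()] per condition/replicate pair.
#'
#' @param path file path (delimiter inferred from extension).
#' @return named list of [melt_curve()] objects.
#' @export
read_melt_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("temperature_C", "signal") %in% names(df)))
    stop("melt table needs columns temperature_C and signal", call. = FALSE)
  if (is.null(df$condition)) df$condition <- "all"
  if (is.null(df$replicate)) df$replicate <- 1L
  keys <- unique(df[, c("condition", "replicate")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$condition == keys$condition[i] &
                df$replicate == keys$replicate[i], ]
    sub <- sub[order(sub$temperature_C), ]
    out[[paste(keys$condition[i], keys$replicate[i], sep = ".")]] <-
      melt_curve(sub$temperature_C, sub$signal,
                 condition = keys$condition[i],
                 replicate = keys$replicate[i])
  }
  out
}
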