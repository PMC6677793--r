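DPM_PER_MCI <- 2.22e9  # disintegrations per minute per millicurie

#' Specific activity of a radiolabelled compound
#'
#' @param value specific activity, mCi/mmol.
#' @param efficiency scintillation counting efficiency (cpm/dpm), in (0, 1].
#' @return a `specific_activity` object.
#' @export
specific_activity <- function(value, efficiency = 1) {
  if (value <= 0) stop("parameter error: specific activity must be positive",
                       call. = FALSE)
  if (efficiency <= 0 || efficiency > 1)
    stop("parameter error: efficiency must be in (0, 1]", call. = FALSE)
  structure(list(value = value, efficiency = efficiency),
            class = "specific_activity")
}

#' Convert scintillation counts to a molar concentration
#'
#' amount (mmol) = (cpm / efficiency) / (SA (mCi/mmol) x 2.22e9 dpm/mCi);
#' concentration = amount / volume.
#'
#' @param counts_cpm counts per minute (>= 0, vectorized).
#' @param sa a [specific_activity()].
#' @param volume_uL counted volume, microlitres.
#' @return concentration in micromolar.
#' @export
cpm_to_concentration <- function(counts_cpm, sa, volume_uL) {
  stopifnot(inherits(sa, "specific_activity"))
  if (volume_uL <= 0) stop("parameter error: volume must be positive",
                           call. = FALSE)
  if (any(counts_cpm < 0)) stop("counts must be >= 0", call. = FALSE)
  amount_mmol <- (counts_cpm / sa$efficiency) / (sa$value * DPM_PER_MCI)
  amount_mmol / (volume_uL * 1e-9)   # mmol / (L * 1e-3) -> uM
}

#' Isotopic dilution of specific activity
#'
#' Mixing hot compound with cold at a cold:hot molar ratio q gives
#' SA_mix = SA_hot / (1 + q). The inverse mode returns the cold:hot ratio
#' required to reach a target specific activity.
#'
#' @param hot_sa specific activity of the labelled stock, mCi/mmol.
#' @param cold_to_hot cold:hot molar ratio (mixing mode).
#' @param target target specific activity, mCi/mmol (inverse mode).
#' @return mixed specific activity (mCi/mmol), or the required cold:hot
#'   ratio when `target` is given.
#' @export
dilute_specific_activity <- function(hot_sa, cold_to_hot = NULL, target = NULL) {
  if (hot_sa <= 0) stop("parameter error: hot SA must be positive", call. = FALSE)
  if (!is.null(target)) {
    if (target >= hot_sa)
      stop("dilution error: target SA must be below the hot SA", call. = FALSE)
    return(hot_sa / target - 1)
  }
  if (is.null(cold_to_hot) || cold_to_hot < 0)
    stop("parameter error: cold_to_hot ratio must be >= 0", call. = FALSE)
  hot_sa / (1 + cold_to_hot)
}

#' A binding isotherm
#'
#' @param conc_uM free-ligand concentrations, micromolar (>= 0).
#' @param bound bound quantity (micromolar, or molar-ratio units).
#' @param condition `"pre_incubation"` or `"post_incubation"`.
#' @return an `isotherm` object.
#' @export
isotherm <- function(conc_uM, bound,
                     condition = c("pre_incubation", "post_incubation")) {
  condition <- match.arg(condition)
  if (length(conc_uM) != length(bound))
    stop("conc and bound lengths differ", call. = FALSE)
  if (any(conc_uM < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (length(unique(conc_uM)) < 4)
    stop("need >= 4 distinct concentrations", call. = FALSE)
  structure(list(conc_uM = as.numeric(conc_uM), bound = as.numeric(bound),
                 condition = condition),
            class = "isotherm")
}

#' One-site specific binding fit
#'
#' Least-squares fit of B(L) = Bmax L / (Kd + L) with L the free ligand
#' concentration. An ill-conditioned fit (fitted Kd beyond 3x the largest
#' concentration, i.e. no curvature in range) is flagged via the
#' `ill_conditioned` element.
#'
#' @param iso an [isotherm()].
#' @param fix_bmax optional fixed Bmax.
#' @return object of class `one_site_fit` with `kd`, `bmax`, `se_kd`,
#'   `se_bmax`, `rss`, `n`, `ill_conditioned`.
#' @export
fit_one_site <- function(iso, fix_bmax = NULL) {
  stopifnot(inherits(iso, "isotherm"))
  L <- iso$conc_uM; B <- iso$bound
  if (max(abs(B)) < 1e-12)
    stop("fit error: all bound values are zero", call. = FALSE)
  dat <- data.frame(L = L, B = B)
  half <- max(B) / 2
  kd0 <- L[which.min(abs(B - half))]
  if (kd0 <= 0) kd0 <- stats::median(L[L > 0])
  fit <- tryCatch({
    if (is.null(fix_bmax)) {
      minpack.lm::nlsLM(B ~ Bmax * L / (Kd + L), data = dat,
                        start = list(Bmax = max(B) * 1.2, Kd = kd0),
                        lower = c(1e-9, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(B ~ Bmax * L / (Kd + L),
                        data = cbind(dat, Bmax = fix_bmax),
                        start = list(Kd = kd0), lower = 1e-9,
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) stop("fit error: one-site fit did not converge (",
                              conditionMessage(e), ")", call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(
                   rep(NA_real_, length(cf)), names(cf)))
  kd <- unname(cf["Kd"])
  bmax <- if (is.null(fix_bmax)) unname(cf["Bmax"]) else fix_bmax
  structure(list(kd = kd, bmax = bmax,
                 se_kd = unname(se["Kd"]),
                 se_bmax = if (is.null(fix_bmax)) unname(se["Bmax"]) else 0,
                 rss = sum(stats::resid(fit)^2), n = length(L),
                 ill_conditioned = kd > 3 * max(L)),
            class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat(sprintf("one-site fit: Kd %.3g uM (se %.2g), Bmax %.3g (se %.2g), n %d%s\n",
              x$kd, x$se_kd, x$bmax, x$se_bmax, x$n,
              if (x$ill_conditioned) " [ill-conditioned]" else ""))
  invisible(x)
}

#' Molar ratio of bound ligand per overlap junction
#'
#' In a continuous head-to-tail co-polymer every coiled-coil dimer
#' contributes one overlap junction, so the default `junctions_per_dimer`
#' is 1; a finite-filament correction ((n-1)/n for n dimers) can be passed
#' instead.
#'
#' @param bound_uM bound ligand, micromolar.
#' @param dimer_uM coiled-coil dimer concentration, micromolar (> 0).
#' @param junctions_per_dimer junctions contributed per dimer, in (0, 1].
#' @return molar ratio (dimensionless).
#' @export
molar_ratio_per_junction <- function(bound_uM, dimer_uM,
                                     junctions_per_dimer = 1) {
  if (dimer_uM <= 0) stop("division error: dimer concentration must be > 0",
                          call. = FALSE)
  if (junctions_per_dimer <= 0 || junctions_per_dimer > 1)
    stop("junctions_per_dimer must be in (0, 1]", call. = FALSE)
  bound_uM / (dimer_uM * junctions_per_dimer)
}

#' Compare pre- and post-incubation binding
#'
#' Interpolates both isotherms onto the overlapping concentration range and
#' reports per-concentration bound differences (pre - post). The
#' post-incubation condition is flagged background-level when its bound
#' signal stays below `background_fraction` of the pre-condition Bmax across
#' the whole range.
#'
#' @param pre,post [isotherm()] objects.
#' @param background_fraction flag threshold (default 0.2).
#' @return list with `table` (conc, pre, post, difference),
#'   `background_level` flag, `sign` (+1 if pre >= post overall) and the
#'   pre-condition `bmax`.
#' @export
compare_conditions <- function(pre, post, background_fraction = 0.2) {
  stopifnot(inherits(pre, "isotherm"), inherits(post, "isotherm"))
  lo <- max(min(pre$conc_uM), min(post$conc_uM))
  hi <- min(max(pre$conc_uM), max(post$conc_uM))
  if (lo >= hi) stop("comparison error: concentration ranges are disjoint",
                     call. = FALSE)
  grid <- sort(unique(c(pre$conc_uM, post$conc_uM)))
  grid <- grid[grid >= lo & grid <= hi]
  p <- stats::approx(pre$conc_uM, pre$bound, xout = grid, ties = mean)$y
  q <- stats::approx(post$conc_uM, post$bound, xout = grid, ties = mean)$y
  bmax <- fit_one_site(pre)$bmax
  background <- all(q < background_fraction * bmax)
  list(table = data.frame(conc_uM = grid, pre = p, post = q,
                          difference = p - q),
       background_level = background,
       sign = if (all(q >= p)) -1 else 1,
       bmax = bmax)
}

#' Read a radioligand binding table
#'
#' Expected columns: `conc_uM` plus either `bound_uM` or `counts_cpm`
#' (converted via `sa`/`volume_uL`), optional `condition`, `replicate`.
#'
#' @param path CSV/TSV path.
#' @param sa optional [specific_activity()] for count conversion.
#' @param volume_uL counted volume for count conversion.
#' @return data.frame with `conc_uM`, `bound_uM`, `condition`, `replicate`.
#' @export
read_binding_table <- function(path, sa = NULL, volume_uL = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"conc_uM" %in% names(df))
    stop("binding table needs a conc_uM column", call. = FALSE)
  if (is.null(df$bound_uM)) {
    if (is.null(df$counts_cpm) || is.null(sa) || is.null(volume_uL))
      stop("binding table without bound_uM needs counts_cpm plus sa and ",
           "volume_uL", call. = FALSE)
    df$bound_uM <- cpm_to_concentration(df$counts_cpm, sa, volume_uL)
  }
  if (is.null(df$condition)) df$condition <- "pre_incubation"
  if (is.null(df$replicate)) df$replicate <- 1L
  df
}
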