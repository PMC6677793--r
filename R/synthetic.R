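# Seeded generators for every input class consumed by the pipeline. Each is
# a pure function of its arguments (seed included) and records its ground
# truth; when `dir` is given, the data file is written next to a sidecar
# "<name>_truth.json" so downstream code can never read the truth by
# accident.

.write_truth <- function(truth, data_path) {
  truth_path <- paste0(tools::file_path_sans_ext(data_path), "_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  truth_path
}

#' Generate an ideal (optionally jittered) coiled coil
#'
#' Wraps [build_ideal_coiled_coil()], adding seeded Gaussian coordinate
#' jitter.
#'
#' @param seed integer seed.
#' @param params a [crick_parameters()].
#' @param n_residues residues per chain.
#' @param jitter_sd coordinate noise SD, Angstrom.
#' @param dir if given, write `coiled_coil.pdb` plus truth sidecar there.
#' @return list with `structure`, `truth`, and (if written) `paths`.
#' @export
gen_coiled_coil <- function(seed = 1, params = crick_parameters(),
                            n_residues = 60, jitter_sd = 0, dir = NULL) {
  x <- build_ideal_coiled_coil(params, n_residues)
  if (jitter_sd > 0) {
    x <- withr::with_seed(seed, {
      co <- model_coords(x, 1)
      set_model_coords(x, co + matrix(stats::rnorm(length(co), 0, jitter_sd),
                                      ncol = 3))
    })
  }
  truth <- list(kind = "coiled_coil", seed = seed, n_residues = n_residues,
                jitter_sd = jitter_sd, crick = unclass(params))
  out <- list(structure = x, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(dir, "coiled_coil.pdb")
    write_pdb(x, p)
    out$paths <- c(data = p, truth = .write_truth(truth, p))
  }
  out
}

## Base (untransformed) 4-helix bundle: N-side dimer above the junction
## plane, C-side dimer below, all four helices parallel to +z.
.base_bundle <- function(params, n_res, c_start, axial_gap, radial_offsets) {
  rise_total <- (n_res - 1) * params$rise
  nd <- build_ideal_coiled_coil(params, n_res, chain_ids = c("A", "B"),
                                start_resno = 1)
  cd <- build_ideal_coiled_coil(params, n_res, chain_ids = c("C", "D"),
                                start_resno = c_start)
  shift <- function(s, dz) set_model_coords(
    s, sweep(model_coords(s, 1), 2, c(0, 0, -dz), `+`))
  nd <- shift(nd, -axial_gap / 2)                    # z in [g/2, g/2 + L]
  cd <- shift(cd, rise_total + axial_gap / 2)        # z in [-L - g/2, -g/2]
  # Null the baseline twist of the reference geometry: the superhelix
  # accumulates ~4 deg of phase per residue along the C-side window, so the
  # untransformed bundle has a nonzero measured twist. Rotate the C-side
  # dimer so the reference bundle reads theta = 0; imposed twists are then
  # absolute offsets from that reference.
  ref <- .bundle_frame(list(nd = nd, cd = cd), 0, 0)
  jx <- junction_spec(c("A", "B"), c("C", "D"),
                      c(1, n_res), c(c_start, c_start + n_res - 1))
  theta_base <- overlap_angles(ref, jx)$theta
  cd <- set_model_coords(cd, model_coords(cd, 1) %*%
                           t(rotation_about(c(0, 0, 1), -theta_base)))
  if (!is.null(radial_offsets)) {
    # displace each residue outward along its local superhelical phase
    # direction, so the per-residue coiled-coil radius grows by exactly the
    # requested amount
    sh <- if (params$superhelix_left) -1 else 1
    w0_deg <- rad2deg(sh * 2 * pi * params$rise / params$pitch)
    starts <- c(A = 1, B = 1, C = c_start, D = c_start)
    phase0 <- c(A = params$chain_offsets[1], B = params$chain_offsets[2],
                C = params$chain_offsets[1] - theta_base,
                D = params$chain_offsets[2] - theta_base)
    for (s_name in c("nd", "cd")) {
      s <- get(s_name)
      co <- model_coords(s, 1)
      for (ch in intersect(names(radial_offsets), unique(s$atom$chain))) {
        rows <- which(s$atom$chain == ch)
        t0 <- s$atom$resno[rows] - starts[[ch]]
        phi <- deg2rad(w0_deg * t0 + phase0[[ch]])
        co[rows, 1] <- co[rows, 1] + radial_offsets[[ch]] * cos(phi)
        co[rows, 2] <- co[rows, 2] + radial_offsets[[ch]] * sin(phi)
      }
      assign(s_name, set_model_coords(s, co))
    }
  }
  list(nd = nd, cd = cd)
}

.bundle_frame <- function(base, theta, omega) {
  co <- model_coords(base$cd, 1)
  co <- co %*% t(rotation_about(c(0, 0, 1), theta))   # twist about central axis
  co <- co %*% t(rotation_about(c(1, 0, 0), omega))   # bend about junction
  cd <- set_model_coords(base$cd, co)
  atom <- rbind(base$nd$atom, cd$atom)
  atom$eleno <- seq_len(nrow(atom))
  xyz <- cbind(base$nd$xyz, cd$xyz)
  cc_structure(atom, xyz)
}

#' Generate a 4-helix overlap bundle with imposed bend and twist
#'
#' Two ideal parallel dimers (N-terminal chains A/B numbered from 1,
#' C-terminal chains C/D numbered from `c_start`) meet at the junction
#' plane; the C-side is rotated by `theta` about the central axis and by
#' `omega` about an in-plane axis through the junction midpoint. Optional
#' per-chain radial displacement emulates outward movement of individual
#' helices; optional coordinate jitter adds seeded noise.
#'
#' @param seed integer seed (used only when `jitter_sd > 0`).
#' @param theta imposed twist, degrees in (-180, 180].
#' @param omega imposed bend, degrees in \[0, 60\].
#' @param n_res residues per chain.
#' @param c_start first residue number of the C-terminal chains.
#' @param params [crick_parameters()] (dimer).
#' @param axial_gap junction gap between the dimers, Angstrom.
#' @param radial_offsets named numeric (chain -> outward displacement, A).
#' @param jitter_sd coordinate noise SD, Angstrom.
#' @param dir if given, write `overlap_bundle.pdb` + truth sidecar.
#' @return list with `structure`, `junction` (a ready [junction_spec()]),
#'   `truth`, and (if written) `paths`.
#' @export
gen_overlap_bundle <- function(seed = 1, theta = 0, omega = 0, n_res = 30,
                               c_start = 169, params = crick_parameters(),
                               axial_gap = 2.5, radial_offsets = NULL,
                               jitter_sd = 0, dir = NULL) {
  if (omega < 0 || omega > 60)
    stop("parameter error: omega must be in [0, 60] degrees", call. = FALSE)
  if (theta <= -180 || theta > 180)
    stop("parameter error: theta must be in (-180, 180] degrees", call. = FALSE)
  base <- .base_bundle(params, n_res, c_start, axial_gap, radial_offsets)
  x <- .bundle_frame(base, theta, omega)
  # clash check between the two dimers (CA only)
  ca <- x$atom$elety == "CA"
  co <- model_coords(x, 1)
  nd_ca <- co[ca & x$atom$chain %in% c("A", "B"), , drop = FALSE]
  cd_ca <- co[ca & x$atom$chain %in% c("C", "D"), , drop = FALSE]
  dmin <- min(apply(nd_ca, 1, function(p)
    min(sqrt(rowSums(sweep(cd_ca, 2, p)^2)))))
  if (dmin < 2.0)
    stop(sprintf("clash error: inter-dimer CA distance %.2f A < 2.0 A", dmin),
         call. = FALSE)
  if (jitter_sd > 0) {
    x <- withr::with_seed(seed, set_model_coords(
      x, model_coords(x, 1) +
        matrix(stats::rnorm(3 * nrow(x$atom), 0, jitter_sd), ncol = 3)))
  }
  junction <- junction_spec(
    nterm_chains = c("A", "B"), cterm_chains = c("C", "D"),
    nterm_window = c(1, n_res), cterm_window = c(c_start, c_start + n_res - 1))
  truth <- list(kind = "overlap_bundle", seed = seed, theta = theta,
                omega = omega, n_res = n_res, c_start = c_start,
                axial_gap = axial_gap,
                radial_offsets = as.list(radial_offsets),
                jitter_sd = jitter_sd, crick = unclass(params))
  out <- list(structure = x, junction = junction, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(dir, "overlap_bundle.pdb")
    write_pdb(x, p)
    out$paths <- c(data = p, truth = .write_truth(truth, p))
  }
  out
}

#' Generate a multi-frame trajectory of an overlap bundle
#'
#' Frames interpolate the bend/twist linearly from their start values to
#' the target values, reached at `converge_frame`, then fluctuate about the
#' target with Gaussian SD `angle_noise_sd` -- emulating the behaviour of a
#' production run that settles onto a new stable geometry.
#'
#' @param seed integer seed.
#' @param n_frames number of frames (>= 2).
#' @param theta0,omega0 starting angles, degrees.
#' @param theta1,omega1 target angles, degrees.
#' @param converge_frame frame at which the target is reached
#'   (default: one third of the frames).
#' @param angle_noise_sd per-frame angular noise SD, degrees.
#' @param jitter_sd per-frame coordinate noise SD, Angstrom.
#' @param n_res,c_start,params,axial_gap as in [gen_overlap_bundle()].
#' @param dir if given, write `trajectory.pdb` + truth sidecar.
#' @return list with `structure` (multi-model), `junction`, `truth`
#'   (including per-frame realized angles), and optional `paths`.
#' @export
gen_trajectory <- function(seed = 1, n_frames = 35, theta0 = 0, omega0 = 0,
                           theta1 = 15, omega1 = 8, converge_frame = NULL,
                           angle_noise_sd = 0.5, jitter_sd = 0,
                           n_res = 30, c_start = 169,
                           params = crick_parameters(), axial_gap = 2.5,
                           dir = NULL) {
  if (n_frames < 2) stop("parameter error: need >= 2 frames", call. = FALSE)
  if (is.null(converge_frame)) converge_frame <- ceiling(n_frames / 3)
  if (converge_frame < 1 || converge_frame > n_frames)
    stop("parameter error: converge_frame outside 1..n_frames", call. = FALSE)
  base <- .base_bundle(params, n_res, c_start, axial_gap, NULL)
  res <- withr::with_seed(seed, {
    t <- seq_len(n_frames)
    prog <- pmin(t / converge_frame, 1)
    th <- theta0 + (theta1 - theta0) * prog +
      stats::rnorm(n_frames, 0, angle_noise_sd)
    om <- pmax(0, omega0 + (omega1 - omega0) * prog +
                 stats::rnorm(n_frames, 0, angle_noise_sd))
    frames <- lapply(seq_len(n_frames), function(i) {
      f <- .bundle_frame(base, th[i], om[i])
      if (jitter_sd > 0)
        f <- set_model_coords(f, model_coords(f, 1) +
                                matrix(stats::rnorm(3 * nrow(f$atom), 0,
                                                    jitter_sd), ncol = 3))
      f
    })
    list(frames = frames, theta = th, omega = om)
  })
  x <- structures_to_trajectory(res$frames)
  junction <- junction_spec(
    nterm_chains = c("A", "B"), cterm_chains = c("C", "D"),
    nterm_window = c(1, n_res), cterm_window = c(c_start, c_start + n_res - 1))
  truth <- list(kind = "trajectory", seed = seed, n_frames = n_frames,
                theta_start = theta0, omega_start = omega0,
                theta_target = theta1, omega_target = omega1,
                converge_frame = converge_frame,
                angle_noise_sd = angle_noise_sd, jitter_sd = jitter_sd,
                realized = list(theta = res$theta, omega = res$omega))
  out <- list(structure = x, junction = junction, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(dir, "trajectory.pdb")
    write_pdb(x, p)
    out$paths <- c(data = p, truth = .write_truth(truth, p))
  }
  out
}

#' Generate two-state thermal melt curves
#'
#' Signal is a linear folded baseline plus a sum of logistic transitions
#' (one per melting temperature) plus seeded Gaussian noise, on a 20-65
#' degree C grid by default -- the shape of an ellipticity-at-222 nm
#' unfolding experiment.
#'
#' @param seed integer seed.
#' @param tm melting temperature(s), degrees C (inside the grid).
#' @param width transition width(s), degrees C (logistic scale parameter).
#' @param amplitude transition amplitude(s).
#' @param t_range temperature range, degrees C.
#' @param step grid step, degrees C.
#' @param noise_sd Gaussian noise SD, signal units.
#' @param baseline_intercept,baseline_slope folded-baseline parameters.
#' @param replicates number of replicate curves (independent noise).
#' @param condition label carried on the curves.
#' @param dir if given, write `melt_<condition>.csv` + truth sidecar.
#' @return list with `curves` (list of [melt_curve()]), `truth`, optional
#'   `paths`.
#' @export
gen_melt_curve <- function(seed = 1, tm = 52.0, width = 2, amplitude = 1,
                           t_range = c(20, 65), step = 0.5, noise_sd = 0,
                           baseline_intercept = 0, baseline_slope = 0,
                           replicates = 1, condition = "control",
                           dir = NULL) {
  k <- length(tm)
  width <- rep_len(width, k); amplitude <- rep_len(amplitude, k)
  if (any(tm <= t_range[1] | tm >= t_range[2]))
    stop("parameter error: every Tm must lie inside the temperature range",
         call. = FALSE)
  T <- seq(t_range[1], t_range[2], by = step)
  clean <- baseline_intercept + baseline_slope * T
  for (j in seq_len(k))
    clean <- clean + amplitude[j] / (1 + exp(-(T - tm[j]) / width[j]))
  curves <- withr::with_seed(seed, lapply(seq_len(replicates), function(r)
    melt_curve(T, clean + stats::rnorm(length(T), 0, noise_sd),
               condition = condition, replicate = r)))
  truth <- list(kind = "melt_curve", seed = seed, tm = tm, width = width,
                amplitude = amplitude, noise_sd = noise_sd,
                baseline_intercept = baseline_intercept,
                baseline_slope = baseline_slope, replicates = replicates,
                t_range = t_range, step = step, condition = condition)
  out <- list(curves = curves, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(dir, paste0("melt_", condition, ".csv"))
    tab <- do.call(rbind, lapply(curves, function(c)
      data.frame(temperature_C = c$temperature, signal = c$signal,
                 condition = c$condition, replicate = c$replicate)))
    utils::write.csv(tab, p, row.names = FALSE)
    out$paths <- c(data = p, truth = .write_truth(truth, p))
  }
  out
}

#' Generate a saturation-binding isotherm with counting noise
#'
#' Bound ligand follows the one-site hyperbola Bmax L / (Kd + L) on a
#' 2-fold serial dilution grid; bound amounts are converted to expected
#' scintillation counts through the specific activity and Poisson-sampled
#' (plus a constant background). A post-incubation condition is emitted as
#' `post_fraction` of the pre-condition curve.
#'
#' @param seed integer seed.
#' @param kd dissociation constant, micromolar.
#' @param bmax_uM saturating bound concentration, micromolar.
#' @param conc_uM free-ligand grid, micromolar (default 0.25-64, 2-fold).
#' @param replicates replicate counts per concentration.
#' @param sa a [specific_activity()] (default 125 mCi/mmol).
#' @param volume_uL counted volume.
#' @param background_cpm constant background counts.
#' @param poisson apply Poisson counting noise (FALSE gives the exact
#'   hyperbola).
#' @param post_fraction if non-NULL, also emit a post-incubation condition
#'   scaled to this fraction of the pre-condition curve.
#' @param tpm_dimer_uM coiled-coil dimer concentration (for stoichiometry).
#' @param dir if given, write `isotherm.csv` + truth sidecar.
#' @return list with `table` (conc_uM, counts_cpm, condition, replicate),
#'   `truth`, optional `paths`.
#' @export
gen_isotherm <- function(seed = 1, kd = 2, bmax_uM = 5,
                         conc_uM = 0.25 * 2^(0:8), replicates = 4,
                         sa = specific_activity(125), volume_uL = 25,
                         background_cpm = 30, poisson = TRUE,
                         post_fraction = NULL, tpm_dimer_uM = 5,
                         dir = NULL) {
  if (kd <= 0 || bmax_uM <= 0)
    stop("parameter error: Kd and Bmax must be positive", call. = FALSE)
  if (!length(conc_uM) || any(conc_uM < 0))
    stop("parameter error: invalid concentration grid", call. = FALSE)
  expected_cpm <- function(bound_uM) {
    amount_mmol <- bound_uM * volume_uL * 1e-9
    amount_mmol * sa$value * DPM_PER_MCI * sa$efficiency + background_cpm
  }
  conds <- list(pre_incubation = 1)
  if (!is.null(post_fraction)) conds$post_incubation <- post_fraction
  tab <- withr::with_seed(seed, do.call(rbind, lapply(names(conds), function(cn) {
    scale <- conds[[cn]]
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      mu <- expected_cpm(scale * bmax_uM * conc_uM / (kd + conc_uM))
      cpm <- if (poisson) stats::rpois(length(mu), mu) else mu
      data.frame(conc_uM = conc_uM, counts_cpm = cpm, condition = cn,
                 replicate = r)
    }))
  })))
  truth <- list(kind = "isotherm", seed = seed, kd = kd, bmax_uM = bmax_uM,
                conc_uM = conc_uM, replicates = replicates,
                sa_mCi_per_mmol = sa$value, efficiency = sa$efficiency,
                volume_uL = volume_uL, background_cpm = background_cpm,
                poisson = poisson, post_fraction = post_fraction,
                tpm_dimer_uM = tpm_dimer_uM)
  out <- list(table = tab, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(dir, "isotherm.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    out$paths <- c(data = p, truth = .write_truth(truth, p))
  }
  out
}

#' Build an [isotherm()] from a generated (or read) counts table
#'
#' Averages replicates per concentration, converts counts to bound
#' concentration through the specific activity and subtracts the constant
#' background.
#'
#' @param tab data.frame with `conc_uM`, `counts_cpm`, `condition`,
#'   `replicate`.
#' @param sa a [specific_activity()].
#' @param volume_uL counted volume.
#' @param background_cpm background subtracted before conversion.
#' @param condition which condition to extract.
#' @return an [isotherm()].
#' @export
isotherm_from_counts <- function(tab, sa, volume_uL, background_cpm = 0,
                                 condition = "pre_incubation") {
  sub <- tab[tab$condition == condition, ]
  if (!nrow(sub)) stop("condition '", condition, "' not present", call. = FALSE)
  agg <- stats::aggregate(counts_cpm ~ conc_uM, data = sub, FUN = mean)
  bound <- cpm_to_concentration(pmax(0, agg$counts_cpm - background_cpm),
                                sa, volume_uL)
  isotherm(agg$conc_uM, bound, condition = condition)
}
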