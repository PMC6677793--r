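#' Describe the overlap junction of a 4-helix bundle
#'
#' Names the two chains of the N-terminal coiled coil and the two chains of
#' the C-terminal coiled coil, together with the flanking residue windows
#' (author numbering) on each side of the junction used for axis fitting.
#' Flank windows shorter than 5 residues are rejected: the flank axis is a
#' total-least-squares line through per-residue axis points, and the bisector
#' construction consumes two residues per window end.
#'
#' @param nterm_chains,cterm_chains length-2 character vectors; the order
#'   within each pair fixes the sign of the inter-helix vector.
#' @param nterm_window,cterm_window inclusive residue ranges `c(start, end)`.
#' @param align_offsets optional named numeric per-chain numbering offsets
#'   (see [radius_profile()]).
#' @return a `junction_spec` object.
#' @export
junction_spec <- function(nterm_chains, cterm_chains,
                          nterm_window, cterm_window,
                          align_offsets = NULL) {
  if (length(nterm_chains) != 2 || length(cterm_chains) != 2)
    stop("junction spec error: each flank needs exactly 2 chains", call. = FALSE)
  for (w in list(nterm_window, cterm_window)) {
    if (length(w) != 2 || w[2] - w[1] + 1 < 5)
      stop("window error: flank windows must span >= 5 residues", call. = FALSE)
  }
  structure(list(nterm_chains = nterm_chains, cterm_chains = cterm_chains,
                 nterm_window = nterm_window, cterm_window = cterm_window,
                 align_offsets = align_offsets),
            class = "junction_spec")
}

## One flank: central-axis line direction (oriented by increasing residue
## number, i.e. C-to-N along the polymer for both flanks) plus the
## inter-helix vector at the reference residue nearest the junction.
.flank_geometry <- function(x, chains, window, model, align_offsets, ref_end) {
  missing_ch <- setdiff(chains, unique(x$atom$chain))
  if (length(missing_ch))
    stop("junction spec error: chain(s) ", paste(missing_ch, collapse = ","),
         " not in structure", call. = FALSE)
  traces <- .aligned_traces(x, chains, window, model, align_offsets)
  ctr <- .axis_points(central_axis(traces))
  if (nrow(ctr) < 3)
    stop("window error: flank yields fewer than 3 axis points", call. = FALSE)
  ln <- fit_line(ctr)
  dir <- ln$direction
  # orient along increasing residue number
  prog <- ctr[nrow(ctr), ] - ctr[1, ]
  if (sum(dir * prog) < 0) dir <- -dir
  ref_row <- if (ref_end == "last") nrow(ctr) else 1L
  v <- .axis_points(traces[[2]])[ref_row, ] - .axis_points(traces[[1]])[ref_row, ]
  list(direction = dir, inter_helix = v, center = ln$center, points = ctr)
}

#' Bend and twist of the overlap junction
#'
#' Measures, for one frame, the bending angle omega and the twisting angle
#' theta between the C-terminal and N-terminal coiled coils flanking the
#' junction. Per-residue helix axes (bisector construction) are averaged
#' into a central axis per flank and a straight total-least-squares line is
#' fitted to each; omega is the angle between the two flank directions
#' (both oriented by increasing residue number, i.e. C-to-N along the
#' polymer). Theta is the signed angle, about the overall central axis
#' (mean of the flank directions, oriented C-to-N), from the N-flank
#' inter-helix vector to the C-flank inter-helix vector; each inter-helix
#' vector (second minus first paired chain, at the flank residue nearest
#' the junction) is first carried into the plane perpendicular to the
#' overall axis by the minimal rotation taking its flank direction onto
#' the overall axis. A positive theta is a right-handed twist of the
#' C-terminal flank about the axis; omega is non-negative by construction.
#'
#' @param x a [cc_structure()].
#' @param junction a [junction_spec()].
#' @param model frame index.
#' @return list of class `overlap_geometry` with `theta` (degrees, signed,
#'   in (-180, 180]), `omega` (degrees, >= 0) and `frame`.
#' @export
overlap_angles <- function(x, junction, model = 1) {
  stopifnot(inherits(junction, "junction_spec"))
  nf <- .flank_geometry(x, junction$nterm_chains, junction$nterm_window,
                        model, junction$align_offsets, ref_end = "first")
  cf <- .flank_geometry(x, junction$cterm_chains, junction$cterm_window,
                        model, junction$align_offsets, ref_end = "last")

  omega <- angle_between(cf$direction, nf$direction)
  axis0 <- unit_vec(cf$direction + nf$direction)

  vc <- rotation_aligning(cf$direction, axis0) %*% cf$inter_helix
  vn <- rotation_aligning(nf$direction, axis0) %*% nf$inter_helix
  # remove any residual axial component, then signed angle about the axis
  vc <- vc - axis0 * sum(axis0 * vc)
  vn <- vn - axis0 * sum(axis0 * vn)
  theta <- signed_angle(as.vector(vn), as.vector(vc), axis0)

  structure(list(theta = theta, omega = omega, frame = model),
            class = "overlap_geometry")
}

#' @export
print.overlap_geometry <- function(x, ...) {
  cat(sprintf("overlap geometry (frame %d): theta %+.2f deg, omega %.2f deg\n",
              x$frame, x$theta, x$omega))
  invisible(x)
}

#' Bend/twist angles along a trajectory
#'
#' Computes theta and omega for every frame of a multi-model structure and
#' summarizes mean and SD over a frame window (default the last third,
#' the converged tail of a production run).
#'
#' @param x a multi-model [cc_structure()].
#' @param junction a [junction_spec()].
#' @param frame_window frames to compute (default all).
#' @param summary_window frames summarized (default `"last_third"`).
#' @return list with `series` (data.frame frame/theta/omega) and `summary`
#'   (data.frame quantity/mean/sd/n_frames).
#' @export
angle_time_series <- function(x, junction, frame_window = NULL,
                              summary_window = "last_third") {
  if (n_models(x) < 2)
    stop("trajectory error: need >= 2 frames", call. = FALSE)
  frames <- resolve_frame_window(frame_window, n_models(x))
  geo <- lapply(frames, function(m) overlap_angles(x, junction, m))
  series <- data.frame(frame = frames,
                       theta = vapply(geo, `[[`, numeric(1), "theta"),
                       omega = vapply(geo, `[[`, numeric(1), "omega"))
  sw <- resolve_frame_window(summary_window, length(frames))
  sub <- series[sw, ]
  summary <- data.frame(
    quantity = c("theta", "omega"),
    mean = c(mean(sub$theta), mean(sub$omega)),
    sd = c(stats::sd(sub$theta), stats::sd(sub$omega)),
    n_frames = nrow(sub))
  list(series = series, summary = summary)
}
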