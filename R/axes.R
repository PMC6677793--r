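#' Per-residue local helix axis from alpha-carbon coordinates
#'
#' Uses the three-point bisector construction: at each interior residue i the
#' unit bisector of the CA(i-1)-CA(i)-CA(i+1) angle points toward the local
#' helix axis. Two consecutive bisectors define the local axis direction; the
#' local helix radius r1 is solved by requiring that the displacement between
#' consecutive axis points be parallel to that direction. The axis point for
#' residue i is CA(i) + r1 * bisector(i). Terminal residues carry no axis
#' point.
#'
#' @param ca n x 3 matrix of consecutive alpha-carbon coordinates (may carry a
#'   `resno` attribute, propagated to the output).
#' @return data.frame with columns `index` (input row of the residue),
#'   `resno` (if available), `x`, `y`, `z` (axis point) and `r1` (local helix
#'   radius, Angstrom).
#' @export
fit_local_axes <- function(ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 4)
    stop("insufficient input: need >= 4 consecutive CA atoms, got ", n,
         call. = FALSE)
  resno <- attr(ca, "resno")

  # unit bisectors at interior residues 2..n-1
  bis <- matrix(NA_real_, n, 3)
  for (i in 2:(n - 1)) {
    u <- ca[i - 1, ] - ca[i, ]
    v <- ca[i + 1, ] - ca[i, ]
    if (vnorm(crossprod3(u, v)) / (vnorm(u) * vnorm(v)) < 1e-8)
      stop("degenerate geometry: collinear CA triple at position ", i,
           call. = FALSE)
    bis[i, ] <- unit_vec(unit_vec(u) + unit_vec(v))
  }

  # local radius from consecutive bisector pairs (i, i+1), i = 2..n-2
  r_pair <- rep(NA_real_, n)
  for (i in 2:(n - 2)) {
    b1 <- bis[i, ]; b2 <- bis[i + 1, ]
    ax <- crossprod3(b1, b2)
    if (vnorm(ax) < 1e-10) {
      # parallel bisectors (e.g. planar arc): axis direction from CA step
      ax <- crossprod3(b1, ca[i + 1, ] - ca[i, ])
      ax <- crossprod3(ax, b1)
    }
    u <- unit_vec(ax)
    d <- ca[i + 1, ] - ca[i, ]
    db <- b2 - b1
    pd <- d - u * sum(u * d)
    pdb <- db - u * sum(u * db)
    denom <- sum(pdb * pdb)
    r_pair[i] <- if (denom < 1e-12) 0 else -sum(pd * pdb) / denom
  }
  r <- r_pair
  r[n - 1] <- r_pair[n - 2]

  idx <- 2:(n - 1)
  pts <- ca[idx, , drop = FALSE] + bis[idx, , drop = FALSE] * r[idx]
  out <- data.frame(index = idx, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    r1 = r[idx])
  if (!is.null(resno)) out$resno <- resno[idx]
  out
}

.axis_points <- function(trace) as.matrix(trace[, c("x", "y", "z")])

#' Central axis of a helix bundle
#'
#' Averages per-residue axis points across member helices at each aligned
#' residue index. For a dimer this is the coiled-coil axis; for the 4-helix
#' overlap bundle it is the bundle axis.
#'
#' @param traces list of >= 2 axis traces from [fit_local_axes()], aligned
#'   row-by-row (equal row counts; align on `resno` upstream).
#' @return data.frame with columns `x`, `y`, `z` (and `resno` when all traces
#'   agree on it).
#' @export
central_axis <- function(traces) {
  if (!is.list(traces) || length(traces) < 2)
    stop("alignment error: central axis needs >= 2 helices", call. = FALSE)
  nr <- vapply(traces, nrow, integer(1))
  if (length(unique(nr)) != 1)
    stop("alignment error: axis traces have differing lengths (",
         paste(nr, collapse = ", "), ")", call. = FALSE)
  mats <- lapply(traces, .axis_points)
  ctr <- Reduce(`+`, mats) / length(mats)
  out <- data.frame(x = ctr[, 1], y = ctr[, 2], z = ctr[, 3])
  if (all(vapply(traces, function(t) !is.null(t$resno), logical(1)))) {
    rs <- sapply(traces, function(t) t$resno)
    if (is.matrix(rs) && all(rs == rs[, 1])) out$resno <- rs[, 1]
  }
  out
}

## Align the axis traces of several chains on residue number (minus per-chain
## offsets), returning the traces restricted to the common aligned indices.
.aligned_traces <- function(x, chains, range, model, align_offsets = NULL) {
  traces <- lapply(chains, function(ch) {
    ca <- select_coords(x, coord_selection(ch, range, "CA"), model)
    tr <- fit_local_axes(ca)
    off <- if (!is.null(align_offsets) && ch %in% names(align_offsets))
      align_offsets[[ch]] else 0
    tr$aligned <- tr$resno - off
    tr
  })
  common <- Reduce(intersect, lapply(traces, function(t) t$aligned))
  if (!length(common))
    stop("alignment error: no residues shared across chains after applying ",
         "offsets", call. = FALSE)
  lapply(traces, function(t) t[match(common, t$aligned), , drop = FALSE])
}

#' Per-residue coiled-coil radius profile
#'
#' For each aligned residue, the radius of a helix is the distance of its
#' local axis point from the bundle's central-axis point at that residue.
#' With a multi-frame structure the profile is averaged over the frame
#' window, reporting per-residue mean and SD.
#'
#' @param x a [cc_structure()].
#' @param chains character vector (>= 2) of member chain ids.
#' @param range inclusive residue range `c(start, end)` (applies per chain,
#'   before offsets).
#' @param frame_window integer vector of frame indices, or `"last_third"`,
#'   or `NULL` for all frames.
#' @param align_offsets optional named numeric: per-chain residue-numbering
#'   offset subtracted before aligning chains (for bundles whose chains use
#'   different author numbering).
#' @param per_helix if `TRUE`, report one radius column per chain instead of
#'   the helix-averaged radius.
#' @return data.frame with `aligned` residue index, per-chain `resno`, and
#'   either `radius` (+ `sd` for multi-frame) or per-chain columns.
#' @export
radius_profile <- function(x, chains, range, frame_window = NULL,
                           align_offsets = NULL, per_helix = FALSE) {
  if (length(chains) < 2)
    stop("radius profile needs >= 2 member chains", call. = FALSE)
  frames <- resolve_frame_window(frame_window, n_models(x))

  per_frame <- lapply(frames, function(m) {
    traces <- .aligned_traces(x, chains, range, m, align_offsets)
    ctr <- .axis_points(central_axis(traces))
    sapply(traces, function(t)
      sqrt(rowSums((.axis_points(t) - ctr)^2)))  # n_res x n_chains
  })
  traces1 <- .aligned_traces(x, chains, range, frames[1], align_offsets)
  aligned <- traces1[[1]]$aligned

  arr <- simplify2array(per_frame)  # n_res x n_chains x n_frames
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  out <- data.frame(aligned = aligned)
  for (i in seq_along(chains)) out[[paste0("resno_", chains[i])]] <-
    traces1[[i]]$resno
  if (per_helix) {
    for (i in seq_along(chains)) {
      out[[paste0("radius_", chains[i])]] <- apply(arr[, i, , drop = FALSE], 1, mean)
      if (length(frames) >= 2)
        out[[paste0("sd_", chains[i])]] <- apply(arr[, i, , drop = FALSE], 1, stats::sd)
    }
  } else {
    per_res <- apply(arr, c(1, 3), mean)     # average over chains
    if (is.null(dim(per_res))) per_res <- matrix(per_res, ncol = length(frames))
    out$radius <- rowMeans(per_res)
    if (length(frames) >= 2) out$sd <- apply(per_res, 1, stats::sd)
  }
  attr(out, "frames") <- frames
  out
}

#' Resolve a frame-window argument to frame indices
#'
#' `NULL` means all frames; `"last_third"` the final third (at least one
#' frame), mirroring summaries taken over the converged tail of a
#' trajectory; otherwise an integer vector of 1-based frame indices.
#'
#' @param frame_window window specifier.
#' @param n_frames total frames available.
#' @return integer vector of frame indices.
#' @export
resolve_frame_window <- function(frame_window, n_frames) {
  if (is.null(frame_window)) return(seq_len(n_frames))
  if (identical(frame_window, "last_third")) {
    k <- max(1L, floor(n_frames / 3))
    return(seq.int(n_frames - k + 1L, n_frames))
  }
  fw <- as.integer(frame_window)
  if (!length(fw)) stop("window error: empty frame window", call. = FALSE)
  if (any(fw < 1 | fw > n_frames))
    stop("window error: frame indices outside 1..", n_frames, call. = FALSE)
  fw
}
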