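#' Crick parameters for an ideal coiled coil
#'
#' Canonical parallel-dimer defaults: minor helix radius 2.26 A, rise
#' 1.495 A/residue, 3.5 residues per turn of the minor helix in the
#' superhelix-following frame (the heptad periodicity), superhelical radius
#' 4.9 A and a left-handed superhelix of 140 A pitch. These are textbook
#' values for a parallel two-stranded coiled coil, chosen as design defaults;
#' all are overridable.
#'
#' @param r0 superhelical radius, Angstrom (0 gives a straight helix).
#' @param r1 minor helix radius, Angstrom.
#' @param rise axial rise per residue, Angstrom.
#' @param residues_per_turn minor-helix periodicity, residues/turn.
#' @param pitch superhelical pitch, Angstrom.
#' @param phase minor-helix starting phase, degrees.
#' @param superhelix_left,minor_right handedness flags.
#' @param n_chains number of chains.
#' @param chain_offsets per-chain rotation about the superhelical axis,
#'   degrees; default evenly spaced (0/180 for a dimer).
#' @return a `crick_parameters` object.
#' @export
crick_parameters <- function(r0 = 4.9, r1 = 2.26, rise = 1.495,
                             residues_per_turn = 3.5, pitch = 140,
                             phase = 0, superhelix_left = TRUE,
                             minor_right = TRUE, n_chains = 2,
                             chain_offsets = NULL) {
  if (r0 < 0 || r1 <= 0 || rise <= 0 || pitch <= 0 || residues_per_turn <= 0)
    stop("invalid Crick parameters: radii, rise, pitch and periodicity must ",
         "be positive (r0 may be 0)", call. = FALSE)
  if (n_chains < 1) stop("n_chains must be >= 1", call. = FALSE)
  if (is.null(chain_offsets))
    chain_offsets <- seq(0, 360, length.out = n_chains + 1)[seq_len(n_chains)]
  if (length(chain_offsets) != n_chains)
    stop("chain_offsets length must equal n_chains", call. = FALSE)
  structure(list(r0 = r0, r1 = r1, rise = rise,
                 residues_per_turn = residues_per_turn, pitch = pitch,
                 phase = phase, superhelix_left = superhelix_left,
                 minor_right = minor_right, n_chains = n_chains,
                 chain_offsets = chain_offsets),
            class = "crick_parameters")
}

## CA trace for the reference chain (offset 0), n x 3
.crick_chain <- function(p, n_residues) {
  t <- seq_len(n_residues) - 1
  w1 <- (if (p$minor_right) 1 else -1) * 2 * pi / p$residues_per_turn
  ph1 <- w1 * t + deg2rad(p$phase)
  if (p$r0 == 0) {
    return(cbind(p$r1 * cos(ph1), p$r1 * sin(ph1), p$rise * t))
  }
  sh <- if (p$superhelix_left) -1 else 1
  w0 <- sh * 2 * pi * p$rise / p$pitch
  ph0 <- w0 * t
  alpha <- sh * atan(2 * pi * p$r0 / p$pitch)   # signed pitch angle
  x <- p$r0 * cos(ph0) +
    p$r1 * (cos(ph0) * cos(ph1) - cos(alpha) * sin(ph0) * sin(ph1))
  y <- p$r0 * sin(ph0) +
    p$r1 * (sin(ph0) * cos(ph1) + cos(alpha) * cos(ph0) * sin(ph1))
  z <- p$rise * t - p$r1 * sin(alpha) * sin(ph1)
  cbind(x, y, z)
}

#' Build an ideal coiled-coil CA backbone from Crick parameters
#'
#' Places alpha carbons on the Crick parametric curve (minor helix wound
#' around a superhelical path along +z); additional chains are copies of the
#' first rotated about the superhelical axis by their phase offsets, so a
#' 0/180 dimer has exact C2 symmetry. Parameter combinations giving
#' consecutive CA spacings outside 3.6-4.0 A are rejected as unphysical.
#'
#' @param params a [crick_parameters()].
#' @param n_residues residues per chain (>= 4).
#' @param chain_ids chain identifiers (default A, B, ...).
#' @param start_resno first residue number.
#' @param resid 3-letter residue name used for every residue.
#' @return a single-model [cc_structure()] with one CA atom per residue.
#' @export
build_ideal_coiled_coil <- function(params, n_residues,
                                    chain_ids = NULL, start_resno = 1,
                                    resid = "ALA") {
  stopifnot(inherits(params, "crick_parameters"))
  if (n_residues < 4) stop("need >= 4 residues per chain", call. = FALSE)
  if (is.null(chain_ids)) chain_ids <- LETTERS[seq_len(params$n_chains)]
  base <- .crick_chain(params, n_residues)
  spacings <- sqrt(rowSums(diff(base)^2))
  if (any(spacings < 3.6 | spacings > 4.0))
    stop(sprintf(paste0("geometry error: parameters imply CA spacing ",
                        "%.2f-%.2f A, outside 3.6-4.0 A"),
                 min(spacings), max(spacings)), call. = FALSE)
  chains <- list()
  for (i in seq_len(params$n_chains)) {
    co <- base %*% t(rotation_about(c(0, 0, 1), params$chain_offsets[i]))
    chains[[chain_ids[i]]] <- data.frame(
      resno = start_resno + seq_len(n_residues) - 1,
      resid = resid, elety = "CA",
      x = co[, 1], y = co[, 2], z = co[, 3])
  }
  structure_from_chains(chains, metadata = list(crick = unclass(params)))
}

#' Measure superhelical radius and rise of a coiled coil
#'
#' Round-trip companion to [build_ideal_coiled_coil()]: fits per-residue
#' local axes for each chain, averages them into the central axis, and
#' reports the mean distance of helix axis points from the central axis
#' (superhelical radius) and the mean per-residue advance of the central
#' axis along its overall direction (axial rise).
#'
#' @param x a [cc_structure()].
#' @param chains member chain ids (>= 2).
#' @param range residue range used.
#' @param model frame index.
#' @param align_offsets optional per-chain numbering offsets.
#' @return list with `r0` (Angstrom), `rise` (Angstrom/residue), and the
#'   per-residue `profile`.
#' @export
measure_coiled_coil <- function(x, chains, range, model = 1,
                                align_offsets = NULL) {
  prof <- radius_profile(x, chains, range, frame_window = model,
                         align_offsets = align_offsets)
  traces <- .aligned_traces(x, chains, range, model, align_offsets)
  ctr <- .axis_points(central_axis(traces))
  dir <- fit_line(ctr)$direction
  steps <- diff(ctr %*% dir)
  list(r0 = mean(prof$radius), rise = mean(abs(steps)), profile = prof)
}

#' Assemble a chimeric overlap model by fragment superposition
#'
#' Splices a fragment structure into a scaffold: the fragment's mapping
#' window is superposed (CA atoms, Kabsch) onto the scaffold's window, the
#' whole fragment is moved by that transform, and the scaffold's residues in
#' the window plus everything on the replaced side are substituted by the
#' fragment's, renumbered into the scaffold's author numbering. Scaffold
#' chains not named in the chain map are carried through unchanged, so
#' splicing a two-chain fragment into a 4-helix scaffold leaves a 4-chain
#' junction model. The window-fit RMSD is recorded in the metadata, with a
#' warning entry when it exceeds `rmsd_warn`.
#'
#' @param scaffold,fragment [cc_structure()] objects (single model).
#' @param scaffold_window,fragment_window inclusive residue ranges; must
#'   contain the same number of residues.
#' @param chain_map named character vector: names are fragment chain ids,
#'   values the scaffold chains they replace.
#' @param side which side of the scaffold window the fragment replaces
#'   (`"nterm"`: everything up to the window end; `"cterm"`: everything from
#'   the window start).
#' @param rmsd_warn window-fit RMSD (Angstrom) above which a warning is
#'   recorded.
#' @return spliced [cc_structure()]; metadata carries `window_rmsd`,
#'   `splice_distances` (CA-CA gap at each splice point) and the
#'   source-to-target numbering offset.
#' @export
assemble_overlap <- function(scaffold, fragment, scaffold_window,
                             fragment_window, chain_map, side = c("nterm", "cterm"),
                             rmsd_warn = 5) {
  side <- match.arg(side)
  len_s <- scaffold_window[2] - scaffold_window[1] + 1
  len_f <- fragment_window[2] - fragment_window[1] + 1
  if (len_s != len_f)
    stop("window length mismatch: fragment window has ", len_f,
         " residues, scaffold window ", len_s, call. = FALSE)

  frag_sel <- coord_selection(names(chain_map), fragment_window, "CA")
  scaf_sel <- coord_selection(unname(chain_map), scaffold_window, "CA")
  fit <- superpose(select_coords(fragment, frag_sel),
                   select_coords(scaffold, scaf_sel))
  fragment <- apply_superposition(fragment, fit)

  offset <- scaffold_window[1] - fragment_window[1]
  scaf_atom <- scaffold$atom
  scaf_xyz <- model_coords(scaffold, 1)
  frag_atom <- fragment$atom
  frag_xyz <- model_coords(fragment, 1)

  keep_rows <- list(); splice_gap <- numeric(0)
  for (sc in unique(scaf_atom$chain)) {
    rows <- which(scaf_atom$chain == sc)
    fc <- names(chain_map)[match(sc, chain_map)]
    if (is.na(fc)) {                      # chain untouched by the map
      keep_rows[[sc]] <- list(src = "scaffold", rows = rows, new_resno = scaf_atom$resno[rows])
      next
    }
    frows <- which(frag_atom$chain == fc)
    if (side == "nterm") {
      s_keep <- rows[scaf_atom$resno[rows] > scaffold_window[2]]
      f_keep <- frows[frag_atom$resno[frows] <= fragment_window[2]]
    } else {
      s_keep <- rows[scaf_atom$resno[rows] < scaffold_window[1]]
      f_keep <- frows[frag_atom$resno[frows] >= fragment_window[1]]
    }
    keep_rows[[paste0(sc, ".frag")]] <- list(src = "fragment", rows = f_keep,
                                             new_resno = frag_atom$resno[f_keep] + offset,
                                             chain = sc)
    keep_rows[[sc]] <- list(src = "scaffold", rows = s_keep,
                            new_resno = scaf_atom$resno[s_keep])
    # splice gap: CA at window edge vs adjacent scaffold CA
    edge_res <- if (side == "nterm") scaffold_window[2] else scaffold_window[1]
    nb_res <- if (side == "nterm") edge_res + 1 else edge_res - 1
    ca_f <- f_keep[frag_atom$elety[f_keep] == "CA" &
                   frag_atom$resno[f_keep] + offset == edge_res]
    ca_s <- rows[scaf_atom$elety[rows] == "CA" & scaf_atom$resno[rows] == nb_res]
    if (length(ca_f) == 1 && length(ca_s) == 1)
      splice_gap[sc] <- vnorm(frag_xyz[ca_f, ] - scaf_xyz[ca_s, ])
  }

  pieces <- lapply(names(keep_rows), function(k) {
    info <- keep_rows[[k]]
    if (!length(info$rows)) return(NULL)
    if (info$src == "scaffold") {
      df <- scaf_atom[info$rows, ]
      co <- scaf_xyz[info$rows, , drop = FALSE]
    } else {
      df <- frag_atom[info$rows, ]
      co <- frag_xyz[info$rows, , drop = FALSE]
      df$chain <- info$chain
    }
    df$resno <- info$new_resno
    cbind(df[, c("type", "elety", "resid", "chain", "resno")],
          x = co[, 1], y = co[, 2], z = co[, 3])
  })
  atom <- do.call(rbind, pieces)
  atom <- atom[order(match(atom$chain, unique(scaf_atom$chain)), atom$resno), ]
  atom$eleno <- seq_len(nrow(atom))
  atom$o <- 1; atom$b <- 0
  atom$elesy <- substr(trimws(atom$elety), 1, 1)
  xyz <- matrix(as.vector(t(as.matrix(atom[, c("x", "y", "z")]))), nrow = 1)

  md <- list(window_rmsd = fit$rmsd, numbering_offset = offset,
             splice_distances = splice_gap)
  if (fit$rmsd > rmsd_warn)
    md$warning <- sprintf("window-fit rmsd %.2f A exceeds %.1f A", fit$rmsd,
                          rmsd_warn)
  cc_structure(atom[, c("type", "eleno", "elety", "resid", "chain", "resno",
                        "o", "b", "elesy")], xyz, metadata = md)
}

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

#' Thread a target sequence onto a backbone
#'
#' Renames residues to the target sequence without moving any atom: residue
#' `register + i - 1` receives sequence letter `i`. Side-chain atoms beyond
#' CB are dropped (set `keep_cb = FALSE` to drop CB too); CB is removed on
#' glycine targets. Applies to every chain unless `chains` is given.
#'
#' @param x a [cc_structure()].
#' @param sequence one-letter amino-acid string.
#' @param register residue number receiving the first sequence letter.
#' @param chains chains to thread (default all protein chains).
#' @param keep_cb retain CB atoms where present.
#' @return threaded [cc_structure()]; metadata records the mapping.
#' @export
thread_sequence <- function(x, sequence, register = 1, chains = NULL,
                            keep_cb = TRUE) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters1, names(.aa3))
  if (length(bad))
    stop("alphabet error: non-standard residue letter(s) ",
         paste(unique(bad), collapse = ","), call. = FALSE)
  atom <- x$atom
  if (is.null(chains)) chains <- unique(atom$chain[atom$type == "ATOM"])
  span <- range(atom$resno[atom$type == "ATOM" & atom$chain %in% chains])
  covered <- seq(register, register + length(letters1) - 1)
  if (span[1] < covered[1] || span[2] > covered[length(covered)])
    stop("length error: backbone spans residues ", span[1], "-", span[2],
         " but sequence covers ", covered[1], "-", covered[length(covered)],
         call. = FALSE)
  keep_atoms <- c("N", "CA", "C", "O", if (keep_cb) "CB")
  sel <- atom$type == "ATOM" & atom$chain %in% chains
  drop <- sel & !(atom$elety %in% keep_atoms)
  new_resid <- atom$resid
  idx <- which(sel)
  new_resid[idx] <- .aa3[letters1[atom$resno[idx] - register + 1]]
  drop <- drop | (sel & atom$elety == "CB" & new_resid == "GLY")
  atom$resid <- new_resid
  keep <- which(!drop)
  xyz_cols <- as.vector(t(outer(keep, 1:3, function(i, j) 3 * (i - 1) + j)))
  out <- cc_structure(atom[keep, ], x$xyz[, xyz_cols, drop = FALSE],
                      metadata = c(x$metadata,
                                   list(threaded = list(register = register,
                                                        length = length(letters1)))))
  out
}

#' Extend a coiled coil with an ideal segment
#'
#' Builds an ideal coiled-coil segment from `params`, superposes its leading
#' (or trailing) 5 CA per chain onto the terminal 5 CA of the structure, and
#' splices the extra residues on with continuous numbering. Extension by 0
#' residues returns the input unchanged.
#'
#' @param x a [cc_structure()] (single model, CA trace).
#' @param params [crick_parameters()] for the new segment.
#' @param n_extra residues to add per chain.
#' @param end `"cterm"` or `"nterm"`.
#' @param chains chains to extend (default all, in structure order).
#' @return extended [cc_structure()].
#' @export
extend_termini <- function(x, params, n_extra, end = c("cterm", "nterm"),
                           chains = NULL) {
  end <- match.arg(end)
  if (n_extra == 0) return(x)
  atom <- x$atom
  if (is.null(chains)) chains <- unique(atom$chain[atom$type == "ATOM"])
  res_by_chain <- lapply(chains, function(ch)
    sort(unique(atom$resno[atom$chain == ch & atom$type == "ATOM"])))
  if (any(vapply(res_by_chain, length, integer(1)) < 5))
    stop("need >= 5 terminal residues per chain to establish the frame",
         call. = FALSE)

  # advance the minor-helix phase so the segment continues the body's helix:
  # superhelical phase and position are absorbed by the rigid anchor fit,
  # but the minor phase is not
  n_body <- length(res_by_chain[[1]])
  w1_deg <- (if (params$minor_right) 1 else -1) * 360 / params$residues_per_turn
  t_anchor <- if (end == "cterm") n_body - 5 else 0
  seg_anchor_idx <- if (end == "cterm") 0 else n_extra
  params$phase <- params$phase + w1_deg * (t_anchor - seg_anchor_idx)
  seg <- build_ideal_coiled_coil(params, n_extra + 5L, chain_ids = chains)
  # anchor: terminal 5 residues of x; matching end of the segment
  anchor_res <- lapply(res_by_chain, function(r)
    if (end == "cterm") utils::tail(r, 5) else utils::head(r, 5))
  seg_res <- sort(unique(seg$atom$resno))
  seg_anchor <- if (end == "cterm") utils::head(seg_res, 5) else utils::tail(seg_res, 5)

  anchor_xyz <- do.call(rbind, lapply(seq_along(chains), function(i)
    select_coords(x, coord_selection(chains[i], range(anchor_res[[i]]), "CA"))))
  seg_anchor_xyz <- do.call(rbind, lapply(chains, function(ch)
    select_coords(seg, coord_selection(ch, range(seg_anchor), "CA"))))
  fit <- superpose(seg_anchor_xyz, anchor_xyz)
  seg <- apply_superposition(seg, fit)

  new_res <- setdiff(seg_res, seg_anchor)
  seg_xyz <- model_coords(seg, 1)
  x_xyz <- model_coords(x, 1)
  keep_new <- seg$atom$resno %in% new_res
  old_ca <- which(atom$elety == "CA")
  dmin <- min(apply(seg_xyz[keep_new & seg$atom$elety == "CA", , drop = FALSE],
                    1, function(p) min(sqrt(rowSums(sweep(
                      x_xyz[old_ca, , drop = FALSE], 2, p)^2)))))
  if (dmin < 2.5)
    stop(sprintf("clash error: extension CA within %.2f A of existing CA", dmin),
         call. = FALSE)

  pieces <- list(cbind(atom[, c("type", "elety", "resid", "chain", "resno")],
                       x = x_xyz[, 1], y = x_xyz[, 2], z = x_xyz[, 3]))
  for (i in seq_along(chains)) {
    ch <- chains[i]
    rows <- which(seg$atom$chain == ch & seg$atom$resno %in% new_res)
    df <- seg$atom[rows, c("type", "elety", "resid", "chain", "resno")]
    r <- res_by_chain[[i]]
    k <- rank(seg$atom$resno[rows])
    df$resno <- if (end == "cterm") max(r) + k else min(r) - (length(new_res) - k + 1)
    co <- seg_xyz[rows, , drop = FALSE]
    pieces[[length(pieces) + 1]] <- cbind(df, x = co[, 1], y = co[, 2], z = co[, 3])
  }
  atom_all <- do.call(rbind, pieces)
  atom_all <- atom_all[order(match(atom_all$chain, unique(atom$chain)),
                             atom_all$resno), ]
  atom_all$eleno <- seq_len(nrow(atom_all))
  atom_all$o <- 1; atom_all$b <- 0
  atom_all$elesy <- substr(trimws(atom_all$elety), 1, 1)
  xyz <- matrix(as.vector(t(as.matrix(atom_all[, c("x", "y", "z")]))), nrow = 1)
  cc_structure(atom_all[, c("type", "eleno", "elety", "resid", "chain",
                            "resno", "o", "b", "elesy")], xyz,
               metadata = c(x$metadata, list(extended = list(end = end, n = n_extra))))
}
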