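#' Structures with one or more coordinate frames
#'
#' A `cc_structure` holds a PDB-style atom table together with a coordinate
#' matrix carrying one row per model (frame), so that a multi-MODEL PDB file
#' can stand in for a trajectory. The atom table fixes the topology, which is
#' therefore identical across frames by construction.
#'
#' @param atom data.frame with columns `type` ("ATOM"/"HETATM"), `eleno`,
#'   `elety` (atom name), `resid` (3-letter residue), `chain`, `resno`
#'   (author numbering), `o`, `b`, `elesy` (element symbol).
#' @param xyz numeric matrix, `n_models` rows by `3 * n_atoms` columns, in
#'   Angstrom, ordered x1,y1,z1,x2,...
#' @param metadata free-form provenance list.
#' @return object of class `cc_structure`.
#' @export
cc_structure <- function(atom, xyz, metadata = list()) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  stopifnot(is.data.frame(atom), is.matrix(xyz))
  needed <- c("type", "elety", "resid", "chain", "resno")
  missing_cols <- setdiff(needed, names(atom))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (ncol(xyz) != 3 * nrow(atom))
    stop("coordinate matrix width (", ncol(xyz), ") does not match 3 x ",
         nrow(atom), " atoms", call. = FALSE)
  if (nrow(xyz) < 1) stop("structure needs at least one model", call. = FALSE)
  if (!all(is.finite(xyz))) stop("coordinates must be finite", call. = FALSE)
  if (any(!nzchar(atom$elety))) stop("atom names must be non-empty", call. = FALSE)
  if (is.null(atom$eleno)) atom$eleno <- seq_len(nrow(atom))
  if (is.null(atom$o)) atom$o <- 1
  if (is.null(atom$b)) atom$b <- 0
  if (is.null(atom$elesy)) atom$elesy <- substr(trimws(atom$elety), 1, 1)
  structure(list(atom = atom, xyz = xyz, metadata = metadata),
            class = "cc_structure")
}

#' @export
print.cc_structure <- function(x, ...) {
  cat("cc_structure:", n_models(x), "model(s),",
      length(unique(x$atom$chain)), "chain(s),", nrow(x$atom), "atoms\n")
  invisible(x)
}

#' Number of models (frames) in a structure
#' @param x a `cc_structure`.
#' @return integer frame count.
#' @export
n_models <- function(x) nrow(x$xyz)

#' Coordinates of one model as an n_atoms x 3 matrix
#' @param x a `cc_structure`.
#' @param model 1-based frame index.
#' @return numeric matrix with columns x, y, z.
#' @export
model_coords <- function(x, model = 1) {
  if (model < 1 || model > n_models(x))
    stop("model index ", model, " out of range 1..", n_models(x), call. = FALSE)
  matrix(x$xyz[model, ], ncol = 3, byrow = TRUE)
}

#' Replace coordinates of one model
#' @inheritParams model_coords
#' @param coords n_atoms x 3 matrix.
#' @return the modified structure.
#' @export
set_model_coords <- function(x, coords, model = 1) {
  stopifnot(nrow(coords) == nrow(x$atom), ncol(coords) == 3)
  x$xyz[model, ] <- as.vector(t(coords))
  x
}

#' Read a PDB file into a `cc_structure`
#'
#' Parsing is delegated to [bio3d::read.pdb()]; MODEL records become frames.
#' Author residue numbering is preserved. Alternate locations are reduced to
#' one atom per name (highest occupancy, ties broken alphabetically by altloc
#' id); insertion codes are not supported and raise an error.
#'
#' @param path PDB file path.
#' @return a [cc_structure()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty PDB file: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse failure for ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  atom <- pdb$atom
  if (nrow(atom) == 0) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)

  ins <- atom$insert
  if (!is.null(ins) && any(!is.na(ins) & nzchar(ins)))
    stop("insertion codes are not supported (found in ", path, ")",
         call. = FALSE)

  # altloc reduction: keep highest occupancy, then alphabetic altloc id
  alt <- atom$alt
  if (!is.null(alt) && any(!is.na(alt) & nzchar(alt))) {
    alt[is.na(alt)] <- ""
    key <- paste(atom$chain, atom$resno, atom$elety, sep = "|")
    occ <- ifelse(is.na(atom$o), 1, atom$o)
    ord <- order(key, -occ, alt)
    keep_first <- !duplicated(key[ord])
    keep <- sort(ord[keep_first])
    atom <- atom[keep, , drop = FALSE]
    xyz <- xyz[, as.vector(t(outer(keep, 1:3, function(i, j) 3 * (i - 1) + j))),
               drop = FALSE]
  }
  atom$chain[is.na(atom$chain)] <- " "
  cc_structure(atom[, c("type", "eleno", "elety", "resid", "chain", "resno",
                        "o", "b", "elesy")],
               xyz, metadata = list(source = path))
}

#' Write a `cc_structure` to a PDB file
#'
#' Multi-model structures are written with MODEL/ENDMDL records; coordinates
#' are fixed-column at 3 decimals, via [bio3d::write.pdb()].
#'
#' @param x a [cc_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "cc_structure"))
  if (any(abs(x$xyz) >= 10000))
    stop("coordinate exceeds PDB fixed-column width (|x| >= 10000 A)",
         call. = FALSE)
  xyz <- if (n_models(x) == 1) as.vector(x$xyz) else x$xyz
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = x$atom$type, resno = x$atom$resno,
                   resid = x$atom$resid, eleno = x$atom$eleno,
                   elety = x$atom$elety, chain = x$atom$chain,
                   o = x$atom$o, b = x$atom$b, elesy = x$atom$elesy)
  # bio3d omits TER records; delimit chains explicitly
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  ch <- ifelse(is_atom, substr(lines, 22, 22), NA)
  out <- character(0)
  for (i in seq_along(lines)) {
    out <- c(out, lines[i])
    if (is_atom[i] &&
        (i == length(lines) || !is_atom[i + 1] || ch[i + 1] != ch[i]))
      out <- c(out, "TER")
  }
  writeLines(out, path)
  invisible(path)
}

#' Describe an atom selection
#'
#' @param chains character vector of chain ids, in the order coordinates
#'   should be returned.
#' @param range length-2 integer vector, inclusive author-numbering residue
#'   range `c(start, end)`.
#' @param atoms `"CA"`, `"backbone"` (N, CA, C, O), `"heavy"` (all non-H), or
#'   a character vector of atom names.
#' @return a `coord_selection` object.
#' @export
coord_selection <- function(chains, range, atoms = "CA") {
  stopifnot(length(range) == 2)
  if (range[1] > range[2]) stop("selection range start > end", call. = FALSE)
  structure(list(chains = chains, range = as.integer(range), atoms = atoms),
            class = "coord_selection")
}

.selection_atoms <- function(atoms) {
  if (identical(atoms, "CA")) return(c("CA"))
  if (identical(atoms, "backbone")) return(c("N", "CA", "C", "O"))
  if (identical(atoms, "heavy")) return(NULL)  # all non-hydrogen
  atoms
}

#' Extract ordered coordinates for a selection
#'
#' Coordinates are ordered by the chain order given in the selection, then by
#' residue number, then by canonical atom-name order (N, CA, C, O, CB, rest
#' alphabetical). By default a residue inside the range that lacks one of the
#' requested atoms is an error; `on_missing = "skip"` drops such residues
#' (useful when terminal residues are absent from a model).
#'
#' @param x a [cc_structure()].
#' @param sel a [coord_selection()].
#' @param model frame index (default 1).
#' @param on_missing `"error"` or `"skip"`.
#' @return n x 3 coordinate matrix with attributes `chain`, `resno`, `elety`.
#' @export
select_coords <- function(x, sel, model = 1, on_missing = c("error", "skip")) {
  stopifnot(inherits(x, "cc_structure"), inherits(sel, "coord_selection"))
  on_missing <- match.arg(on_missing)
  atom <- x$atom
  coords <- model_coords(x, model)
  names_wanted <- .selection_atoms(sel$atoms)

  rows_all <- integer(0)
  for (ch in sel$chains) {
    in_ch <- which(atom$chain == ch & atom$type == "ATOM")
    if (!length(in_ch))
      stop("selection error: chain '", ch, "' not present", call. = FALSE)
    in_rng <- in_ch[atom$resno[in_ch] >= sel$range[1] &
                    atom$resno[in_ch] <= sel$range[2]]
    if (!length(in_rng))
      stop("selection error: chain '", ch, "' has no residues in range ",
           sel$range[1], "-", sel$range[2], call. = FALSE)
    if (is.null(names_wanted)) {
      in_sel <- in_rng[atom$elesy[in_rng] != "H"]
    } else {
      in_sel <- in_rng[atom$elety[in_rng] %in% names_wanted]
    }
    # per-residue completeness check
    resnos <- sort(unique(atom$resno[in_rng]))
    keep_res <- resnos
    if (!is.null(names_wanted)) {
      have <- split(atom$elety[in_sel], atom$resno[in_sel])
      complete <- vapply(as.character(resnos), function(r) {
        a <- have[[r]]
        !is.null(a) && all(names_wanted %in% a)
      }, logical(1))
      if (!all(complete)) {
        if (on_missing == "error")
          stop("selection error: chain '", ch, "' residues ",
               paste(resnos[!complete], collapse = ","),
               " lack requested atoms (", paste(names_wanted, collapse = ","),
               ")", call. = FALSE)
        keep_res <- resnos[complete]
      }
      in_sel <- in_sel[atom$resno[in_sel] %in% keep_res]
    }
    if (!length(in_sel))
      stop("selection error: no atoms resolved on chain '", ch, "' in range ",
           sel$range[1], "-", sel$range[2], call. = FALSE)
    sub <- atom[in_sel, ]
    canon <- c("N", "CA", "C", "O", "CB")
    rk <- match(sub$elety, canon)
    rk[is.na(rk)] <- length(canon) + 1
    ord <- in_sel[order(sub$resno, rk, sub$elety)]
    rows_all <- c(rows_all, ord)
  }
  out <- coords[rows_all, , drop = FALSE]
  attr(out, "chain") <- atom$chain[rows_all]
  attr(out, "resno") <- atom$resno[rows_all]
  attr(out, "elety") <- atom$elety[rows_all]
  out
}

#' Assemble a single-model structure from per-chain atom tables
#'
#' Convenience constructor used by the backbone builder and the generators.
#'
#' @param chains named list (names = chain ids); each element a data.frame
#'   with columns `resno`, `resid`, `elety`, `x`, `y`, `z` (and optionally
#'   `type`).
#' @param metadata provenance list.
#' @return a [cc_structure()].
#' @export
structure_from_chains <- function(chains, metadata = list()) {
  stopifnot(length(chains) >= 1, !is.null(names(chains)))
  tabs <- lapply(names(chains), function(id) {
    df <- chains[[id]]
    df$chain <- id
    if (is.null(df$type)) df$type <- "ATOM"
    df
  })
  atom <- do.call(rbind, tabs)
  atom$eleno <- seq_len(nrow(atom))
  atom$o <- 1
  atom$b <- 0
  atom$elesy <- substr(trimws(atom$elety), 1, 1)
  xyz <- matrix(as.vector(t(as.matrix(atom[, c("x", "y", "z")]))), nrow = 1)
  cc_structure(atom[, c("type", "eleno", "elety", "resid", "chain", "resno",
                        "o", "b", "elesy")], xyz, metadata)
}

#' Stack single-model structures with identical topology into a trajectory
#' @param frames list of single-model `cc_structure`s sharing one topology.
#' @param metadata provenance list.
#' @return multi-model [cc_structure()].
#' @export
structures_to_trajectory <- function(frames, metadata = list()) {
  stopifnot(length(frames) >= 1)
  ref <- frames[[1]]$atom
  for (f in frames[-1]) {
    same <- identical(f$atom[, c("type", "elety", "resid", "chain", "resno")],
                      ref[, c("type", "elety", "resid", "chain", "resno")])
    if (!same) stop("trajectory error: frames differ in topology", call. = FALSE)
  }
  xyz <- do.call(rbind, lapply(frames, function(f) f$xyz))
  cc_structure(ref, xyz, metadata)
}
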