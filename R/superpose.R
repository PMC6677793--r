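#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired point sets, by SVD of the cross-covariance matrix with the usual
#' sign correction that forbids reflections.
#'
#' @param mobile n x 3 matrix moved onto `reference`.
#' @param reference n x 3 matrix.
#' @return list of class `superposition_result` with `rotation` (3 x 3,
#'   det +1), `translation` (applied after rotation), `rmsd` (Angstrom),
#'   `n_atoms`, and `fitted` (transformed mobile coordinates).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3)
    stop("coordinate sets must be n x 3 matrices", call. = FALSE)
  if (nrow(mobile) != nrow(reference))
    stop("pairing error: ", nrow(mobile), " vs ", nrow(reference), " points",
         call. = FALSE)
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 paired points", call. = FALSE)

  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- sweep(P %*% t(R), 2, -cr)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  trans <- as.vector(cr - R %*% cm)
  structure(list(rotation = R, translation = trans, rmsd = rmsd,
                 n_atoms = n, fitted = fitted),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition over %d atoms: rmsd %.3f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition to a whole structure
#'
#' @param x a [cc_structure()].
#' @param fit a `superposition_result` from [superpose()].
#' @param model frame to transform (default all frames).
#' @return the transformed structure.
#' @export
apply_superposition <- function(x, fit, model = NULL) {
  models <- if (is.null(model)) seq_len(n_models(x)) else model
  for (m in models) {
    co <- model_coords(x, m)
    x <- set_model_coords(x, sweep(co %*% t(fit$rotation), 2, -fit$translation), m)
  }
  x
}

#' Range-restricted RMSD between two structures
#'
#' Convenience wrapper: selects matching atoms on both structures via
#' [coord_selection()] specs and reports the Kabsch-fit RMSD, as used for
#' comparisons like backbone residues 12-74 between two coiled-coil crystal
#' structures.
#'
#' @param mobile,reference [cc_structure()] objects.
#' @param mobile_sel,reference_sel [coord_selection()] for each structure;
#'   `reference_sel` defaults to `mobile_sel`.
#' @param model_mobile,model_reference frame indices.
#' @param on_missing passed to [select_coords()].
#' @return a `superposition_result`.
#' @export
#' Best RMSD over candidate chain pairings
#'
#' Crystal structures of coiled-coil fragments often contain several
#' equivalent chains with arbitrary labels (e.g. four chains forming two
#' coiled coils). This helper superposes every ordered pair of mobile
#' chains onto a fixed reference chain pair over a residue range, pairing
#' only residues present (with complete requested atoms) in both
#' structures, and returns the best fit.
#'
#' @param mobile,reference [cc_structure()] objects.
#' @param range inclusive residue range `c(start, end)` (author numbering,
#'   assumed comparable between the structures).
#' @param atoms atom set as in [coord_selection()].
#' @param reference_chains length-2 chain pair on the reference (default:
#'   first two protein chains).
#' @param mobile_chains candidate chains on the mobile structure (default:
#'   all protein chains; every ordered pair is tried).
#' @return list with `rmsd`, `n_atoms`, `mobile_chains`, `reference_chains`
#'   for the best pairing, plus `all` (data.frame of every pairing tried).
#' @export
best_pairing_rmsd <- function(mobile, reference, range, atoms = "backbone",
                              reference_chains = NULL, mobile_chains = NULL) {
  prot_chains <- function(x) unique(x$atom$chain[x$atom$type == "ATOM"])
  if (is.null(reference_chains))
    reference_chains <- utils::head(prot_chains(reference), 2)
  if (is.null(mobile_chains)) mobile_chains <- prot_chains(mobile)
  stopifnot(length(reference_chains) == 2)

  chain_coords <- function(x, ch) {
    co <- tryCatch(
      select_coords(x, coord_selection(ch, range, atoms), on_missing = "skip"),
      error = function(e) NULL)
    co
  }
  ref_co <- lapply(reference_chains, chain_coords, x = reference)
  if (any(vapply(ref_co, is.null, logical(1))))
    stop("reference chains do not resolve in range ", range[1], "-", range[2],
         call. = FALSE)

  pair_coords <- function(mob_co, ref_co) {
    # restrict both to residues carried by both selections
    common <- intersect(unique(attr(mob_co, "resno")),
                        unique(attr(ref_co, "resno")))
    if (length(common) < 3) return(NULL)
    pick <- function(co) {
      keep <- attr(co, "resno") %in% common
      co[keep, , drop = FALSE]
    }
    list(mob = pick(mob_co), ref = pick(ref_co))
  }

  results <- list()
  for (c1 in mobile_chains) for (c2 in setdiff(mobile_chains, c1)) {
    m1 <- chain_coords(mobile, c1); m2 <- chain_coords(mobile, c2)
    if (is.null(m1) || is.null(m2)) next
    p1 <- pair_coords(m1, ref_co[[1]]); p2 <- pair_coords(m2, ref_co[[2]])
    if (is.null(p1) || is.null(p2)) next
    fit <- superpose(rbind(p1$mob, p2$mob), rbind(p1$ref, p2$ref))
    results[[paste(c1, c2)]] <- data.frame(
      chain1 = c1, chain2 = c2, rmsd = fit$rmsd, n_atoms = fit$n_atoms)
  }
  if (!length(results))
    stop("no chain pairing resolves the requested range in both structures",
         call. = FALSE)
  all <- do.call(rbind, results)
  best <- all[which.min(all$rmsd), ]
  list(rmsd = best$rmsd, n_atoms = best$n_atoms,
       mobile_chains = c(best$chain1, best$chain2),
       reference_chains = reference_chains, all = all)
}

rmsd_between <- function(mobile, reference, mobile_sel,
                         reference_sel = mobile_sel,
                         model_mobile = 1, model_reference = 1,
                         on_missing = "error") {
  a <- select_coords(mobile, mobile_sel, model_mobile, on_missing)
  b <- select_coords(reference, reference_sel, model_reference, on_missing)
  if (nrow(a) != nrow(b))
    stop("pairing error: selections resolve to ", nrow(a), " vs ", nrow(b),
         " atoms", call. = FALSE)
  superpose(a, b)
}
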