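## Rigid-body superposition (Kabsch, proper rotations only: molecular
## chirality must be preserved) and the three-tier RMSD report used for
## comparing CDN conformers: all heavy atoms / 12-atom macrocyclic backbone /
## nucleobase heavy atoms.

#' Optimal rigid superposition of two point sets
#'
#' Least-squares rigid transform (rotation + translation, reflections
#' excluded) of `B` onto `A` by the Kabsch/SVD construction, and the RMSD
#' after transformation.
#'
#' @param A,B `n x 3` coordinate matrices with corresponding rows, `n >= 3`,
#'   not all collinear.
#' @return List with `rotation` (3 x 3, `det = +1`), `translation` (length
#'   3; the transform is `B %*% t(rotation) + translation`), `rmsd`
#'   (Angstrom) and `B_transformed`.
#' @examples
#' A <- matrix(rnorm(15), 5, 3)
#' superpose(A, A)$rmsd  # 0
#' @export
superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3) {
    stop("'A' and 'B' must be n x 3 matrices of equal size", call. = FALSE)
  }
  n <- nrow(A)
  if (n < 3) stop("need at least 3 points to superpose", call. = FALSE)
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  if (min(svd(A0)$d) < 1e-10 * max(svd(A0)$d, 1)) {
    stop("degenerate (collinear) reference points", call. = FALSE)
  }
  H <- crossprod(B0, A0)           # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))   # exclude reflections
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  Bt <- B0 %*% t(R)
  rmsd <- sqrt(sum((Bt - A0)^2) / n)
  list(rotation = R, translation = as.numeric(cA - cB %*% t(R)),
       rmsd = rmsd, B_transformed = sweep(Bt, 2, cA, `+`))
}

## resolve a tier's atom indices in an atoms table; heavy atoms only
macrocycle_atoms <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
base_atom_names <- c("N1", "C2", "N3", "C4", "C5", "C6", "N6", "O6",
                     "N7", "C8", "N9", "N2", "N4", "O2", "O4")

resolve_tier <- function(atoms, tier = c("overall", "macrocycle", "base")) {
  tier <- match.arg(tier)
  heavy <- !grepl("^H", atoms$atom_name)
  idx <- switch(tier,
    overall = which(heavy),
    macrocycle = which(atoms$atom_name %in% macrocycle_atoms),
    base = which(atoms$atom_name %in% base_atom_names)
  )
  if (tier == "macrocycle") {
    per_res <- table(atoms$res_id[idx])
    if (length(idx) != 12 || length(per_res) != 2 || any(per_res != 6)) {
      have <- split(atoms$atom_name[idx], atoms$res_id[idx])
      missing <- vapply(unique(atoms$res_id), function(r) {
        paste(setdiff(macrocycle_atoms,
                      atoms$atom_name[atoms$res_id == r]), collapse = ",")
      }, character(1))
      stop("macrocycle tier must resolve exactly 12 atoms (P, O5', C5', ",
           "C4', C3', O3' in each of two residues); missing per residue: ",
           paste(sprintf("res %s: [%s]", unique(atoms$res_id), missing),
                 collapse = "; "), call. = FALSE)
    }
  }
  if (length(idx) == 0) {
    stop("tier '", tier, "' resolves no atoms", call. = FALSE)
  }
  idx
}

## match atoms of B to A by (residue order position, atom name)
match_atoms <- function(atoms_A, atoms_B, idx_A, pairing = NULL) {
  ra <- atoms_A$res_id[idx_A]
  if (is.null(pairing)) {
    ua <- unique(atoms_A$res_id); ub <- unique(atoms_B$res_id)
    if (length(ua) != length(ub)) {
      stop("ambiguous residue pairing (", length(ua), " vs ", length(ub),
           " residues); supply 'pairing' explicitly", call. = FALSE)
    }
    pairing <- stats::setNames(ub, ua)
  }
  keyB <- paste(atoms_B$res_id, atoms_B$atom_name)
  idx_B <- match(paste(pairing[as.character(ra)],
                       atoms_A$atom_name[idx_A]), keyB)
  if (anyNA(idx_B)) {
    miss <- which(is.na(idx_B))
    stop("atoms unresolvable in second conformer: ",
         paste(sprintf("%s/%s", pairing[as.character(ra[miss])],
                       atoms_A$atom_name[idx_A][miss]), collapse = ", "),
         call. = FALSE)
  }
  idx_B
}

#' Three-tier RMSD report between two CDN conformers
#'
#' For each tier (`overall` = all heavy atoms, `macrocycle` = the 12
#' sugar-phosphate ring atoms, `base` = nucleobase heavy atoms) the two
#' conformers are superposed on that tier's atoms and the RMSD after
#' superposition is reported.  Atom correspondence is established by
#' (residue pairing, atom name).
#'
#' @param A,B single-frame [conformer_ensemble()] objects (frame 1 is used),
#'   or lists with `frames`/`atoms`.
#' @param pairing optional named vector mapping residue ids of `A` to
#'   residue ids of `B` (required when automatic pairing is ambiguous, e.g.
#'   mixed-base c-GAMP against a homodimer).
#' @return Object of class `"rmsd_report"`: list with `overall_rmsd`,
#'   `macrocycle_rmsd`, `base_rmsd` (Angstrom) and `superpositions`.
#' @export
cdn_rmsd_report <- function(A, B, pairing = NULL) {
  tiers <- c("overall", "macrocycle", "base")
  sups <- lapply(tiers, function(tier) {
    ia <- resolve_tier(A$atoms, tier)
    ib <- match_atoms(A$atoms, B$atoms, ia, pairing)
    superpose(A$frames[[1]][ia, , drop = FALSE],
              B$frames[[1]][ib, , drop = FALSE])
  })
  names(sups) <- tiers
  structure(list(overall_rmsd = sups$overall$rmsd,
                 macrocycle_rmsd = sups$macrocycle$rmsd,
                 base_rmsd = sups$base$rmsd,
                 superpositions = sups),
            class = "rmsd_report")
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat(sprintf(
    "<rmsd_report> overall %.3f A | macrocycle %.3f A | base %.3f A\n",
    x$overall_rmsd, x$macrocycle_rmsd, x$base_rmsd))
  invisible(x)
}

#' Pairwise RMSD matrix over ensemble frames
#'
#' @param e a [conformer_ensemble()] with at least 2 frames.
#' @param tier atom selection tier (see [cdn_rmsd_report()]).
#' @return Symmetric matrix of RMSDs (Angstrom) with zero diagonal.
#' @export
pairwise_matrix <- function(e, tier = c("overall", "macrocycle", "base")) {
  tier <- match.arg(tier)
  stopifnot(inherits(e, "conformer_ensemble"))
  nf <- length(e$frames)
  if (nf < 2) stop("need at least 2 frames", call. = FALSE)
  idx <- resolve_tier(e$atoms, tier)
  M <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      r <- superpose(e$frames[[i]][idx, , drop = FALSE],
                     e$frames[[j]][idx, , drop = FALSE])$rmsd
      M[i, j] <- M[j, i] <- r
    }
  }
  M
}
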