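## Idealized macrocycle template builder: sequential internal-coordinate
## (NeRF) construction of a two-nucleotide CDN-like fragment with specified
## torsions, ideal bond lengths/angles, and NO ring closure (neither the
## 12-membered macrocycle nor the furanose ring is closed by construction;
## this is a test fixture generator, not a model builder).

## place atom D given A, B, C, bond |CD|, angle B-C-D and torsion A-B-C-D
nerf_place <- function(A, B, C, bond, angle, torsion) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

## ideal internal coordinates (Angstrom / degrees)
ideal_bonds <- c("P-O5'" = 1.59, "O5'-C5'" = 1.44, "C5'-C4'" = 1.51,
                 "C4'-C3'" = 1.53, "C3'-O3'" = 1.42, "O3'-P" = 1.61,
                 "C4'-O4'" = 1.45, "O4'-C1'" = 1.41, "C1'-C2'" = 1.53,
                 "C1'-N" = 1.47, "N-C" = 1.37)
ideal_angle <- 109.5   # generic sp3; base angles use 126

#' Build an idealized two-residue macrocycle template frame
#'
#' Constructs coordinates for a CDN-like fragment (two nucleotide units:
#' sugar-phosphate backbone, furanose ring atoms `O4'`, `C1'`, `C2'`, and a
#' three-atom base stub) by sequential internal-coordinate placement with
#' ideal bond lengths and tetrahedral angles, realizing the requested
#' torsions exactly.  The torsions that lie along the construction tree are
#' realized to numerical precision: `beta`, `gamma`, `delta` of both
#' residues, `epsilon`/`zeta` of residue 1, `alpha` of residue 2, `chi`,
#' `nu0` and `nu4` of both residues (with `nu0`/`nu4` derived from `P` and
#' `psi_m`).  Ring closure is NOT enforced, so `alpha` of residue 1,
#' `epsilon`/`zeta` of residue 2 and the remaining endocyclic torsions
#' (`nu1`-`nu3`) are only approximate consequences of the geometry.
#'
#' @param torsions named list with one entry per residue (`res1`, `res2`),
#'   each a named list/vector providing `beta`, `gamma`, `delta`,
#'   `epsilon`, `zeta`, `alpha`, `chi`, `P`, `psi_m` (degrees).
#' @param res_names length-2 character: residue (base) names, e.g.
#'   `c("G", "G")`; purines (`A`/`G`) get an `N9`/`C4`/`C8` stub,
#'   pyrimidines (`C`/`U`/`T`) an `N1`/`C2`/`C6` stub.
#' @return A single-frame [conformer_ensemble()] (cyclic flag set).
#' @export
build_macrocycle_template <- function(torsions, res_names = c("G", "G")) {
  required <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                "chi", "P", "psi_m")
  for (r in c("res1", "res2")) {
    t <- torsions[[r]]
    if (is.null(t) || !all(required %in% names(t))) {
      stop("incomplete torsion set for ", r, ": need ",
           paste(setdiff(required, names(torsions[[r]])), collapse = ", "),
           call. = FALSE)
    }
  }
  t1 <- as.list(torsions$res1)
  t2 <- as.list(torsions$res2)
  nu <- function(t, j) t$psi_m * cosd(t$P + 144 * (j - 2))

  xyz <- list()
  atoms <- list()
  put <- function(res, name, pos) {
    xyz[[length(xyz) + 1L]] <<- pos
    atoms[[length(atoms) + 1L]] <<- data.frame(
      res_id = res, res_name = res_names[res], atom_name = name,
      stringsAsFactors = FALSE)
    pos
  }
  ## residue 1 backbone seed (first three atoms define the frame)
  P1  <- put(1L, "P",   c(0, 0, 0))
  O51 <- put(1L, "O5'", c(ideal_bonds[["P-O5'"]], 0, 0))
  C51 <- put(1L, "C5'", nerf_place(c(0, 0, 1), P1, O51,
                                   ideal_bonds[["O5'-C5'"]], 120, 0))
  chain <- function(A, B, C, res, name, bond, tors, angle = ideal_angle) {
    put(res, name, nerf_place(A, B, C, bond, angle, tors))
  }
  C41 <- chain(P1, O51, C51, 1L, "C4'", ideal_bonds[["C5'-C4'"]], t1$beta)
  C31 <- chain(O51, C51, C41, 1L, "C3'", ideal_bonds[["C4'-C3'"]], t1$gamma)
  O31 <- chain(C51, C41, C31, 1L, "O3'", ideal_bonds[["C3'-O3'"]], t1$delta)
  P2  <- chain(C41, C31, O31, 1L, NA, ideal_bonds[["O3'-P"]], t1$epsilon)
  ## P2 belongs to residue 2; fix the bookkeeping entry just written
  atoms[[length(atoms)]]$res_id <- 2L
  atoms[[length(atoms)]]$res_name <- res_names[2]
  atoms[[length(atoms)]]$atom_name <- "P"
  O52 <- chain(C31, O31, P2, 2L, "O5'", ideal_bonds[["P-O5'"]], t1$zeta, 104)
  C52 <- chain(O31, P2, O52, 2L, "C5'", ideal_bonds[["O5'-C5'"]], t2$alpha, 120)
  C42 <- chain(P2, O52, C52, 2L, "C4'", ideal_bonds[["C5'-C4'"]], t2$beta)
  C32 <- chain(O52, C52, C42, 2L, "C3'", ideal_bonds[["C4'-C3'"]], t2$gamma)
  O32 <- chain(C52, C42, C32, 2L, "O3'", ideal_bonds[["C3'-O3'"]], t2$delta)

  sugar_base <- function(res, t, O5, C5, C4, C3) {
    purine <- res_names[res] %in% c("A", "G")
    ## O4' branch: auxiliary torsion offset from gamma (other C4' substituent)
    O4 <- put(res, "O4'", nerf_place(O5, C5, C4, ideal_bonds[["C4'-O4'"]],
                                     ideal_angle, t$gamma - 121))
    C1 <- put(res, "C1'", nerf_place(C3, C4, O4, ideal_bonds[["O4'-C1'"]],
                                     ideal_angle, nu(t, 4)))
    C2s <- put(res, "C2'", nerf_place(C4, O4, C1, ideal_bonds[["C1'-C2'"]],
                                      ideal_angle, nu(t, 0)))
    N <- put(res, if (purine) "N9" else "N1",
             nerf_place(C4, O4, C1, ideal_bonds[["C1'-N"]], ideal_angle,
                        nu(t, 0) - 121))  # other C1' substituent vs C2'
    Cb <- put(res, if (purine) "C4" else "C2",
              nerf_place(O4, C1, N, ideal_bonds[["N-C"]], 126, t$chi))
    put(res, if (purine) "C8" else "C6",
        nerf_place(O4, C1, N, ideal_bonds[["N-C"]], 126, t$chi + 180))
    invisible(NULL)
  }
  sugar_base(1L, t1, O51, C51, C41, C31)
  sugar_base(2L, t2, O52, C52, C42, C32)

  coords <- do.call(rbind, xyz)
  atoms <- do.call(rbind, atoms)
  ## reorder so residue 2's P follows residue 1's atoms naturally
  ord <- order(atoms$res_id, seq_len(nrow(atoms)))
  conformer_ensemble(frames = list(coords[ord, , drop = FALSE]),
                     atoms = atoms[ord, , drop = FALSE], cyclic = TRUE)
}
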