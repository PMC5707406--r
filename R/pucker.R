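## Pseudorotation algebra for five-membered (furanose) rings, in the
## Altona-Sundaralingam convention: the five endocyclic torsions nu0..nu4 are
## generated from a single phase angle P and amplitude psi_m by
##   nu_j = psi_m * cos(P + 144 * (j - 2)),   j = 0..4,
## so that nu2 = psi_m * cos(P).  North (C3'-endo-like) sugars have P near 0,
## South (C2'-endo-like) near 160.

#' Pseudorotation parameters of a furanose ring
#'
#' Bundles the phase angle `P` (degrees, wrapped to `[-180, 180)`) and the
#' puckering amplitude `psi_m` (degrees, strictly positive) that together
#' determine all five endocyclic ring torsions.
#'
#' @param P phase angle of pseudorotation, degrees.
#' @param psi_m puckering amplitude, degrees, `> 0`.
#' @return An object of class `"pucker_params"`: a named list with elements
#'   `P` and `psi_m`.
#' @examples
#' pucker_params(0, 41)    # canonical N-type ribose
#' pucker_params(163, 38)  # canonical S-type ribose
#' @export
pucker_params <- function(P, psi_m) {
  check_scalar_finite(P, "P")
  check_scalar_finite(psi_m, "psi_m")
  if (psi_m <= 0) {
    stop("'psi_m' must be a finite, strictly positive amplitude (degrees)",
         call. = FALSE)
  }
  structure(list(P = wrap_angle(P), psi_m = psi_m), class = "pucker_params")
}

#' @export
print.pucker_params <- function(x, ...) {
  cat(sprintf("<pucker_params> P = %.2f deg, psi_m = %.2f deg (%s-type)\n",
              x$P, x$psi_m, classify_torsion(x$P, "pucker")))
  invisible(x)
}

#' Endocyclic ring torsions from pseudorotation parameters
#'
#' Evaluates `nu_j = psi_m * cos(P + 144 * (j - 2))` for `j = 0..4` and wraps
#' each torsion to `[-180, 180)`.
#'
#' @param p a [pucker_params()] object (or a list with `P` and `psi_m`).
#' @return Named numeric vector `c(nu0, nu1, nu2, nu3, nu4)`, degrees, class
#'   `"ring_torsions"`.
#' @examples
#' torsions_from_phase(pucker_params(0, 40))[["nu2"]]  # == 40
#' @export
torsions_from_phase <- function(p) {
  if (!is.list(p) || is.null(p$P) || is.null(p$psi_m)) {
    stop("'p' must be a pucker_params object", call. = FALSE)
  }
  p <- pucker_params(p$P, p$psi_m)  # re-validate
  j <- 0:4
  nu <- wrap_angle(p$psi_m * cosd(p$P + 144 * (j - 2)))
  structure(stats::setNames(nu, paste0("nu", j)), class = "ring_torsions")
}

#' Pseudorotation parameters from endocyclic ring torsions
#'
#' Inverts [torsions_from_phase()]: the phase follows from
#' `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 * nu2 * (sin 36 + sin 72))`
#' with the quadrant resolved via `atan2` on the sign of `nu2` (so `nu2 = 0`
#' yields the `P = +/-90` branch rather than a division failure), and the
#' amplitude from `psi_m = nu2 / cos P`.  On noise-free input this is an exact
#' left inverse of [torsions_from_phase()].
#'
#' @param t numeric vector of the five torsions `nu0..nu4` in that order
#'   (degrees), e.g. the output of [torsions_from_phase()].
#' @return A [pucker_params()] object.  `psi_m` is always positive.
#' @examples
#' phase_from_torsions(torsions_from_phase(pucker_params(163, 38)))
#' @export
phase_from_torsions <- function(t) {
  t <- unclass(t)
  if (!is.numeric(t) || length(t) != 5L || any(!is.finite(t))) {
    stop("'t' must be five finite endocyclic torsions nu0..nu4 (degrees)",
         call. = FALSE)
  }
  t <- unname(t)
  num <- (t[5] + t[2]) - (t[4] + t[1])              # (nu4+nu1) - (nu3+nu0)
  den <- 2 * t[3] * (sind(36) + sind(72))           # 2*nu2*(sin36+sin72)
  P <- rad2deg(atan2(num, den))
  psi_m <- t[3] / cosd(P)
  if (!is.finite(psi_m) || abs(cosd(P)) < 1e-12) {
    ## nu2 = 0 branch: amplitude from the out-of-phase combination instead
    psi_m <- num / (2 * (sind(36) + sind(72)))
    psi_m <- abs(psi_m)
    P <- if (num >= 0) 90 else -90
    ## sign of P already consistent: atan2(num, 0) gives +/-90
  }
  if (psi_m < 0) {          # keep amplitude positive, flip phase by 180
    psi_m <- -psi_m
    P <- wrap_angle(P + 180)
  }
  if (psi_m <= 0) {
    stop("degenerate (planar) ring: amplitude is zero, phase undefined",
         call. = FALSE)
  }
  pucker_params(P, psi_m)
}

#' Classify a torsion angle into a conformational class
#'
#' Three classification schemes are supported, each operating on the angle
#' wrapped to `[-180, 180)` (so the result is invariant under adding full
#' turns):
#' \describe{
#'   \item{`"pucker"`}{phase angle `P`: `"N"` iff `P` in `(-90, 90]`,
#'     else `"S"`.}
#'   \item{`"glycosidic"`}{chi torsion: `"syn"` iff chi in `(-90, 90]`,
#'     else `"anti"`.}
#'   \item{`"rotamer"`}{staggered single-bond rotamers: `"g+"` for
#'     `[0, 120)`, `"t"` for `[120, 240)` (i.e. `[120, 180) U [-180, -120)`),
#'     `"g-"` otherwise.}
#' }
#' Boundary angles belong to the left-closed class; this is a convention
#' choice made so classification is deterministic.
#'
#' @param angle numeric vector of angles in degrees (any real value).
#' @param scheme one of `"pucker"`, `"glycosidic"`, `"rotamer"`.
#' @return Character vector of class labels, same length as `angle`.
#' @examples
#' classify_torsion(0, "pucker")        # "N"
#' classify_torsion(211, "glycosidic")  # "anti"
#' classify_torsion(c(53, 180, -70), "rotamer")
#' @export
classify_torsion <- function(angle, scheme = c("pucker", "glycosidic",
                                               "rotamer")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("'angle' must be finite (degrees)", call. = FALSE)
  }
  w <- wrap_angle(angle)
  switch(scheme,
    pucker     = ifelse(w > -90 & w <= 90, "N", "S"),
    glycosidic = ifelse(w > -90 & w <= 90, "syn", "anti"),
    rotamer    = {
      u <- angle %% 360  # [0, 360)
      ifelse(u < 120, "g+", ifelse(u < 240, "t", "g-"))
    }
  )
}
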