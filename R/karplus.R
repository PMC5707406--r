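## Forward prediction of three-bond scalar couplings from torsion angles.
## Coefficients live in a JSON registry (inst/extdata/karplus_params.json) so
## alternative published parametrizations can be swapped in without touching
## code.  All couplings in Hz, all angles in degrees.

the <- new.env(parent = emptyenv())  # registry cache

#' Load a Karplus parameter registry
#'
#' Reads a JSON file with named Karplus coefficient sets, the proton-torsion
#' map for the ribose and exocyclic H-H pairs, and the backbone fragment map
#' used for beta/epsilon estimation.  The packaged default is returned when
#' `path` is `NULL`.
#'
#' @param path path to a registry JSON file, or `NULL` for the packaged
#'   default.
#' @return A list of class `"karplus_registry"` with elements `karplus_sets`,
#'   `proton_torsion_map`, `backbone_fragment_map`, `annotation_fragments`.
#' @export
load_karplus_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$default_registry)) return(the$default_registry)
    path <- system.file("extdata", "karplus_params.json", package = "cdnconf")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("Karplus registry file not found: ", path, call. = FALSE)
  }
  reg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  for (nm in names(reg$karplus_sets)) {
    s <- reg$karplus_sets[[nm]]
    if (!all(is.finite(c(s$A, s$B, s$C)))) {
      stop("non-finite coefficients in Karplus set '", nm, "'", call. = FALSE)
    }
  }
  reg <- structure(reg, class = "karplus_registry")
  if (cache) the$default_registry <- reg
  reg
}

#' Evaluate a Karplus curve
#'
#' `J(phi) = A cos^2(phi) + B cos(phi) + C`, plus, when the parameter set
#' carries substituent (electronegativity) terms, the generalized correction
#' `sum_i dchi_i * (D_i + E_i * cos^2(xi_i * phi + F_i * |dchi_i|))`.
#'
#' @param phi torsion angle(s), degrees; vectorized.
#' @param params a single Karplus set: a list with `A`, `B`, `C` and optional
#'   `substituent_terms` (each a list with `dchi`, `xi`, `D`, `E`, `F`), or a
#'   set name resolved in `registry`.
#' @param registry registry used to resolve a set name
#'   (default [load_karplus_registry()]).
#' @return Predicted coupling(s), Hz.
#' @examples
#' j3_karplus(180, list(A = 6.9, B = -3.4, C = 0.7))  # A - B + C
#' @export
j3_karplus <- function(phi, params, registry = load_karplus_registry()) {
  if (is.character(params)) {
    nm <- params
    params <- registry$karplus_sets[[nm]]
    if (is.null(params)) {
      stop("unknown Karplus set '", nm, "'; available: ",
           paste(names(registry$karplus_sets), collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.numeric(phi) || any(!is.finite(phi))) {
    stop("'phi' must be finite (degrees)", call. = FALSE)
  }
  cphi <- cosd(phi)
  j <- params$A * cphi^2 + params$B * cphi + params$C
  for (term in params$substituent_terms) {
    j <- j + term$dchi *
      (term$D + term$E * cosd(term$xi * phi + term$F * abs(term$dchi))^2)
  }
  j
}

## Vectorized ribose J prediction over parallel vectors of (P, psi_m); used
## by the fitters where thousands of grid points are evaluated at once.
predict_ribose_jhh_vec <- function(P, psi_m,
                                   registry = load_karplus_registry()) {
  pairs <- c("H1'H2'", "H2'H3'", "H3'H4'")
  nus <- list(nu1 = psi_m * cosd(P - 144),
              nu2 = psi_m * cosd(P),
              nu3 = psi_m * cosd(P + 144))
  out <- matrix(NA_real_, nrow = length(P), ncol = 3,
                dimnames = list(NULL, pairs))
  for (pair in pairs) {
    m <- registry$proton_torsion_map[[pair]]
    if (is.null(m)) {
      stop("proton-torsion map has no entry for pair '", pair, "'",
           call. = FALSE)
    }
    phi <- m$offset + m$slope * nus[[m$governing]]
    out[, pair] <- j3_karplus(phi, m$set, registry)
  }
  out
}

#' Predict the three ribose proton-proton couplings of a sugar pucker state
#'
#' Computes the endocyclic torsions `nu1`, `nu2`, `nu3` from the
#' pseudorotation state, maps each to its proton-proton torsion through the
#' registry's affine proton-torsion map, and evaluates the corresponding
#' Karplus curves.
#'
#' @param p a [pucker_params()] object.
#' @inheritParams j3_karplus
#' @return Named numeric vector `c("H1'H2'", "H2'H3'", "H3'H4'")`, Hz.
#' @examples
#' predict_ribose_jhh(pucker_params(0, 41))    # N-type: J(H1'H2') small
#' predict_ribose_jhh(pucker_params(163, 38))  # S-type: J(H1'H2') large
#' @export
predict_ribose_jhh <- function(p, registry = load_karplus_registry()) {
  p <- pucker_params(p$P, p$psi_m)
  drop(predict_ribose_jhh_vec(p$P, p$psi_m, registry)[1, ])
}

#' Predict the H4'-H5' and H4'-H5'' couplings of a gamma torsion
#'
#' The two proton-proton torsions are `gamma` and `gamma - 120` (registry
#' defaults), chosen so that the canonical `g+` rotamer at 53 degrees
#' predicts both couplings small.
#'
#' @param gamma C4'-C5' torsion angle(s), degrees; vectorized.
#' @inheritParams j3_karplus
#' @return For scalar input, named vector `c("H4'H5'", "H4'H5''")` (Hz); for
#'   vector input, a matrix with those columns.
#' @examples
#' predict_gamma_jhh(53)   # both small
#' predict_gamma_jhh(180)  # one large
#' @export
predict_gamma_jhh <- function(gamma, registry = load_karplus_registry()) {
  if (!is.numeric(gamma) || any(!is.finite(gamma))) {
    stop("'gamma' must be finite (degrees)", call. = FALSE)
  }
  pairs <- c("H4'H5'", "H4'H5''")
  out <- matrix(NA_real_, nrow = length(gamma), ncol = 2,
                dimnames = list(NULL, pairs))
  for (pair in pairs) {
    m <- registry$proton_torsion_map[[pair]]
    if (is.null(m)) {
      stop("proton-torsion map has no entry for pair '", pair, "'",
           call. = FALSE)
    }
    out[, pair] <- j3_karplus(m$offset + m$slope * gamma, m$set, registry)
  }
  if (length(gamma) == 1L) drop(out[1, ]) else out
}

## Predicted couplings for a backbone torsion angle across the fragments
## listed in the registry's backbone map for that torsion.  Returns a matrix
## (length(angle) x fragments).
predict_backbone_j <- function(angle, torsion = c("beta", "epsilon"),
                               registry = load_karplus_registry()) {
  torsion <- match.arg(torsion)
  bm <- registry$backbone_fragment_map
  frags <- names(bm)[vapply(bm, function(m) m$governing == torsion,
                            logical(1))]
  out <- matrix(NA_real_, nrow = length(angle), ncol = length(frags),
                dimnames = list(NULL, frags))
  for (f in frags) {
    out[, f] <- j3_karplus(angle + bm[[f]]$offset, bm[[f]]$set, registry)
  }
  out
}
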