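## Container for measured (or simulated) scalar couplings of one residue at
## one temperature.

## fragment vocabulary comes from the registry: proton pairs, backbone
## fragments, and annotation-only (4J) labels
coupling_vocabulary <- function(registry = load_karplus_registry()) {
  c(names(registry$proton_torsion_map),
    names(registry$backbone_fragment_map),
    registry$annotation_fragments)
}

#' Create a set of scalar coupling constants
#'
#' @param fragment character vector of fragment labels from the controlled
#'   vocabulary (see [coupling_vocabulary()]), e.g. `"H1'H2'"`, `"C2'P"`.
#' @param J_Hz coupling values, Hz.  Values outside the plausibility band
#'   `[0, 15]` Hz trigger a warning, not an error.
#' @param sigma_Hz optional per-coupling uncertainties, Hz (`NA` allowed).
#' @param residue residue label, e.g. `"G1"`.
#' @param temperature_K temperature, K.
#' @param registry Karplus registry used for vocabulary checking.
#' @return A data frame of class `"jcoupling_set"` with columns `fragment`,
#'   `J_Hz`, `sigma_Hz` and attributes `residue`, `temperature_K`.
#' @examples
#' jcoupling_set(c("H1'H2'", "H3'H4'"), c(1.2, 7.1), residue = "G1")
#' @export
jcoupling_set <- function(fragment, J_Hz, sigma_Hz = NA_real_,
                          residue = "res1", temperature_K = 298,
                          registry = load_karplus_registry()) {
  fragment <- as.character(fragment)
  if (length(fragment) != length(J_Hz)) {
    stop("'fragment' and 'J_Hz' must have equal length", call. = FALSE)
  }
  vocab <- coupling_vocabulary(registry)
  bad <- setdiff(fragment, vocab)
  if (length(bad) > 0) {
    stop("unknown fragment label(s): ", paste(bad, collapse = ", "),
         "; expected one of: ", paste(vocab, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(fragment)) {
    stop("duplicate fragment label(s): ",
         paste(unique(fragment[duplicated(fragment)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(J_Hz))) stop("'J_Hz' must be finite", call. = FALSE)
  if (any(J_Hz < 0 | J_Hz > 15)) {
    warning("coupling value(s) outside the 0-15 Hz plausibility band",
            call. = FALSE)
  }
  check_scalar_finite(temperature_K, "temperature_K")
  df <- data.frame(fragment = fragment, J_Hz = as.numeric(J_Hz),
                   sigma_Hz = rep_len(as.numeric(sigma_Hz), length(J_Hz)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("jcoupling_set", "data.frame"),
            residue = as.character(residue),
            temperature_K = temperature_K)
}

#' @export
print.jcoupling_set <- function(x, ...) {
  cat(sprintf("<jcoupling_set> residue %s at %g K, %d coupling(s)\n",
              attr(x, "residue"), attr(x, "temperature_K"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

## pull named couplings (and weights) for a subset of fragments; NA for absent
couplings_for <- function(obs, fragments) {
  stopifnot(inherits(obs, "jcoupling_set"))
  idx <- match(fragments, obs$fragment)
  j <- obs$J_Hz[idx]
  s <- obs$sigma_Hz[idx]
  ## equal weights unless every present coupling has an uncertainty
  w <- if (all(is.finite(s[!is.na(j)]))) 1 / s^2 else rep(1, length(j))
  list(J = stats::setNames(j, fragments),
       w = stats::setNames(w, fragments))
}
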