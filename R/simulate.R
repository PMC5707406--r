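## Synthetic-data generators: von Mises (circular-normal) torsion ensembles
## with known ground truth, and forward-modelled coupling sets.  All
## generators are pure functions of (spec, seed): the global RNG state is
## saved and restored around each call.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## von Mises sampler (Best & Fisher 1979 wrapped-Cauchy rejection); kappa = 0
## degenerates to the circular uniform.  mean/"mu" in degrees.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("'kappa' must be >= 0", call. = FALSE)
  if (kappa == 0) return(stats::runif(n, -180, 180))
  if (kappa > 5e5) return(rep(mu, n))  # numerically a point mass
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- seq_len(min(sum(ok), m))
    out[got + take] <- th[take]
    got <- got + length(take)
  }
  wrap_angle(mu + rad2deg(out))
}

#' Torsion distribution specification for the synthetic ensemble generator
#'
#' Each torsion is described by a mixture of circular-normal (von Mises)
#' components `(mean, kappa, weight)`.  Weights must sum to 1 and
#' concentrations be non-negative.
#'
#' @param ... named torsion entries; each a data frame (or list coercible to
#'   one) with columns `mean` (degrees), `kappa` (`>= 0`) and `weight`.
#' @return Object of class `"torsion_spec"` (named list of component
#'   tables).
#' @seealso [cdn_torsion_spec()] for the packaged CDN-like default.
#' @export
torsion_spec <- function(...) {
  spec <- lapply(list(...), function(x) {
    x <- as.data.frame(x)
    stopifnot(all(c("mean", "kappa", "weight") %in% names(x)))
    if (any(x$kappa < 0) || any(x$weight < 0)) {
      stop("concentrations and weights must be >= 0", call. = FALSE)
    }
    if (abs(sum(x$weight) - 1) > 1e-9) {
      stop("component weights must sum to 1", call. = FALSE)
    }
    x
  })
  if (length(spec) == 0 || is.null(names(spec)) || any(names(spec) == "")) {
    stop("torsion entries must be named", call. = FALSE)
  }
  structure(spec, class = "torsion_spec")
}

one_mode <- function(mean, kappa) {
  data.frame(mean = mean, kappa = kappa, weight = 1)
}

#' CDN-like default torsion distribution
#'
#' Means follow the measured/optimized values for cyclic di-nucleotides
#' (tight unimodal backbone: alpha 75, beta -172, gamma 53, delta 84,
#' epsilon -155, zeta 70; N-type pucker at P = 10), with the glycosidic
#' torsion either purely `anti` (mean -149, i.e. 211) for pyrimidine-like
#' molecules or an anti/syn mixture for purine-like ones.  The syn:anti
#' weight ratio defaults to `exp(-1/(k_B * 300))` (a 1 kcal/mol free-energy
#' gap at 300 K).  Concentrations: 50 for the backbone (about 8-degree
#' spread), 20 for chi and P.
#'
#' @param base `"purine"` (bimodal chi) or `"pyrimidine"` (unimodal anti).
#' @param syn_gap_kcal free-energy gap of the syn mode above anti, kcal/mol
#'   (purine only).
#' @param T temperature used to convert the gap to a weight ratio, K.
#' @return A [torsion_spec()] with entries `alpha`..`zeta`, `chi`, `P`.
#' @export
cdn_torsion_spec <- function(base = c("purine", "pyrimidine"),
                             syn_gap_kcal = 1, T = 300) {
  base <- match.arg(base)
  chi <- if (base == "purine") {
    ratio <- exp(-syn_gap_kcal / (0.0019872 * T))  # syn/anti population
    data.frame(mean = c(-149, 60), kappa = c(20, 20),
               weight = c(1, ratio) / (1 + ratio))
  } else {
    one_mode(-149, 20)
  }
  torsion_spec(alpha = one_mode(75, 50), beta = one_mode(-172, 50),
               gamma = one_mode(53, 50), delta = one_mode(84, 50),
               epsilon = one_mode(-155, 50), zeta = one_mode(70, 50),
               chi = chi, P = one_mode(10, 20))
}

#' Sample a synthetic torsion ensemble
#'
#' Draws `n` frames per residue from the circular-normal mixtures of `spec`
#' and derives the endocyclic torsions `nu0`-`nu4` from the sampled phase
#' angle at fixed amplitude `psi_m`, yielding the same `"torsion_series"`
#' shape that [compute_torsion_series()] produces from coordinates.
#'
#' @param spec a [torsion_spec()].
#' @param n number of frames (`>= 1`).
#' @param seed integer seed; same seed, same series.
#' @param n_residues number of residue units (sampled independently).
#' @param psi_m fixed puckering amplitude used to expand `P` into
#'   `nu0..nu4`, degrees.
#' @return A `"torsion_series"` object.
#' @export
sample_torsion_ensemble <- function(spec, n, seed = NULL, n_residues = 2,
                                    psi_m = 41) {
  if (!inherits(spec, "torsion_spec")) {
    stop("'spec' must be a torsion_spec object", call. = FALSE)
  }
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    residues <- lapply(seq_len(n_residues), function(r) {
      df <- as.data.frame(lapply(spec, function(comp) {
        k <- nrow(comp)
        pick <- if (k == 1) rep(1L, n) else
          sample.int(k, n, replace = TRUE, prob = comp$weight)
        vals <- numeric(n)
        for (ci in seq_len(k)) {
          sel <- pick == ci
          if (any(sel)) {
            vals[sel] <- rvonmises(sum(sel), comp$mean[ci], comp$kappa[ci])
          }
        }
        vals
      }))
      if (!is.null(df$P)) {
        for (j in 0:4) {
          df[[paste0("nu", j)]] <-
            wrap_angle(psi_m * cosd(df$P + 144 * (j - 2)))
        }
        df$psi_m <- psi_m
      }
      df
    })
    names(residues) <- paste0("res", seq_len(n_residues))
    structure(list(residues = residues, n_frames = n),
              class = "torsion_series")
  })
}

#' Forward-simulate ribose coupling sets from a two-state pucker model
#'
#' Generates `n_replicates` coupling sets according to
#' `J = f_N * J(P_N, psi_N) + (1 - f_N) * J(P_S, psi_S) + N(0, sigma^2)`,
#' the exact forward model that [fit_two_state_pucker()] inverts.
#'
#' @param P_N,psi_N North-state pseudorotation parameters, degrees.
#' @param f_N N-state population fraction in `[0, 1]`.
#' @param sigma coupling noise standard deviation, Hz (`>= 0`).
#' @param n_replicates number of independent coupling sets.
#' @param seed integer seed.
#' @param fixed_S fixed South state ([pucker_params()]).
#' @param temperature_K stored on each set.
#' @param registry Karplus registry.
#' @return List of [jcoupling_set()] objects (length `n_replicates`).
#' @export
generate_ribose_couplings <- function(P_N, psi_N, f_N, sigma = 0,
                                      n_replicates = 1, seed = NULL,
                                      fixed_S = pucker_params(163, 38),
                                      temperature_K = 298,
                                      registry = load_karplus_registry()) {
  if (!is.numeric(sigma) || sigma < 0) {
    stop("'sigma' must be >= 0 (Hz)", call. = FALSE)
  }
  if (f_N < 0 || f_N > 1) stop("'f_N' must be in [0, 1]", call. = FALSE)
  jN <- predict_ribose_jhh(pucker_params(P_N, psi_N), registry)
  jS <- predict_ribose_jhh(pucker_params(fixed_S$P, fixed_S$psi_m), registry)
  jmix <- f_N * jN + (1 - f_N) * jS
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      suppressWarnings(jcoupling_set(
        names(jmix), jmix + stats::rnorm(length(jmix), 0, sigma),
        sigma_Hz = if (sigma > 0) sigma else NA_real_,
        residue = sprintf("sim%d", i), temperature_K = temperature_K,
        registry = registry))
    })
  })
}
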