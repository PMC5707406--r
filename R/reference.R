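## NMR-derived conformational parameters of the five cyclic di-nucleotides
## (per residue unit where the two differ), as printed in the published
## per-CDN tables: glycosidic class, two-state pucker fit results
## (P_N, psi_N, fraction N), gamma rotamer class, and backbone beta/epsilon.
## These serve as ground-truth inputs for the synthetic coupling generator.

#' Reference conformational parameters for the five CDNs
#'
#' Measured (NMR-derived) parameters per CDN residue unit: the two-state
#' pucker result (`P_N`, `psi_N` in degrees, `f_N` fraction of N-type), the
#' temperature at which the pucker was determined, the dominant glycosidic
#' class, the gamma rotamer populations (all `g+` where determined) and the
#' backbone `beta`/`epsilon` torsions (degrees).
#'
#' @return data frame, one row per CDN residue unit.
#' @export
cdn_reference_params <- function() {
  data.frame(
    cdn = c("c-di-GMP", "c-di-AMP", "c-GAMP(G)", "c-GAMP(A)",
            "c-di-CMP", "c-di-UMP"),
    base = c("G", "A", "G", "A", "C", "U"),
    chi_class = "anti",
    P_N = c(0, 4, 4, 1, 19, 18),
    psi_N = c(41, 42, 40, 40, 43, 40),
    f_N = c(1, 1, 0.95, 1, 1, 1),
    pucker_T_K = c(298, 298, 333, 298, 298, 298),
    gamma = 53,          # 100% g+ where determined
    beta = c(-170, -170, -160, -170, -170, -170),
    epsilon = c(-150, -150, -150, -160, -150, -150),
    stringsAsFactors = FALSE
  )
}

#' Synthetic stand-in for the supplementary coupling tables
#'
#' The original per-CDN measured coupling tables are not redistributable, so
#' this generator forward-models them: for every CDN residue unit in
#' [cdn_reference_params()] it predicts the three ribose `3J(H-H)`
#' couplings from the two-state pucker model, the two exocyclic `3J(H4'H5x)`
#' couplings from the pure `g+` gamma rotamer, and the six phosphorus
#' couplings from the tabulated `beta`/`epsilon` torsions, through the
#' package's Karplus registry, optionally adding Gaussian noise.  This is a
#' SYNTHETIC data set: round-tripping it through the fitters tests
#' self-consistency at the published parameter values, not agreement with
#' the original spectra.
#'
#' @param noise_sd Gaussian noise added to every coupling, Hz.
#' @param seed integer seed (used when `noise_sd > 0`).
#' @param registry Karplus registry.
#' @return data frame with columns `cdn`, `residue`, `fragment`, `J_Hz`,
#'   `sigma_Hz`, `temperature_K` (the CSV schema of [read_couplings()]).
#' @export
synthetic_supplementary_couplings <- function(noise_sd = 0, seed = NULL,
                                              registry =
                                                load_karplus_registry()) {
  ref <- cdn_reference_params()
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    jr <- r$f_N * predict_ribose_jhh(pucker_params(r$P_N, r$psi_N),
                                     registry) +
      (1 - r$f_N) * predict_ribose_jhh(pucker_params(163, 38), registry)
    jg <- predict_gamma_jhh(r$gamma, registry)
    jb <- predict_backbone_j(r$beta, "beta", registry)[1, ]
    je <- predict_backbone_j(r$epsilon, "epsilon", registry)[1, ]
    j <- c(jr, jg, jb, je)
    data.frame(cdn = r$cdn, residue = r$cdn, fragment = names(j),
               J_Hz = as.numeric(j), sigma_Hz = NA_real_,
               temperature_K = r$pucker_T_K, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (noise_sd > 0) {
    out$J_Hz <- with_seed(seed, out$J_Hz +
                            stats::rnorm(nrow(out), 0, noise_sd))
    out$sigma_Hz <- noise_sd
  }
  out
}
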