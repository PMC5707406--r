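## NMR inference stage: two-state N/S pseudorotation fit, three-rotamer gamma
## population fit, and grid-based backbone-torsion estimation, all driven by
## the Karplus registry.  The Karplus objective is multimodal, so the pucker
## fit uses multi-start bounded minimization (coarse grid, then local
## refinement of the best starts); a single-start optimizer can land on the
## wrong branch.

#' Two-state (N/S) pseudorotation fit of ribose proton couplings
#'
#' Models each observed ribose coupling as a population-weighted average of a
#' variable North conformer and a fixed South conformer,
#' `J = f_N * J(P_N, psi_N) + (1 - f_N) * J(P_S, psi_S)`, and minimizes the
#' (optionally inverse-variance weighted) sum of squared residuals over
#' `P_N`, `psi_N` and `f_N`.  The South state is held fixed, by default at
#' `(P_S, psi_S) = (163, 38)` degrees.
#'
#' @param obs a [jcoupling_set()] containing at least two of the three ribose
#'   couplings `H1'H2'`, `H2'H3'`, `H3'H4'`.
#' @param fixed_S [pucker_params()] of the fixed minor (S-type) conformer.
#' @param bounds named list of `c(lower, upper)` bounds for `P_N` (default
#'   `c(-90, 90)`), `psi_N` (default `c(25, 50)`, typical furanose
#'   amplitudes) and `f_N` (default `c(0, 1)`).
#' @param fix optional named list fixing a subset of `P_N`, `psi_N`, `f_N` at
#'   given values (needed when fewer couplings than free parameters are
#'   observed).
#' @param registry Karplus registry.
#' @param n_starts number of coarse-grid starting points refined locally.
#' @return Object of class `"two_state_fit"`: list with `P_N`, `psi_N`,
#'   `f_N`, `rmsd_J` (Hz), `fixed_S`, `fitted`, `observed`, `n_obs`.
#' @examples
#' obs <- jcoupling_set(c("H1'H2'", "H2'H3'", "H3'H4'"),
#'                      predict_ribose_jhh(pucker_params(0, 41)))
#' fit_two_state_pucker(obs)  # recovers (0, 41, 1)
#' @export
fit_two_state_pucker <- function(obs,
                                 fixed_S = pucker_params(163, 38),
                                 bounds = list(P_N = c(-90, 90),
                                               psi_N = c(25, 50),
                                               f_N = c(0, 1)),
                                 fix = list(),
                                 registry = load_karplus_registry(),
                                 n_starts = 8) {
  pairs <- c("H1'H2'", "H2'H3'", "H3'H4'")
  cw <- couplings_for(obs, pairs)
  have <- !is.na(cw$J)
  n_obs <- sum(have)
  free <- setdiff(c("P_N", "psi_N", "f_N"), names(fix))
  if (n_obs < 2) {
    stop("need at least two of ", paste(pairs, collapse = ", "),
         " in 'obs' (found ", n_obs, ")", call. = FALSE)
  }
  if (n_obs < length(free)) {
    stop("underdetermined fit: ", n_obs, " coupling(s) for ", length(free),
         " free parameter(s); fix ", length(free) - n_obs, " of ",
         paste(free, collapse = ", "), " via 'fix'", call. = FALSE)
  }
  jobs <- cw$J[have]
  w <- cw$w[have]
  fixed_S <- pucker_params(fixed_S$P, fixed_S$psi_m)
  jS <- predict_ribose_jhh_vec(fixed_S$P, fixed_S$psi_m, registry)[1, pairs]
  jS <- jS[have]

  full_par <- function(par) {
    p <- c(as.list(par), fix)
    c(P_N = p$P_N, psi_N = p$psi_N, f_N = p$f_N)
  }
  ## vectorized objective over parallel parameter vectors
  sse_vec <- function(P_N, psi_N, f_N) {
    jN <- predict_ribose_jhh_vec(P_N, psi_N, registry)[, pairs, drop = FALSE]
    jN <- jN[, have, drop = FALSE]
    pred <- f_N * jN + (1 - f_N) %o% jS
    resid2 <- sweep(pred, 2, jobs)^2
    as.numeric(resid2 %*% w)
  }
  obj <- function(par) {
    p <- full_par(stats::setNames(as.list(par), free))
    sse_vec(p[["P_N"]], p[["psi_N"]], p[["f_N"]])
  }

  ## coarse grid over the free parameters
  grids <- list(P_N = seq(bounds$P_N[1], bounds$P_N[2], length.out = 13),
                psi_N = seq(bounds$psi_N[1], bounds$psi_N[2], length.out = 6),
                f_N = seq(bounds$f_N[1], bounds$f_N[2], length.out = 11))
  g <- expand.grid(grids[free], KEEP.OUT.ATTRS = FALSE)
  gp <- lapply(stats::setNames(free, free), function(nm) g[[nm]])
  pfull <- c(gp, fix)
  v <- sse_vec(rep_len(pfull$P_N, nrow(g)), rep_len(pfull$psi_N, nrow(g)),
               rep_len(pfull$f_N, nrow(g)))
  starts <- g[order(v)[seq_len(min(n_starts, nrow(g)))], , drop = FALSE]

  lower <- vapply(bounds[free], `[`, numeric(1), 1)
  upper <- vapply(bounds[free], `[`, numeric(1), 2)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(factr = 1e4,
                                       parscale = pmax(upper - lower, 1e-3)))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1e-16) break  # exact fit reached, remaining starts moot
  }
  pb <- full_par(stats::setNames(as.list(best$par), free))
  jN <- predict_ribose_jhh_vec(pb[["P_N"]], pb[["psi_N"]], registry)[1, pairs]
  fitted <- pb[["f_N"]] * jN + (1 - pb[["f_N"]]) *
    predict_ribose_jhh_vec(fixed_S$P, fixed_S$psi_m, registry)[1, pairs]
  rmsd_J <- sqrt(sum(w * (fitted[have] - jobs)^2) / sum(w))
  structure(list(P_N = wrap_angle(pb[["P_N"]]), psi_N = pb[["psi_N"]],
                 f_N = pb[["f_N"]], rmsd_J = rmsd_J, fixed_S = fixed_S,
                 fitted = fitted, observed = cw$J, n_obs = n_obs),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(paste0("<two_state_fit> P_N = %.1f deg, psi_N = %.1f deg, ",
                     "f_N = %.2f (%.0f%% N-type), rmsd = %.3f Hz\n"),
              x$P_N, x$psi_N, x$f_N, 100 * x$f_N, x$rmsd_J))
  invisible(x)
}

#' Three-rotamer population fit of the gamma torsion
#'
#' Assumes the C4'-C5' torsion interconverts between the three canonical
#' staggered rotamers (`g+` at 53, `t` at 180, `g-` at -70 degrees) and
#' solves the simplex-constrained least-squares problem
#' `J_obs ~ sum_r f_r * J_pred(gamma_r)` with `f_r >= 0`, `sum f_r = 1`,
#' from the observed `H4'H5'` and `H4'H5''` couplings.  The solution is
#' exact: all faces of the simplex are enumerated and each face's
#' equality-constrained least-squares problem is solved in closed form.
#'
#' @param J45p observed `3J(H4'H5')`, Hz.
#' @param J45pp observed `3J(H4'H5'')`, Hz.
#' @param gammas canonical rotamer angles, degrees (g+, t, g- order).
#' @param registry Karplus registry.
#' @return Object of class `"rotamer_fit"`: list with `fractions` (named
#'   `g+`, `t`, `g-`), `residual` (RMSD, Hz), `predicted`.  Warns when the
#'   residual exceeds 1 Hz (model misfit).
#' @examples
#' j <- predict_gamma_jhh(53)
#' fit_gamma_rotamers(j[["H4'H5'"]], j[["H4'H5''"]])  # pure g+
#' @export
fit_gamma_rotamers <- function(J45p, J45pp, gammas = c(53, 180, -70),
                               registry = load_karplus_registry()) {
  check_scalar_finite(J45p, "J45p")
  check_scalar_finite(J45pp, "J45pp")
  A <- t(predict_gamma_jhh(gammas, registry))  # 2 x 3: rows couplings
  j <- c(J45p, J45pp)
  k <- length(gammas)
  best <- NULL
  for (sz in seq_len(k)) {
    for (S in utils::combn(k, sz, simplify = FALSE)) {
      f <- solve_simplex_face(A[, S, drop = FALSE], j)
      if (is.null(f) || any(f < -1e-10)) next
      full <- numeric(k); full[S] <- pmax(f, 0); full <- full / sum(full)
      r <- sqrt(mean((A %*% full - j)^2))
      if (is.null(best) || r < best$residual - 1e-12) {
        best <- list(fractions = full, residual = r)
      }
    }
  }
  fr <- stats::setNames(best$fractions, c("g+", "t", "g-")[seq_len(k)])
  if (best$residual > 1) {
    warning(sprintf("rotamer model misfit: residual %.2f Hz > 1 Hz",
                    best$residual), call. = FALSE)
  }
  structure(list(fractions = fr, residual = best$residual,
                 predicted = stats::setNames(as.numeric(A %*% best$fractions),
                                             c("H4'H5'", "H4'H5''")),
                 gammas = gammas),
            class = "rotamer_fit")
}

## equality-constrained LS on a simplex face: min ||A f - j||^2, sum f = 1.
## KKT system; NULL when singular (e.g. duplicate columns).
solve_simplex_face <- function(A, j) {
  m <- ncol(A)
  K <- rbind(cbind(2 * crossprod(A), rep(1, m)),
             c(rep(1, m), 0))
  rhs <- c(2 * crossprod(A, j), 1)
  f <- tryCatch(solve(K, rhs)[seq_len(m)], error = function(e) NULL)
  f
}

#' @export
print.rotamer_fit <- function(x, ...) {
  cat(sprintf("<rotamer_fit> g+ %.2f / t %.2f / g- %.2f, residual %.3f Hz\n",
              x$fractions[["g+"]], x$fractions[["t"]], x$fractions[["g-"]],
              x$residual))
  invisible(x)
}

#' Grid-based estimation of a backbone torsion from phosphorus couplings
#'
#' Scans the requested torsion over `[-180, 180)` on a fixed grid, computes
#' the weighted sum of squared deviations between predicted and observed
#' couplings across every relevant fragment present in `obs`, and returns
#' all local minima (circular neighbourhood) whose residual lies within
#' twice the global minimum.  Karplus curves are even in the torsion, so a
#' single coupling cannot distinguish `phi` from `-phi`; combining fragments
#' with distinct offsets (the registry default) breaks the degeneracy.
#'
#' @param obs a [jcoupling_set()] with at least one fragment relevant to the
#'   requested torsion (see the registry's `backbone_fragment_map`).
#' @param torsion `"beta"` (P-O5'-C5'-C4') or `"epsilon"` (C4'-C3'-O3'-P).
#' @param grid_step scan step, degrees.
#' @param registry Karplus registry.
#' @return Object of class `"torsion_scan"`: list with `candidates` (data
#'   frame `angle`, `residual` sorted by residual), `best` (index, always 1),
#'   `torsion`, `fragments`.
#' @examples
#' obs <- jcoupling_set(c("H5'P", "H5''P", "C4'Pb"),
#'                      predict_backbone_j(-170, "beta")[1, ])
#' estimate_backbone_torsion(obs, "beta")$candidates[1, ]
#' @export
estimate_backbone_torsion <- function(obs, torsion = c("beta", "epsilon"),
                                      grid_step = 1,
                                      registry = load_karplus_registry()) {
  torsion <- match.arg(torsion)
  bm <- registry$backbone_fragment_map
  frags <- names(bm)[vapply(bm, function(m) m$governing == torsion,
                            logical(1))]
  cw <- couplings_for(obs, frags)
  have <- !is.na(cw$J)
  if (!any(have)) {
    stop("no couplings relevant to ", torsion, " in 'obs'; expected ",
         "fragment label(s): ", paste(frags, collapse = ", "), call. = FALSE)
  }
  frags <- frags[have]
  jobs <- cw$J[have]
  w <- cw$w[have]
  grid <- seq(-180, 180 - grid_step, by = grid_step)
  pred <- predict_backbone_j(grid, torsion, registry)[, frags, drop = FALSE]
  sse <- as.numeric(sweep(pred, 2, jobs)^2 %*% w)
  n <- length(grid)
  prv <- c(n, seq_len(n - 1))
  nxt <- c(2:n, 1)
  is_min <- sse < sse[prv] & sse <= sse[nxt]  # circular local minima
  rmsd <- sqrt(sse / sum(w))
  gmin <- min(rmsd)
  keep <- which(is_min & rmsd <= 2 * gmin + 1e-9)
  cand <- data.frame(angle = grid[keep], residual = rmsd[keep])
  cand <- cand[order(cand$residual, cand$angle), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(candidates = cand, best = 1L, torsion = torsion,
                 fragments = frags),
            class = "torsion_scan")
}

#' @export
print.torsion_scan <- function(x, ...) {
  cat(sprintf("<torsion_scan> %s from %s: best %g deg (residual %.3f Hz), %d candidate(s)\n",
              x$torsion, paste(x$fragments, collapse = "+"),
              x$candidates$angle[1], x$candidates$residual[1],
              nrow(x$candidates)))
  invisible(x)
}
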