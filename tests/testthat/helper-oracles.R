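## Independent oracles, deliberately written without reusing package
## internals: straight transcriptions of the defining formulas, brute-force
## grids, and a quaternion rotation search.

orc_d2r <- function(x) x * pi / 180

## one-line pseudorotation forward formula
orc_nu <- function(P, psi, j) psi * cos(orc_d2r(P + 144 * (j - 2)))

## one-line Karplus evaluation (A cos^2 + B cos + C + substituent terms)
orc_karplus <- function(phi, A, B, C, terms = NULL) {
  j <- A * cos(orc_d2r(phi))^2 + B * cos(orc_d2r(phi)) + C
  for (t in terms) {
    j <- j + t$dchi *
      (t$D + t$E * cos(orc_d2r(t$xi * phi + t$F * abs(t$dchi)))^2)
  }
  j
}

## ribose J prediction straight from the registry tables (no package calls)
orc_ribose_j <- function(P, psi, reg) {
  nus <- c(nu1 = orc_nu(P, psi, 1), nu2 = orc_nu(P, psi, 2),
           nu3 = orc_nu(P, psi, 3))
  vapply(c("H1'H2'", "H2'H3'", "H3'H4'"), function(pair) {
    m <- reg$proton_torsion_map[[pair]]
    s <- reg$karplus_sets[[m$set]]
    orc_karplus(m$offset + m$slope * nus[[m$governing]],
                s$A, s$B, s$C, s$substituent_terms)
  }, numeric(1))
}

## brute-force two-state fit on a (0.5 deg, 0.5 deg, 0.01) grid
orc_two_state_grid <- function(jobs, reg, P_S = 163, psi_S = 38) {
  Pg <- seq(-90, 90, by = 0.5)
  psig <- seq(25, 50, by = 0.5)
  fg <- seq(0, 1, by = 0.01)
  grid <- expand.grid(P = Pg, psi = psig)
  JN <- t(vapply(seq_len(nrow(grid)),
                 function(i) orc_ribose_j(grid$P[i], grid$psi[i], reg),
                 numeric(3)))
  JS <- orc_ribose_j(P_S, psi_S, reg)
  best <- list(sse = Inf)
  for (f in fg) {
    pred <- f * JN + matrix((1 - f) * JS, nrow(JN), 3, byrow = TRUE)
    sse <- rowSums(sweep(pred, 2, jobs)^2)
    i <- which.min(sse)
    if (sse[i] < best$sse) {
      best <- list(sse = sse[i], P = grid$P[i], psi = grid$psi[i], f = f)
    }
  }
  best
}

## brute-force gamma rotamer fractions on a 0.005-step simplex grid
orc_rotamer_grid <- function(jobs, Jmat, step = 0.005) {
  f1 <- seq(0, 1, by = step)
  best <- list(sse = Inf)
  for (a in f1) {
    b <- seq(0, 1 - a, by = step)
    pred1 <- a * Jmat[1, 1] + b * Jmat[1, 2] + (1 - a - b) * Jmat[1, 3]
    pred2 <- a * Jmat[2, 1] + b * Jmat[2, 2] + (1 - a - b) * Jmat[2, 3]
    sse <- (pred1 - jobs[1])^2 + (pred2 - jobs[2])^2
    i <- which.min(sse)
    if (sse[i] < best$sse) {
      best <- list(sse = sse[i], f = c(a, b[i], 1 - a - b[i]))
    }
  }
  best
}

## exhaustive backbone torsion scan, duplicated implementation
orc_backbone_scan <- function(jobs, frag_specs, reg, step = 1) {
  grid <- seq(-180, 180 - step, by = step)
  sse <- vapply(grid, function(ang) {
    sum(vapply(seq_along(frag_specs), function(i) {
      s <- reg$karplus_sets[[frag_specs[[i]]$set]]
      (orc_karplus(ang + frag_specs[[i]]$offset, s$A, s$B, s$C) -
         jobs[i])^2
    }, numeric(1)))
  }, numeric(1))
  n <- length(grid)
  prv <- c(n, seq_len(n - 1)); nxt <- c(2:n, 1)
  mins <- which(sse < sse[prv] & sse <= sse[nxt])
  list(grid = grid, sse = sse, minima = grid[mins],
       min_sse = sse[mins])
}

## independent dihedral via explicit plane-normal construction
orc_dihedral <- function(p1, p2, p3, p4) {
  u <- p2 - p1; v <- p3 - p2; w <- p4 - p3
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cx(u, v); n2 <- cx(v, w)
  x <- sum(n1 * n2)
  y <- sum(cx(n1, n2) * v / sqrt(sum(v^2)))
  ang <- atan2(y, x) * 180 / pi
  ((ang + 180) %% 360) - 180
}

## rotation matrix from a unit quaternion
orc_quat_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## brute-force rigid-superposition RMSD: random quaternion search plus
## Nelder-Mead refinement of the best starts (independent of any SVD)
orc_min_rmsd <- function(A, B, n_starts = 4000) {
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  obj <- function(q) {
    R <- orc_quat_rot(q)
    sqrt(mean(rowSums((B0 %*% t(R) - A0)^2)))
  }
  qs <- matrix(rnorm(4 * n_starts), ncol = 4)
  vals <- apply(qs, 1, obj)
  best <- Inf
  for (i in order(vals)[1:5]) {
    r <- stats::optim(qs[i, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
    r <- stats::optim(r$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
    best <- min(best, r$value)
  }
  best
}

## random rigid transform applied to coordinates
orc_rigid_move <- function(X, angle_deg = 37) {
  ax <- c(1, 2, 3) / sqrt(14)
  th <- orc_d2r(angle_deg)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  sweep(X %*% t(R), 2, c(4.2, -1.3, 0.7), `+`)
}

## shared fixture: idealized CDN-like template frame
make_template <- function(chi = -149, P = 10, psi_m = 41, delta = 84) {
  tors <- list(alpha = 75, beta = -172, gamma = 53, delta = delta,
               epsilon = -155, zeta = 70, chi = chi, P = P, psi_m = psi_m)
  build_macrocycle_template(list(res1 = tors, res2 = tors))
}
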