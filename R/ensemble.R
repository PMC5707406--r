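## Conformer-ensemble container and torsion analytics.  An ensemble is a set
## of frames (identical atom ordering) over a cyclic di-nucleotide-like
## molecule; torsions follow the IUPAC nucleic-acid definitions with the
## macrocycle's 3'->5' wrap-around for alpha and zeta.

#' Create a conformer ensemble
#'
#' @param frames list of `n_atoms x 3` numeric coordinate matrices
#'   (Angstrom), one per conformer; identical atom count and ordering.
#' @param atoms data frame with columns `res_id` (integer), `res_name`,
#'   `atom_name`, one row per atom, in frame order.
#' @param cyclic logical: is the backbone a closed macrocycle (alpha/zeta
#'   wrap around the residue cycle)?
#' @param residue_order integer vector giving the 3'->5' linkage order of
#'   residues; defaults to the order of first appearance.
#' @return Object of class `"conformer_ensemble"`.
#' @export
conformer_ensemble <- function(frames, atoms, cyclic = TRUE,
                               residue_order = NULL) {
  if (!is.list(frames) || length(frames) == 0) {
    stop("'frames' must be a non-empty list of coordinate matrices",
         call. = FALSE)
  }
  frames <- lapply(frames, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  n_atoms <- nrow(frames[[1]])
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]) != n_atoms || ncol(frames[[i]]) != 3) {
      stop(sprintf("frame %d has %d atoms, expected %d (x 3 coordinates)",
                   i, nrow(frames[[i]]), n_atoms), call. = FALSE)
    }
    if (any(!is.finite(frames[[i]]))) {
      stop(sprintf("non-finite coordinates in frame %d", i), call. = FALSE)
    }
  }
  stopifnot(is.data.frame(atoms),
            all(c("res_id", "res_name", "atom_name") %in% names(atoms)),
            nrow(atoms) == n_atoms)
  if (is.null(residue_order)) residue_order <- unique(atoms$res_id)
  structure(list(frames = frames, atoms = atoms, cyclic = cyclic,
                 residue_order = residue_order),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d frame(s), %d atoms, %d residue(s)%s\n",
              length(x$frames), nrow(x$atoms),
              length(unique(x$atoms$res_id)),
              if (x$cyclic) ", cyclic" else ""))
  invisible(x)
}

#' Dihedral angle of four points
#'
#' Signed torsion (degrees, in `[-180, 180)`) about the `b`-`c` axis, by the
#' standard atan2 construction.  Each argument may be a single coordinate
#' triple or an `n x 3` matrix of parallel points.
#'
#' @param a,b,c,d coordinates (length-3 vectors or `n x 3` matrices).
#' @return numeric vector of dihedrals, degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  as_m <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 3)
  a <- as_m(a); b <- as_m(b); c <- as_m(c); d <- as_m(d)
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  cross <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  x <- rowSums(n1 * n2)
  y <- rowSums(cross(n1, n2) * b2 / sqrt(rowSums(b2^2)))
  wrap_angle(rad2deg(atan2(y, x)))
}

## named torsion definitions for residue i (j = linkage neighbour indices);
## each entry: atom spec list of (residue slot, atom name); slot "i" = this
## residue, "prev"/"next" = neighbours in 3'->5' order
torsion_atom_table <- function(base_n, base_c) {
  list(
    alpha = list(c("prev", "O3'"), c("i", "P"),   c("i", "O5'"), c("i", "C5'")),
    beta  = list(c("i", "P"),    c("i", "O5'"), c("i", "C5'"), c("i", "C4'")),
    gamma = list(c("i", "O5'"),  c("i", "C5'"), c("i", "C4'"), c("i", "C3'")),
    delta = list(c("i", "C5'"),  c("i", "C4'"), c("i", "C3'"), c("i", "O3'")),
    epsilon = list(c("i", "C4'"), c("i", "C3'"), c("i", "O3'"), c("next", "P")),
    zeta  = list(c("i", "C3'"),  c("i", "O3'"), c("next", "P"), c("next", "O5'")),
    chi   = list(c("i", "O4'"),  c("i", "C1'"), c("i", base_n), c("i", base_c)),
    nu0   = list(c("i", "C4'"),  c("i", "O4'"), c("i", "C1'"), c("i", "C2'")),
    nu1   = list(c("i", "O4'"),  c("i", "C1'"), c("i", "C2'"), c("i", "C3'")),
    nu2   = list(c("i", "C1'"),  c("i", "C2'"), c("i", "C3'"), c("i", "C4'")),
    nu3   = list(c("i", "C2'"),  c("i", "C3'"), c("i", "C4'"), c("i", "O4'")),
    nu4   = list(c("i", "C3'"),  c("i", "C4'"), c("i", "O4'"), c("i", "C1'"))
  )
}

#' Extract all nucleic-acid torsions from a conformer ensemble
#'
#' Computes, per residue and per frame, the glycosidic torsion `chi`
#' (`O4'-C1'-N9-C4` for purines, `O4'-C1'-N1-C2` for pyrimidines), the
#' backbone torsions `alpha`-`zeta` (with the macrocycle wrap-around:
#' `alpha` of a residue uses `O3'` of the preceding residue in the linkage
#' cycle, `epsilon`/`zeta` the `P`/`O5'` of the following one), the five
#' endocyclic torsions `nu0`-`nu4`, and the derived pseudorotation
#' parameters `P`, `psi_m`.
#'
#' @param e a [conformer_ensemble()].
#' @return Object of class `"torsion_series"`: named list `residues`, one
#'   data frame (frames x torsions) per residue, plus `n_frames`.
#' @export
compute_torsion_series <- function(e) {
  stopifnot(inherits(e, "conformer_ensemble"))
  coords <- e$frames
  n_frames <- length(coords)
  all_xyz <- do.call(rbind, coords)   # (n_frames * n_atoms) x 3, frame blocks
  n_atoms <- nrow(e$atoms)
  res_ids <- e$residue_order
  n_res <- length(res_ids)
  atom_idx <- function(rid, name) {
    which(e$atoms$res_id == rid & e$atoms$atom_name == name)
  }
  stacked <- function(idx) {  # coordinates of one atom across frames
    all_xyz[idx + n_atoms * (seq_len(n_frames) - 1L), , drop = FALSE]
  }
  out <- vector("list", n_res)
  names(out) <- paste0("res", res_ids)
  for (k in seq_len(n_res)) {
    rid <- res_ids[k]
    prev_rid <- res_ids[if (k == 1) n_res else k - 1]
    next_rid <- res_ids[if (k == n_res) 1 else k + 1]
    purine <- length(atom_idx(rid, "N9")) == 1
    tab <- torsion_atom_table(if (purine) "N9" else "N1",
                              if (purine) "C4" else "C2")
    if (!e$cyclic) {  # open chain: no wrap-around torsions at the ends
      if (k == 1) tab$alpha <- NULL
      if (k == n_res) tab$epsilon <- tab$zeta <- NULL
    }
    res <- matrix(NA_real_, nrow = n_frames, ncol = length(tab),
                  dimnames = list(NULL, names(tab)))
    for (tor in names(tab)) {
      pts <- lapply(tab[[tor]], function(spec) {
        r <- switch(spec[1], i = rid, prev = prev_rid, `next` = next_rid)
        idx <- atom_idx(r, spec[2])
        if (length(idx) != 1) {
          stop(sprintf(
            "residue %s: atom %s required for torsion %s is %s",
            r, spec[2], tor,
            if (length(idx) == 0) "missing" else "ambiguous"),
            call. = FALSE)
        }
        stacked(idx)
      })
      res[, tor] <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    }
    res <- as.data.frame(res)
    ## pseudorotation parameters, vectorized over frames
    num <- (res$nu4 + res$nu1) - (res$nu3 + res$nu0)
    den <- 2 * res$nu2 * (sind(36) + sind(72))
    P <- rad2deg(atan2(num, den))
    psi <- res$nu2 / cosd(P)
    flip <- is.finite(psi) & psi < 0
    P[flip] <- wrap_angle(P[flip] + 180)
    psi[flip] <- -psi[flip]
    res$P <- P
    res$psi_m <- psi
    out[[k]] <- res
  }
  structure(list(residues = out, n_frames = n_frames),
            class = "torsion_series")
}

#' @export
print.torsion_series <- function(x, ...) {
  cat(sprintf("<torsion_series> %d frame(s) x %d residue(s) [%s]\n",
              x$n_frames, length(x$residues),
              paste(names(x$residues), collapse = ", ")))
  invisible(x)
}

#' Conformational class frequencies over a torsion series
#'
#' Classifies every frame (pooled over residues unless `residue` is given)
#' with [classify_torsion()] and returns class frequencies summing to 1.
#'
#' @param s a [compute_torsion_series()] result.
#' @param scheme classification scheme (see [classify_torsion()]).
#' @param torsion which torsion column to classify; defaults to `"P"` for
#'   the pucker scheme and `"chi"` for the glycosidic scheme, and must be
#'   given explicitly for the rotamer scheme (e.g. `"gamma"`).
#' @param residue optional residue name (e.g. `"res1"`) to restrict to.
#' @return Named numeric vector of class fractions (all classes of the
#'   scheme, zeros included), summing to 1.
#' @export
population_fractions <- function(s, scheme = c("pucker", "glycosidic",
                                               "rotamer"),
                                 torsion = NULL, residue = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(s, "torsion_series"))
  if (is.null(torsion)) {
    torsion <- switch(scheme, pucker = "P", glycosidic = "chi",
                      rotamer = stop("'torsion' must be given for the ",
                                     "rotamer scheme", call. = FALSE))
  }
  res <- if (is.null(residue)) s$residues else s$residues[residue]
  vals <- unlist(lapply(res, function(df) df[[torsion]]), use.names = FALSE)
  if (length(vals) == 0) stop("empty torsion series", call. = FALSE)
  labels <- switch(scheme, pucker = c("N", "S"),
                   glycosidic = c("syn", "anti"),
                   rotamer = c("g+", "t", "g-"))
  cls <- factor(classify_torsion(vals, scheme), levels = labels)
  tab <- table(cls) / length(vals)
  stats::setNames(as.numeric(tab), labels)
}

#' Population-based free-energy landscape over the (chi, P) plane
#'
#' Bins the paired series on `[-180, 180)^2` and converts bin populations to
#' free energies by `G_i = -k_B * T * ln(N_i / N_max)` with
#' `k_B = 0.0019872 kcal/(mol K)`.  The most populated bin sits at exactly
#' `G = 0`; empty bins are `NA` (undefined), never 0.
#'
#' @param chi,P equal-length numeric series, degrees (any real values; they
#'   are wrapped).
#' @param nbins number of bins per axis (`>= 2`); default 72 (5-degree bins).
#' @param T temperature, K (`> 0`).
#' @return Object of class `"cdn_landscape"`: list with `breaks` (shared bin
#'   edges), `counts` and `G` (`nbins x nbins` matrices, chi rows x P
#'   columns), `T`, `k_B`.
#' @export
free_energy_landscape <- function(chi, P, nbins = 72, T = 300) {
  if (length(chi) != length(P)) {
    stop("'chi' and 'P' must have equal length", call. = FALSE)
  }
  if (!is.numeric(nbins) || nbins < 2) stop("'nbins' must be >= 2",
                                            call. = FALSE)
  check_scalar_finite(T, "T")
  if (T <= 0) stop("'T' must be > 0 (Kelvin)", call. = FALSE)
  k_B <- 0.0019872  # kcal / (mol K)
  breaks <- seq(-180, 180, length.out = nbins + 1)
  bx <- findInterval(wrap_angle(chi), breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  by <- findInterval(wrap_angle(P), breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0L, nbins, nbins)
  for (i in seq_along(bx)) counts[bx[i], by[i]] <- counts[bx[i], by[i]] + 1L
  G <- matrix(NA_real_, nbins, nbins)
  occ <- counts > 0
  G[occ] <- -k_B * T * log(counts[occ] / max(counts))
  structure(list(breaks = breaks, counts = counts, G = G, T = T, k_B = k_B),
            class = "cdn_landscape")
}

#' @export
print.cdn_landscape <- function(x, ...) {
  cat(sprintf(
    "<cdn_landscape> %d x %d bins at %g K; %d occupied, G range [0, %.2f] kcal/mol\n",
    nrow(x$G), ncol(x$G), x$T, sum(x$counts > 0),
    max(x$G, na.rm = TRUE)))
  invisible(x)
}

#' Plot a free-energy landscape
#'
#' @param x a [free_energy_landscape()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.cdn_landscape <- function(x, ...) {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  graphics::image(mids, mids, x$G, xlab = "chi [deg]", ylab = "P [deg]",
                  main = sprintf("G [kcal/mol] at %g K", x$T), ...)
  invisible(x)
}

#' Count and locate free-energy basins
#'
#' Labels connected components (8-neighbour, periodic in both angular axes)
#' of bins with defined `G` below `depth_threshold` and reports each basin's
#' minimum.  Basin structure is meaningful only when the landscape is well
#' sampled: isolated occupied rim bins otherwise count as basins of their
#' own.
#'
#' @param l a [free_energy_landscape()] result.
#' @param depth_threshold energy cutoff, kcal/mol (`> 0`).
#' @return List with `n_basins` and `basins`, a data frame (one row per
#'   basin, sorted by `G_min`) with columns `G_min`, `chi`, `P` (bin-centre
#'   location of the basin minimum) and `n_bins`.
#' @export
landscape_basins <- function(l, depth_threshold) {
  stopifnot(inherits(l, "cdn_landscape"))
  check_scalar_finite(depth_threshold, "depth_threshold")
  if (depth_threshold <= 0) stop("'depth_threshold' must be > 0 kcal/mol",
                                 call. = FALSE)
  G <- l$G
  n <- nrow(G)
  inb <- !is.na(G) & G < depth_threshold
  label <- matrix(0L, n, n)
  cur <- 0L
  wrap1 <- function(i) ((i - 1L) %% n) + 1L
  for (start in which(inb)) {
    if (label[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    label[start] <- cur
    while (length(queue) > 0) {
      cell <- queue[1]
      queue <- queue[-1]
      i <- ((cell - 1L) %% n) + 1L
      j <- ((cell - 1L) %/% n) + 1L
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        cid <- wrap1(i + di) + n * (wrap1(j + dj) - 1L)
        if (inb[cid] && label[cid] == 0L) {
          label[cid] <- cur
          queue <- c(queue, cid)
        }
      }
    }
  }
  mids <- (l$breaks[-1] + l$breaks[-length(l$breaks)]) / 2
  basins <- lapply(seq_len(cur), function(b) {
    cells <- which(label == b)
    gmin <- min(G[cells])
    at <- cells[which.min(G[cells])]
    data.frame(G_min = gmin,
               chi = mids[((at - 1L) %% n) + 1L],
               P = mids[((at - 1L) %/% n) + 1L],
               n_bins = length(cells))
  })
  basins <- if (cur > 0) do.call(rbind, basins) else
    data.frame(G_min = numeric(0), chi = numeric(0), P = numeric(0),
               n_bins = integer(0))
  basins <- basins[order(basins$G_min), , drop = FALSE]
  rownames(basins) <- NULL
  list(n_basins = cur, basins = basins)
}
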