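#' Standard 10/10 electrode montage on the unit sphere
#'
#' Constructs idealized spherical 10/10 electrode positions by the classical
#' arc construction: the vertex Cz at (0,0,1), midline electrodes on the
#' sagittal great circle in 18-degree (10%) steps, the circumferential 10%
#' ring (Fpz ... T7 ... Oz ... T8) at 72 degrees polar angle, and
#' intermediate electrodes by great-circle interpolation between the midline
#' and ring electrode of the same row. TP9/TP10 (mastoid proxies used for
#' linked-mastoid referencing) and Iz sit on the equator. The 32-channel set
#' is a strict subset of the 64-channel set.
#'
#' @param n_channels 32 or 64.
#' @return Object of class \code{"eeg_montage"}: \code{labels},
#'   \code{positions} (n x 3 unit rows), \code{n_channels}.
#' @export
build_montage <- function(n_channels = 64) {
  if (!n_channels %in% c(32L, 64L)) stop("unsupported channel count")
  pos <- montage_positions_64()
  if (n_channels == 32L) pos <- pos[montage_labels_32(), , drop = FALSE]
  structure(list(labels = rownames(pos), positions = pos,
                 n_channels = nrow(pos)),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels (10/10, unit sphere)\n",
              x$n_channels))
  invisible(x)
}

montage_labels_32 <- function() c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6",
  "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
  "P7", "P3", "Pz", "P4", "P8", "PO7", "O1", "Oz", "O2", "PO8")

# polar/azimuth -> cartesian; azimuth measured from front (+y) toward right (+x)
sph_pos <- function(polar_deg, az_deg) {
  th <- polar_deg * pi / 180
  az <- az_deg * pi / 180
  c(sin(th) * sin(az), sin(th) * cos(az), cos(th))
}

slerp <- function(p0, p1, t) {
  om <- acos(max(-1, min(1, sum(p0 * p1))))
  if (om < 1e-12) return(p0)
  (sin((1 - t) * om) * p0 + sin(t * om) * p1) / sin(om)
}

montage_positions_64 <- function() {
  P <- list()
  # circumferential 10% ring, polar 72, 18-degree azimuth steps from Fpz
  ring <- c("Fpz", "Fp2", "AF8", "F8", "FT8", "T8", "TP8", "P8", "PO8", "O2",
            "Oz", "O1", "PO7", "P7", "TP7", "T7", "FT7", "F7", "AF7", "Fp1")
  for (i in seq_along(ring)) P[[ring[i]]] <- sph_pos(72, (i - 1) * 18)
  # sagittal midline, 18-degree steps
  mid <- c(AFz = 54, Fz = 36, FCz = 18, Cz = 0, CPz = -18, Pz = -36,
           POz = -54)
  for (nm in names(mid)) {
    a <- mid[[nm]]
    P[[nm]] <- if (a >= 0) sph_pos(a, 0) else sph_pos(-a, 180)
  }
  # intermediate rows: great-circle interpolation midline -> 10% ring
  rows <- list(
    AF = list(mid = "AFz", ring = "AF7", left = c(AF3 = 0.5)),
    F  = list(mid = "Fz", ring = "F7",
              left = c(F1 = 0.25, F3 = 0.5, F5 = 0.75)),
    FC = list(mid = "FCz", ring = "FT7",
              left = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75)),
    C  = list(mid = "Cz", ring = "T7",
              left = c(C1 = 0.25, C3 = 0.5, C5 = 0.75)),
    CP = list(mid = "CPz", ring = "TP7",
              left = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75)),
    P  = list(mid = "Pz", ring = "P7",
              left = c(P1 = 0.25, P3 = 0.5, P5 = 0.75)),
    PO = list(mid = "POz", ring = "PO7", left = c(PO3 = 0.5)))
  mirror <- function(p) c(-p[1], p[2], p[3])
  right_of <- c(AF3 = "AF4", F1 = "F2", F3 = "F4", F5 = "F6", FC1 = "FC2",
                FC3 = "FC4", FC5 = "FC6", C1 = "C2", C3 = "C4", C5 = "C6",
                CP1 = "CP2", CP3 = "CP4", CP5 = "CP6", P1 = "P2", P3 = "P4",
                P5 = "P6", PO3 = "PO4")
  for (rw in rows) {
    for (nm in names(rw$left)) {
      p <- slerp(P[[rw$mid]], P[[rw$ring]], rw$left[[nm]])
      P[[nm]] <- p
      P[[right_of[[nm]]]] <- mirror(p)
    }
  }
  # below-ring electrodes on the equator
  P[["TP9"]] <- sph_pos(90, 252)
  P[["TP10"]] <- sph_pos(90, 108)
  P[["Iz"]] <- sph_pos(90, 180)
  M <- do.call(rbind, P)
  M <- M / sqrt(rowSums(M^2))
  rownames(M) <- names(P)
  stopifnot(nrow(M) == 64L)
  M
}

#' Import an electrode montage from CSV
#'
#' Reads a \code{label,x,y,z} table, projects the positions onto the unit
#' sphere and returns a montage usable wherever \code{\link{build_montage}}
#' output is.
#'
#' @param path CSV file with columns label, x, y, z.
#' @return an \code{eeg_montage}.
#' @export
read_montage_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("montage CSV needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$label)) stop("duplicate electrode labels")
  pos <- as.matrix(df[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(pos^2))
  if (any(nrm < 1e-12)) stop("electrode at the origin")
  pos <- pos / nrm
  rownames(pos) <- df$label
  structure(list(labels = df$label, positions = pos,
                 n_channels = nrow(pos)),
            class = "eeg_montage")
}

#' Regular source grid inside the brain compartment
#'
#' Cartesian grid of dipole locations strictly inside the innermost shell,
#' with three orthogonal unit orientations per location. Default spacing
#' yields roughly 250-300 in-brain locations — coarse, but enough support for
#' a whole-brain ROI covariance at desk scale.
#'
#' @param spacing grid step (scalp radius = 1); default 0.21.
#' @param r_brain brain compartment radius (default 0.87).
#' @param margin keep sources with |p| < margin * r_brain (default 0.9,
#'   guards the truncated series near the shell boundary).
#' @return Object of class \code{"source_grid"}: \code{positions} (n x 3),
#'   \code{orientations} (3 x 3 identity, shared), \code{n_sources}.
#' @export
source_grid <- function(spacing = 0.21, r_brain = 0.87, margin = 0.9) {
  if (spacing <= 0) stop("grid spacing must be > 0")
  g <- seq(-r_brain, r_brain, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  keep <- sqrt(rowSums(pts^2)) < margin * r_brain
  pts <- pts[keep, , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(positions = pts, orientations = diag(3),
                 n_sources = nrow(pts), spacing = spacing,
                 r_brain = r_brain),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d locations (spacing %.2f) x 3 orientations\n",
              x$n_sources, x$spacing))
  invisible(x)
}

# Legendre P_n(x) and derivative P_n'(x) for n = 1..N, x a vector.
# Returns list of N x length(x) matrices.
legendre_table <- function(x, N) {
  P <- matrix(0, N + 1, length(x))
  dP <- matrix(0, N + 1, length(x))
  P[1, ] <- 1; P[2, ] <- x
  dP[1, ] <- 0; dP[2, ] <- 1
  for (n in 2:N) {
    # rows are offset by one: row n+1 holds degree n
    P[n + 1, ] <- ((2 * n - 1) * x * P[n, ] - (n - 1) * P[n - 1, ]) / n
    dP[n + 1, ] <- dP[n - 1, ] + (2 * n - 1) * P[n, ]
  }
  list(P = P[-1, , drop = FALSE], dP = dP[-1, , drop = FALSE])
}

# Radial transfer factors f_n for a k-shell concentric sphere model:
# potential on the outer surface produced by a unit r^-(n+1) source harmonic
# in the innermost compartment. Solved per degree n from the interface
# continuity conditions (potential and sigma * dV/dr) plus the insulating
# outer boundary.
shell_transfer <- function(radii, cond, N) {
  k <- length(radii)
  stopifnot(length(cond) == k, !is.unsorted(radii))
  f <- numeric(N)
  for (n in seq_len(N)) {
    # unknowns: A_1, then (A_i, B_i) for shells 2..k
    nun <- 2 * k - 1
    M <- matrix(0, nun, nun)
    rhs <- numeric(nun)
    idxA <- function(i) if (i == 1) 1L else 2L * (i - 1)
    idxB <- function(i) 2L * (i - 1) + 1L  # shells >= 2 only
    row <- 0
    for (i in seq_len(k - 1)) {
      r <- radii[i]
      # potential continuity
      row <- row + 1
      M[row, idxA(i)] <- r^n
      if (i > 1) M[row, idxB(i)] <- r^(-(n + 1))
      M[row, idxA(i + 1)] <- -r^n
      M[row, idxB(i + 1)] <- -r^(-(n + 1))
      if (i == 1) rhs[row] <- -r^(-(n + 1))  # source term B_1 = 1
      # current continuity
      row <- row + 1
      M[row, idxA(i)] <- cond[i] * n * r^(n - 1)
      if (i > 1) M[row, idxB(i)] <- -cond[i] * (n + 1) * r^(-(n + 2))
      M[row, idxA(i + 1)] <- -cond[i + 1] * n * r^(n - 1)
      M[row, idxB(i + 1)] <- cond[i + 1] * (n + 1) * r^(-(n + 2))
      if (i == 1) rhs[row] <- cond[1] * (n + 1) * r^(-(n + 2))
    }
    # insulating outer boundary
    row <- row + 1
    R <- radii[k]
    M[row, idxA(k)] <- n * R^(n - 1)
    M[row, idxB(k)] <- -(n + 1) * R^(-(n + 2))
    sol <- solve(M, rhs)
    f[n] <- sol[idxA(k)] * R^n + sol[idxB(k)] * R^(-(n + 1))
  }
  f
}

# potential of one dipole at all electrodes (unit sphere positions * scalp R)
dipole_potential <- function(elec_unit, pos, mom, radii, cond, N,
                             transfer = NULL) {
  b <- sqrt(sum(pos^2))
  if (b >= radii[1]) stop("source outside brain compartment")
  if (is.null(transfer)) transfer <- shell_transfer(radii, cond, N)
  if (b < 1e-12) {
    zhat <- c(0, 0, 1)
    mr <- mom[3]; qt <- mom - mr * zhat
  } else {
    zhat <- pos / b
    mr <- sum(mom * zhat)
    qt <- mom - mr * zhat
  }
  mt <- sqrt(sum(qt^2))
  xhat <- if (mt > 1e-14) qt / mt else {
    v <- if (abs(zhat[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- v - sum(v * zhat) * zhat; v / sqrt(sum(v^2))
  }
  cth <- as.vector(elec_unit %*% zhat)
  cth <- pmax(-1, pmin(1, cth))
  sx <- as.vector(elec_unit %*% xhat)
  leg <- legendre_table(cth, N)
  nn <- seq_len(N)
  bn <- if (b < 1e-12) c(1, numeric(N - 1)) else b^(nn - 1)
  wn <- bn * transfer
  V <- as.vector(t(leg$P) %*% (wn * nn) * mr + (t(leg$dP) %*% wn) * sx * mt)
  V / (4 * pi * cond[1])
}

#' Analytic three-shell spherical leadfield
#'
#' Computes the channel x (source x orientation) gain matrix of a
#' concentric-3-sphere volume conductor (brain/skull/scalp) by the truncated
#' Legendre series solution of the dipole boundary-value problem. Default
#' shells: radii 0.87/0.92/1.0 of the scalp radius, conductivities
#' 1 : 1/50 : 1 (relative). The leadfield is referenced per \code{reference}:
#' average reference (columns sum to zero) or linked-mastoid (TP9/TP10 mean
#' subtracted), consistent with the recording convention.
#'
#' @param montage an \code{\link{eeg_montage}}.
#' @param grid a \code{\link{source_grid}}.
#' @param radii,conductivities 3-shell geometry (innermost first).
#' @param n_terms series truncation (default 60).
#' @param reference \code{"average"} or \code{"linked-mastoid"}.
#' @return Object of class \code{"leadfield"}: \code{L} (channels x
#'   3*n_sources), \code{montage}, \code{grid}, shell parameters.
#' @export
compute_leadfield <- function(montage, grid,
                              radii = c(0.87, 0.92, 1.0),
                              conductivities = c(1, 1 / 50, 1),
                              n_terms = 60,
                              reference = c("average", "linked-mastoid")) {
  reference <- match.arg(reference)
  stopifnot(inherits(montage, "eeg_montage"), inherits(grid, "source_grid"))
  if (any(sqrt(rowSums(grid$positions^2)) >= radii[1]))
    stop("source outside brain compartment")
  tr <- shell_transfer(radii, conductivities, n_terms)
  ns <- grid$n_sources
  L <- matrix(0, montage$n_channels, 3L * ns)
  for (s in seq_len(ns)) {
    for (o in 1:3) {
      L[, 3L * (s - 1L) + o] <- dipole_potential(
        montage$positions, grid$positions[s, ], grid$orientations[, o],
        radii, conductivities, n_terms, transfer = tr)
    }
  }
  L <- rereference_matrix(L, montage, reference)
  rownames(L) <- montage$labels
  structure(list(L = L, montage = montage, grid = grid, radii = radii,
                 conductivities = conductivities, n_terms = n_terms,
                 reference = reference),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf(
    "<leadfield> %d channels x %d columns (%d sources x 3, %s ref)\n",
    nrow(x$L), ncol(x$L), x$grid$n_sources, x$reference))
  invisible(x)
}

#' Leadfield for arbitrary dipoles (not on the grid)
#'
#' @param montage an \code{\link{eeg_montage}}.
#' @param positions n x 3 dipole locations (inside the brain shell).
#' @param moments n x 3 dipole moments.
#' @param radii,conductivities,n_terms as in \code{\link{compute_leadfield}}.
#' @param reference referencing applied to the output columns.
#' @return channels x n gain matrix.
#' @export
dipole_gain <- function(montage, positions, moments,
                        radii = c(0.87, 0.92, 1.0),
                        conductivities = c(1, 1 / 50, 1), n_terms = 60,
                        reference = c("average", "linked-mastoid")) {
  reference <- match.arg(reference)
  positions <- matrix(positions, ncol = 3)
  moments <- matrix(moments, ncol = 3)
  tr <- shell_transfer(radii, conductivities, n_terms)
  G <- sapply(seq_len(nrow(positions)), function(i)
    dipole_potential(montage$positions, positions[i, ], moments[i, ],
                     radii, conductivities, n_terms, transfer = tr))
  G <- matrix(G, nrow = montage$n_channels)
  rereference_matrix(G, montage, reference)
}

rereference_matrix <- function(L, montage, reference) {
  if (reference == "average") {
    sweep(L, 2, colMeans(L))
  } else {
    m <- match(c("TP9", "TP10"), montage$labels)
    if (anyNA(m)) {
      warning("TP9/TP10 not in montage; falling back to average reference")
      return(sweep(L, 2, colMeans(L)))
    }
    sweep(L, 2, colMeans(L[m, , drop = FALSE]))
  }
}

#' Region-of-interest signal covariance
#'
#' Channel-space covariance implied by unit-power uncorrelated sources in a
#' region of interest: \eqn{\Sigma_{ROI} = L_{ROI}\,\Sigma_s\,L_{ROI}^\top}.
#' The default ROI is the whole brain (all grid sources), the default source
#' covariance the identity.
#'
#' @param leadfield a \code{\link{leadfield}}.
#' @param source_indices grid locations in the ROI (default all).
#' @param source_cov source covariance (default identity), dimension
#'   3 * length(source_indices).
#' @return \code{cov_estimate} tagged \code{"roi"}.
#' @export
roi_covariance <- function(leadfield, source_indices = NULL,
                           source_cov = NULL) {
  stopifnot(inherits(leadfield, "leadfield"))
  ns <- leadfield$grid$n_sources
  if (is.null(source_indices)) source_indices <- seq_len(ns)
  if (length(source_indices) == 0) stop("empty ROI")
  if (!all(source_indices %in% seq_len(ns))) stop("ROI indices out of range")
  cols <- as.vector(t(outer(3L * (source_indices - 1L), 1:3, "+")))
  Lr <- leadfield$L[, cols, drop = FALSE]
  S <- if (is.null(source_cov)) tcrossprod(Lr) else {
    if (!isTRUE(all.equal(source_cov, t(source_cov), tolerance = 1e-8)))
      stop("source_cov must be symmetric")
    Lr %*% source_cov %*% t(Lr)
  }
  cov_estimate(S, 0L, 0, "roi")
}
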