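#' Pair-force laws for oracle systems
#'
#' `piecewise_linear_force` builds a force law that lies exactly in the span
#' of a hat-function spline basis (so the MS-CG solver can recover it to
#' numerical precision); `mie_force_law` is a smooth "realistic" law outside
#' the span, separating basis-approximation error from estimation error.
#' Both return a list with `f(r)`, `V(r)` and `r_max` (force is zero beyond
#' `r_max`; V is the integral of f from r to r_max).
#'
#' @param knots knot grid, nm.
#' @param values force values at the knots, kJ/mol/nm.
#' @export
piecewise_linear_force <- function(knots, values) {
  stopifnot(length(knots) == length(values), !is.unsorted(knots))
  f <- function(r) {
    out <- numeric(length(r))
    inside <- r >= knots[1] & r <= knots[length(knots)]
    out[inside] <- approx(knots, values, r[inside])$y
    out
  }
  # trapezoid integral is exact for a piecewise-linear integrand
  seg <- diff(knots) * (values[-1] + values[-length(values)]) / 2
  Icum <- rev(cumsum(rev(c(seg, 0))))
  V <- function(r) {
    out <- numeric(length(r))
    inside <- r >= knots[1] & r < knots[length(knots)]
    if (any(inside)) {
      k <- findInterval(r[inside], knots)
      fr <- approx(knots, values, r[inside])$y
      out[inside] <- Icum[k + 1] +
        (knots[k + 1] - r[inside]) * (fr + values[k + 1]) / 2
    }
    out[r < knots[1]] <- Icum[1] +
      values[1] * (knots[1] - r[r < knots[1]])
    out
  }
  list(f = f, V = V, r_min = knots[1], r_max = knots[length(knots)])
}

#' @rdname piecewise_linear_force
#' @param r_min_mie,epsilon Mie(9,6) parameters (nm, kJ/mol).
#' @param r_cut force truncation radius, nm.
#' @export
mie_force_law <- function(r_min_mie, epsilon, r_cut = 1.2) {
  list(f = function(r) ifelse(r < r_cut, mie96_force(r, r_min_mie, epsilon),
                              0),
       V = function(r) ifelse(r < r_cut,
                              mie96(r, r_min_mie, epsilon) -
                                mie96(r_cut, r_min_mie, epsilon), 0),
       r_min = 0, r_max = r_cut)
}

.fluid_forces <- function(pos, law, box) {
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- .minimum_image(pos[ij[, 1], , drop = FALSE] -
                        pos[ij[, 2], , drop = FALSE], box)
  r <- sqrt(rowSums(d^2))
  fr <- law$f(r) / r
  fv <- d * fr
  rs <- rowsum(rbind(fv, -fv), group = c(ij[, 1], ij[, 2]))
  F[as.integer(rownames(rs)), ] <- rs
  F
}

#' Synthetic fluid with exactly known pairwise forces
#'
#' Generates CG frames by overdamped (Brownian) Langevin sampling of a known
#' pair force law; the stored per-site forces are evaluated exactly from the
#' law, so the frames are an exact oracle for the MS-CG solver (they stand
#' in for force-matched all-atom reference trajectories). Newton's third law
#' holds exactly. Fixed seed gives bit-identical frames.
#'
#' @param n particle count.
#' @param law a force law from [piecewise_linear_force()] or
#'   [mie_force_law()].
#' @param temperature K.
#' @param n_frames number of frames to record.
#' @param seed RNG seed.
#' @param box periodic box (length-3, nm); default a cube sized for reduced
#'   density 0.3 relative to 0.5 nm spacing.
#' @param dt Brownian timestep (mobility 1 units).
#' @param stride steps between recorded frames.
#' @param n_equil equilibration steps.
#' @return list of frames, each `list(pos, forces, box)`.
#' @export
make_oracle_fluid <- function(n, law, temperature, n_frames, seed = 1L,
                              box = NULL, dt = 2e-5, stride = 25L,
                              n_equil = 500L) {
  set.seed(seed)
  if (is.null(box)) box <- rep(round((n / 0.3)^(1 / 3) * 0.5, 2), 3)
  # start on a lattice to avoid overlaps below the potential support
  m <- ceiling(n^(1 / 3))
  g <- seq(0, 1 - 1 / m, length.out = m) * box[1] + box[1] / (2 * m)
  lat <- as.matrix(expand.grid(x = g, y = g, z = g))[seq_len(n), ]
  pos <- lat + matrix(rnorm(3 * n, sd = 0.01), n, 3)
  kT <- KB * temperature
  sdstep <- sqrt(2 * kT * dt)
  frames <- vector("list", n_frames)
  total <- n_equil + n_frames * stride
  fcount <- 0L
  for (s in seq_len(total)) {
    F <- .fluid_forces(pos, law, box)
    pos <- pos + dt * F + matrix(rnorm(3 * n, sd = sdstep), n, 3)
    if (s > n_equil && (s - n_equil) %% stride == 0L) {
      fcount <- fcount + 1L
      p <- pos %% box[1]
      frames[[fcount]] <- list(pos = p, forces = .fluid_forces(p, law, box),
                               box = box)
    }
  }
  frames
}

#' Sample a bonded coordinate from a Boltzmann density
#'
#' I.i.d. rejection sampling from p(x) proportional to exp(-V(x)/kT) J(x),
#' with the Jacobian J = r^2 for bonds, sin(theta) for angles (degrees) and
#' 1 for torsions. Provides the generate-and-recover oracle for Boltzmann
#' inversion.
#'
#' @param kind `"bond"`, `"angle"` or `"torsion"`.
#' @param V potential function of the coordinate (nm or degrees), kJ/mol.
#' @param temperature K.
#' @param n number of samples.
#' @param seed RNG seed.
#' @param support sampling interval; defaults: bonds need an explicit
#'   interval, angles (0, 180), torsions (-180, 180).
#' @return numeric vector of samples.
#' @export
sample_bonded <- function(kind = c("bond", "angle", "torsion"), V,
                          temperature, n, seed = 1L, support = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (is.null(support)) {
    support <- switch(kind, bond = stop("bond sampling needs a support"),
                      angle = c(1e-6, 180), torsion = c(-180, 180))
  }
  kT <- KB * temperature
  jac <- switch(kind, bond = function(x) x^2,
                angle = function(x) sin(x * pi / 180),
                torsion = function(x) rep(1, length(x)))
  grid <- seq(support[1], support[2], length.out = 4096)
  dens <- exp(-(V(grid) - min(V(grid))) / kT) * jac(grid)
  M <- max(dens) * 1.05
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 1000L)
    x <- runif(m, support[1], support[2])
    keep <- runif(m) * M < exp(-(V(x) - min(V(grid))) / kT) * jac(x)
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

#' The published pair-minima force field
#'
#' Loads the shipped pair-minima parameter file (15 rows: location and depth
#' of the attractive minimum for every unordered pair of the five site
#' types) and builds the full set of soft-core Mie(9,6) stand-in tables.
#'
#' @param path optional alternative parameter file.
#' @param ... passed to [build_softcore()].
#' @return list with `minima` (data.frame) and `tables` (named list of 15
#'   `pair_table`s).
#' @export
table2_forcefield <- function(path = NULL, ...) {
  minima <- read_pair_minima(path)
  list(minima = minima, tables = build_softcore(minima, ...))
}

#' Idealised CG peptide
#'
#' Builds the topology and ideal-geometry coordinates for a toy CG chain:
#' consecutive backbone sites 0.38 nm apart (the trans C-alpha virtual bond
#' length) in an extended zig-zag or a helix-like spiral, sidechain sites
#' placed at fixed template offsets pointing away from the backbone axis.
#' No nonbonded pair starts below the table inner wall.
#'
#' @param sequence residue names (one- or three-letter).
#' @param geometry `"extended"` or `"helixlike"`.
#' @param scheme mapping scheme.
#' @param min_separation exclusion rule for the topology.
#' @return list(`topology`, `positions` (`n x 3`, nm)).
#' @export
toy_peptide <- function(sequence, geometry = c("extended", "helixlike"),
                        scheme = default_mapping_scheme(),
                        min_separation = 3L) {
  geometry <- match.arg(geometry)
  topo <- build_topology(sequence, scheme, min_separation)
  st <- topo$sites
  n_res <- max(st$residue_index)
  bb <- matrix(0, n_res, 3)
  if (geometry == "extended") {
    # zig-zag with 0.38 nm bonds, 120 degree backbone angles
    step_x <- 0.38 * sin(pi / 3)
    step_y <- 0.38 * cos(pi / 3)
    bb[, 1] <- (seq_len(n_res) - 1) * step_x
    bb[, 2] <- step_y * (seq_len(n_res) %% 2)
  } else {
    # helix-like: 0.15 nm rise, 100 degrees per residue; radius chosen so
    # consecutive C-alpha sites sit exactly 0.38 nm apart
    phi <- (seq_len(n_res) - 1) * 100 * pi / 180
    rad <- sqrt(0.38^2 - 0.15^2) / (2 * sin(50 * pi / 180))
    bb <- cbind(rad * cos(phi), rad * sin(phi),
                (seq_len(n_res) - 1) * 0.15)
  }
  pos <- matrix(0, nrow(st), 3)
  axis_out <- function(p) {
    d <- p - c(mean(bb[, 1]), mean(bb[, 2]), p[3])
    nd <- sqrt(sum(d[1:2]^2))
    if (nd < 1e-9) c(0, 1, 0) else c(d[1:2] / nd, 0)
  }
  for (r in seq_len(n_res)) {
    rows <- which(st$residue_index == r)
    for (i in rows) {
      si <- st$site_index[i]
      if (si == 0L) {
        pos[i, ] <- bb[r, ]
      } else {
        dir <- if (geometry == "extended") {
          c(0, ifelse(r %% 2 == 1, 1, -1) * 0, 1) # stack above the backbone
        } else axis_out(bb[r, ])
        pos[i, ] <- bb[r, ] + dir * 0.25 * si +
          c(0.03, 0.03, 0) * (si - 1)
      }
    }
  }
  list(topology = topo, positions = pos)
}

#' Synthetic all-atom stand-in structure
#'
#' Builds a deterministic, geometry-idealised heavy-atom structure for a
#' sequence (C-alpha trace plus every sidechain heavy atom the mapping
#' scheme expects), for tests that need a parseable structure when real PDB
#' entries are unavailable. This is a synthetic stand-in: residue counts,
#' atom names and connectivity are faithful; coordinates are idealised, not
#' experimental.
#'
#' @param sequence residue names (one- or three-letter).
#' @param scheme mapping scheme (determines which atoms exist).
#' @return a data.frame usable wherever a [read_pdb()] result is (`atom`,
#'   `resname`, `residue_index`, `x`, `y`, `z` in nm).
#' @export
synthetic_structure <- function(sequence, scheme = default_mapping_scheme()) {
  sequence <- parse_sequence(sequence)
  n_res <- length(sequence)
  step_x <- 0.38 * sin(pi / 3)
  step_y <- 0.38 * cos(pi / 3)
  rows <- list()
  for (r in seq_len(n_res)) {
    ca <- c((r - 1) * step_x, step_y * (r %% 2), 0)
    rows[[length(rows) + 1L]] <- data.frame(
      atom = "CA", resname = sequence[r], residue_index = r,
      x = ca[1], y = ca[2], z = ca[3], stringsAsFactors = FALSE)
    defs <- scheme[[sequence[r]]]
    for (k in seq_len(nrow(defs))) {
      atoms <- .scheme_atoms(defs[k, ])
      center <- ca + c(0, 0, 0.25 * defs$site_index[k]) +
        c(0.02, 0.02, 0) * (defs$site_index[k] - 1)
      offs <- 0.05 * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0))
      for (a in seq_along(atoms)) {
        p <- center + offs[a, ]
        rows[[length(rows) + 1L]] <- data.frame(
          atom = atoms[a], resname = sequence[r], residue_index = r,
          x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname synthetic_structure
#' @param path output PDB path.
#' @export
write_synthetic_pdb <- function(sequence, path,
                                scheme = default_mapping_scheme()) {
  st <- synthetic_structure(sequence, scheme)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
    seq_len(nrow(st)),
    ifelse(nchar(st$atom) < 4, paste0(" ", st$atom), st$atom),
    st$resname, st$residue_index, st$x * 10, st$y * 10, st$z * 10,
    substr(st$atom, 1, 1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
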