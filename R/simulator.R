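#' Simulation configuration
#'
#' Defaults follow the CG-MD protocol: 2 fs (0.002 ps) timestep, Langevin
#' thermostat with a 2 ps inverse friction constant, 1.2 nm nonbonded cutoff
#' with interactions exact within the cutoff every step (a Verlet pair list
#' with a 0.3 nm skin, rebuilt on the half-skin displacement criterion, is an
#' implementation detail).
#'
#' @param timestep integration timestep, ps.
#' @param inverse_friction Langevin inverse friction constant, ps (friction
#'   gamma = 1/inverse_friction; 0 inverse friction is not allowed, use
#'   `gamma = 0` via `inverse_friction = Inf` for pure velocity Verlet).
#' @param temperature thermostat temperature, K.
#' @param cutoff nonbonded cutoff, nm (must not exceed the table range).
#' @param skin neighbor-list skin, nm.
#' @param seed RNG seed (drives `set.seed`; fixed seed gives a
#'   bitwise-reproducible trajectory on one build).
#' @param stride steps between recorded frames/energies.
#' @param restraints optional data.frame `site`, `k` (kJ/mol/nm^2), `x`, `y`,
#'   `z` of harmonic position restraints.
#' @param box optional length-3 periodic box, nm.
#' @return a `sim_config` list.
#' @export
sim_config <- function(timestep = 0.002, inverse_friction = 2,
                       temperature = 300, cutoff = 1.2, skin = 0.3,
                       seed = 1L, stride = 100L, restraints = NULL,
                       box = NULL) {
  stopifnot(timestep > 0, cutoff > 0)
  structure(list(timestep = timestep,
                 gamma = if (is.infinite(inverse_friction)) 0
                         else 1 / inverse_friction,
                 temperature = temperature, cutoff = cutoff, skin = skin,
                 seed = as.integer(seed), stride = as.integer(stride),
                 restraints = restraints, box = box), class = "sim_config")
}

#' Default bonded interaction terms for a topology
#'
#' Compiles the topology's bonded lists into evaluable terms: harmonic bonds
#' (0.38 nm backbone virtual bonds, 0.25 nm sidechain attachments by
#' default), harmonic or quartic angles, the sequence-dependent backbone
#' torsion library, and planarity impropers for Trp/Tyr. All pieces are
#' overridable with fitted potentials from the Boltzmann-inversion module.
#'
#' @param topology a `cg_topology`.
#' @param bond_k,bond_r0_bb,bond_r0_sc harmonic bond parameters (kJ/mol/nm^2,
#'   nm).
#' @param backbone_angle a `polynomial_potential` in degrees (e.g. from
#'   [backbone_angle_potential()]) used for every backbone angle, or `NULL`
#'   for a harmonic default about 120 degrees.
#' @param angle_k,angle_theta0 harmonic defaults for non-backbone angles
#'   (kJ/mol/rad^2, degrees).
#' @param torsion_library a `torsion_library` keyed by middle residue pair,
#'   or `NULL` for no backbone torsion terms.
#' @param improper_k,improper_phi0 harmonic improper parameters (kJ/mol/rad^2,
#'   degrees).
#' @return a `bonded_terms` list of index/coefficient matrices consumed by
#'   the engine.
#' @export
default_bonded_terms <- function(topology, bond_k = 20000, bond_r0_bb = 0.38,
                                 bond_r0_sc = 0.25, backbone_angle = NULL,
                                 angle_k = 100, angle_theta0 = 110,
                                 torsion_library = NULL, improper_k = 100,
                                 improper_phi0 = 0) {
  st <- topology$sites
  b <- topology$bonds
  bonds_coef <- matrix(0, nrow(b), 6)
  for (r in seq_len(nrow(b))) {
    bb <- st$site_type[b[r, 1]] == "backbone" &&
      st$site_type[b[r, 2]] == "backbone"
    bonds_coef[r, ] <- c(if (bb) bond_r0_bb else bond_r0_sc, 0, 0,
                         bond_k / 2, 0, 0)
  }
  a <- topology$angles
  angles_coef <- matrix(0, nrow(a), 6)
  deg <- pi / 180
  for (r in seq_len(nrow(a))) {
    if (a$tag[r] == "backbone" && !is.null(backbone_angle)) {
      angles_coef[r, ] <- .poly_deg_to_rad(backbone_angle)
    } else {
      angles_coef[r, ] <- c(angle_theta0 * deg, 0, 0, angle_k / 2, 0, 0)
    }
  }
  tt <- topology$torsions
  if (!is.null(torsion_library) && nrow(tt)) {
    keys <- paste(tt$res1, tt$res2)
    missing <- setdiff(keys, names(torsion_library))
    if (length(missing)) stop("torsion library missing pair(s): ",
                              paste(unique(missing), collapse = ", "))
    torsions_cos <- t(vapply(keys, function(k) torsion_library[[k]]$a,
                             numeric(5)))
    torsions_sin <- t(vapply(keys, function(k) {
      bterm <- torsion_library[[k]]$b
      if (is.null(bterm)) numeric(4) else bterm
    }, numeric(4)))
    torsions_idx <- as.matrix(tt[, c("i", "j", "k", "l")])
  } else {
    torsions_idx <- matrix(integer(), 0, 4)
    torsions_cos <- matrix(0, 0, 5)
    torsions_sin <- matrix(0, 0, 4)
  }
  im <- topology$impropers
  impropers_par <- if (nrow(im)) {
    cbind(rep(improper_k, nrow(im)), rep(improper_phi0 * deg, nrow(im)))
  } else matrix(0, 0, 2)
  structure(list(bonds_idx = b, bonds_coef = bonds_coef,
                 angles_idx = as.matrix(a[, c("i", "j", "k")]),
                 angles_coef = angles_coef,
                 torsions_idx = torsions_idx, torsions_cos = torsions_cos,
                 torsions_sin = torsions_sin,
                 impropers_idx = im, impropers_par = impropers_par),
            class = "bonded_terms")
}

# convert a polynomial_potential fit in degrees to radian coefficients
.poly_deg_to_rad <- function(pot) {
  k <- 180 / pi
  coefs <- pot$coefficients
  coefs <- c(coefs, rep(0, 5 - length(coefs)))[1:5]
  c(pot$x0 * pi / 180, coefs * k^(0:4))
}

# assemble the engine system list
.compile_system <- function(topology, tables, bonded, config) {
  st <- topology$sites
  types <- sort(unique(st$site_type))
  type_idx <- match(st$site_type, types) - 1L
  K <- length(types)
  paircol <- rep(-1L, K * K)
  tab_list <- list()
  for (nm in names(tables)) {
    pot <- tables[[nm]]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    ia <- match(parts[1], types)
    ib <- match(parts[2], types)
    if (is.na(ia) || is.na(ib)) next
    dr <- diff(pot$r)
    if (max(abs(dr - dr[1])) > 1e-9) stop("table grid must be uniform: ", nm)
    if (config$cutoff > max(pot$r) + 1e-9) {
      stop("cutoff exceeds table range for ", nm)
    }
    tab_list[[length(tab_list) + 1L]] <-
      list(r0 = pot$r[1], dr = dr[1], f = pot$f)
    ci <- length(tab_list) - 1L
    paircol[(ia - 1L) * K + ib] <- ci
    paircol[(ib - 1L) * K + ia] <- ci
  }
  present <- unique(type_idx)
  for (ta in present) for (tb in present) {
    if (paircol[ta * K + tb + 1L] < 0) {
      stop("no pair table for types ", types[ta + 1L], "|", types[tb + 1L])
    }
  }
  if (is.null(bonded)) bonded <- .empty_bonded()
  rst <- config$restraints
  if (is.null(rst) || nrow(rst) == 0L) {
    restraints_idx <- matrix(integer(), 0, 1)
    restraints_par <- matrix(0, 0, 4)
  } else {
    restraints_idx <- matrix(as.integer(rst$site), ncol = 1)
    restraints_par <- cbind(rst$k, rst$x, rst$y, rst$z)
  }
  list(mass = st$mass, type = type_idx, K = K, paircol = paircol,
       tables = tab_list, cutoff = config$cutoff,
       exclusions = .as_int_matrix(topology_exclusions(topology)),
       box = if (is.null(config$box)) numeric(0) else as.numeric(config$box),
       bonds_idx = .as_int_matrix(bonded$bonds_idx),
       bonds_coef = .as_num_matrix(bonded$bonds_coef, 6),
       angles_idx = .as_int_matrix(bonded$angles_idx),
       angles_coef = .as_num_matrix(bonded$angles_coef, 6),
       torsions_idx = .as_int_matrix(bonded$torsions_idx),
       torsions_cos = .as_num_matrix(bonded$torsions_cos, 5),
       torsions_sin = .as_num_matrix(bonded$torsions_sin, 4),
       impropers_idx = .as_int_matrix(bonded$impropers_idx),
       impropers_par = .as_num_matrix(bonded$impropers_par, 2),
       restraints_idx = .as_int_matrix(restraints_idx),
       restraints_par = .as_num_matrix(restraints_par, 4))
}

.empty_bonded <- function() {
  structure(list(bonds_idx = matrix(integer(), 0, 2),
                 bonds_coef = matrix(0, 0, 6),
                 angles_idx = matrix(integer(), 0, 3),
                 angles_coef = matrix(0, 0, 6),
                 torsions_idx = matrix(integer(), 0, 4),
                 torsions_cos = matrix(0, 0, 5),
                 torsions_sin = matrix(0, 0, 4),
                 impropers_idx = matrix(integer(), 0, 4),
                 impropers_par = matrix(0, 0, 2)), class = "bonded_terms")
}

.as_int_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  m
}

.as_num_matrix <- function(m, ncol) {
  if (is.null(m) || length(m) == 0L) return(matrix(0, 0, ncol))
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  m
}

#' Forces and energy decomposition for a CG configuration
#'
#' Nonbonded contributions come from linear interpolation of the tabulated
#' force within the cutoff (energies are the exact integral of the
#' interpolated force, so forces are exact negative gradients of the
#' energy); excluded pairs are skipped; bonded terms are evaluated from the
#' compiled polynomial/cosine-series coefficients. Separations below the
#' table support hit the capped inner wall and are counted in `wall_hits`.
#'
#' @param positions `n x 3` matrix, nm.
#' @param topology a `cg_topology`.
#' @param tables named list of `pair_table`s covering every site-type pair
#'   present.
#' @param bonded a `bonded_terms` (or `NULL` for none).
#' @param config a [sim_config()].
#' @return list with `forces` (kJ/mol/nm), `e_bonded`, `e_nonbonded`,
#'   `e_restraint` (kJ/mol), `wall_hits`.
#' @export
compute_forces <- function(positions, topology, tables, bonded = NULL,
                           config = sim_config()) {
  sys <- .compile_system(topology, tables, bonded, config)
  .cg_forces_cpp(as.matrix(positions), sys)
}

#' Run Langevin CG molecular dynamics
#'
#' BAOAB-discretised Langevin dynamics (friction gamma = 1/inverse_friction;
#' gamma = 0 reduces exactly to velocity Verlet). Velocities are drawn from
#' the Maxwell-Boltzmann distribution at the configured temperature unless
#' supplied. Fixed seed implies a restart-identical trajectory.
#'
#' @inheritParams compute_forces
#' @param n_steps number of integration steps (0 records the initial frame
#'   only).
#' @param velocities optional `n x 3` starting velocities, nm/ps.
#' @param set_seed set the RNG from `config$seed` (disable when an outer
#'   driver manages the RNG stream, e.g. REMD).
#' @return a `cg_trajectory`: `positions` (`n x 3 x n_frames` array, frame
#'   stride `config$stride`), `energies` (data.frame: time, bonded,
#'   nonbonded, restraint, kinetic), `final_pos`, `final_vel`, `wall_hits`,
#'   `config`.
#' @export
run_cg_md <- function(topology, tables, bonded, config, n_steps,
                      positions, velocities = NULL, set_seed = TRUE) {
  sys <- .compile_system(topology, tables, bonded, config)
  positions <- as.matrix(positions)
  if (set_seed) set.seed(config$seed)
  if (is.null(velocities)) {
    velocities <- maxwell_velocities(topology$sites$mass, config$temperature)
  }
  res <- .cg_run_cpp(positions, as.matrix(velocities), sys,
                     as.integer(n_steps), config$timestep, config$gamma,
                     config$temperature, config$stride, config$skin)
  en <- as.data.frame(res$energies)
  en$potential <- en$bonded + en$nonbonded + en$restraint
  structure(list(positions = res$positions, energies = en,
                 final_pos = res$final_pos, final_vel = res$final_vel,
                 wall_hits = res$wall_hits, config = config),
            class = "cg_trajectory")
}

#' Maxwell-Boltzmann velocities
#' @param masses site masses, amu.
#' @param temperature K.
#' @return `n x 3` matrix, nm/ps.
#' @export
maxwell_velocities <- function(masses, temperature) {
  n <- length(masses)
  matrix(rnorm(3 * n, sd = sqrt(KB * temperature / masses)), n, 3)
}

#' High-temperature chain randomization
#'
#' Equilibrates the chain at a high temperature (700 K by default) and
#' returns the final frame as an extended/unfolded starting structure.
#'
#' @inheritParams run_cg_md
#' @param T_high randomization temperature, K.
#' @param steps number of steps.
#' @param seed RNG seed.
#' @return `n x 3` coordinate matrix.
#' @export
randomize_chain <- function(topology, tables, bonded, positions,
                            T_high = 700, steps = 50000L, seed = 1L,
                            config = sim_config()) {
  config$temperature <- T_high
  config$seed <- as.integer(seed)
  config$stride <- max(1L, as.integer(steps))
  traj <- run_cg_md(topology, tables, bonded, config, steps, positions)
  traj$final_pos
}

#' @export
print.cg_trajectory <- function(x, ...) {
  nf <- dim(x$positions)[3]
  cat("CG trajectory:", dim(x$positions)[1], "sites,", nf, "frames",
      sprintf("(%.4g ps)", x$energies$time[nf]), "\n")
  invisible(x)
}

#' Write the energy log of a trajectory as TSV
#' @param traj a `cg_trajectory`.
#' @param path output file.
#' @export
write_energy_log <- function(traj, path) {
  write.table(traj$energies, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
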