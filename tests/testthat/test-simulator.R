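test_that("nonbonded forces: cutoff, table lookup, exclusions", {
  ff <- tbl2()
  topo <- free_sites_topology(2, type = "apolar")
  cfg <- sim_config()
  # beyond cutoff: exactly zero
  far <- compute_forces(rbind(c(0, 0, 0), c(1.3, 0, 0)), topo, ff$tables,
                        NULL, cfg)
  expect_equal(max(abs(far$forces)), 0)
  expect_equal(far$e_nonbonded, 0)
  # at a table grid point the force equals the tabulated value
  pot <- ff$tables[["apolar|apolar"]]
  k <- 300L
  at <- compute_forces(rbind(c(0, 0, 0), c(pot$r[k], 0, 0)), topo,
                       ff$tables, NULL, cfg)
  expect_equal(at$forces[2, 1], pot$f[k], tolerance = 1e-10)
  # 1-2 and 1-3 pairs contribute exactly zero nonbonded energy
  t3 <- build_topology("GGG")
  pos3 <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.55, 0.2, 0))
  fr3 <- compute_forces(pos3, t3, ff$tables, NULL, cfg)
  expect_equal(fr3$e_nonbonded, 0)
  # missing pair table errors
  expect_error(compute_forces(rbind(c(0, 0, 0), c(0.5, 0, 0)),
                              free_sites_topology(2, type = "polar"),
                              ff$tables["apolar|apolar"], NULL, cfg),
               "pair table")
})

test_that("forces are exact negative gradients for every term class", {
  ff <- tbl2()
  tp <- toy_peptide("SWTWENGKWTWK")
  res <- unname(mscg:::.AA3)
  lib <- build_torsion_library(
    data.frame(res1 = rep(res, each = 20), res2 = rep(res, 20),
               a0 = 0, a1 = 0.5, a2 = 0.3, a3 = 0.1, a4 = 0.05), 0.54)
  bonded <- default_bonded_terms(tp$topology, torsion_library = lib)
  bonded$torsions_sin[, 1] <- 0.3  # exercise the sine branch too
  cfg <- sim_config()
  set.seed(11)
  pos <- tp$positions + matrix(rnorm(length(tp$positions), sd = 0.02),
                               ncol = 3)
  fr <- compute_forces(pos, tp$topology, ff$tables, bonded, cfg)
  h <- 1e-6
  worst <- 0
  for (trial in seq_len(40)) {
    i <- sample(nrow(pos), 1); c <- sample(3, 1)
    pp <- pos; pp[i, c] <- pp[i, c] + h
    pm <- pos; pm[i, c] <- pm[i, c] - h
    ep <- compute_forces(pp, tp$topology, ff$tables, bonded, cfg)
    em <- compute_forces(pm, tp$topology, ff$tables, bonded, cfg)
    num <- -((ep$e_bonded + ep$e_nonbonded) -
               (em$e_bonded + em$e_nonbonded)) / (2 * h)
    worst <- max(worst, abs(num - fr$forces[i, c]) /
                   max(1, abs(fr$forces[i, c])))
  }
  expect_lt(worst, 1e-4)
  # momentum: total force is zero without restraints/box
  expect_lt(max(abs(colSums(fr$forces))),
            1e-10 * max(1, max(abs(fr$forces))))
})

test_that("gamma = 0 integrator conserves energy and reduces to Verlet", {
  hd <- harmonic_dimer(k = 1000)
  ff <- tbl2()
  cfg <- sim_config(inverse_friction = Inf, stride = 100L, seed = 42L)
  pos <- rbind(c(0, 0, 0), c(0.40, 0, 0))
  # zero forces: straight-line motion
  hd0 <- harmonic_dimer(k = 0, r0 = 0.38)
  tr0 <- run_cg_md(free_sites_topology(1), ff$tables, empty_bonded(),
                   cfg, 1000L, matrix(0, 1, 3),
                   velocities = matrix(c(0.1, 0, 0), 1))
  expect_equal(tr0$final_pos[1, 1], 0.1 * 1000 * cfg$timestep,
               tolerance = 1e-10)
  # harmonic dimer, 1e5 steps: bounded energy oscillation, no secular drift
  traj <- run_cg_md(hd$topology, ff$tables, hd$bonded, cfg, 1e5, pos)
  E <- traj$energies$potential + traj$energies$kinetic
  n <- length(E)
  drift <- abs(mean(E[(n - 99):n]) - mean(E[1:100])) / abs(mean(E))
  expect_lt(drift, 1e-4)
  expect_lt((max(E) - min(E)) / abs(mean(E)), 5e-3)
})

test_that("trajectories are seed-reproducible and restart-identical", {
  hd <- harmonic_dimer()
  ff <- tbl2()
  cfg <- sim_config(seed = 9L, stride = 50L)
  pos <- rbind(c(0, 0, 0), c(0.40, 0, 0))
  t1 <- run_cg_md(hd$topology, ff$tables, hd$bonded, cfg, 2000L, pos)
  t2 <- run_cg_md(hd$topology, ff$tables, hd$bonded, cfg, 2000L, pos)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$energies, t2$energies)
  # 0 steps: initial frame only
  t0 <- run_cg_md(hd$topology, ff$tables, hd$bonded, cfg, 0L, pos)
  expect_equal(dim(t0$positions)[3], 1L)
  expect_equal(t0$positions[, , 1], pos)
})

test_that("equipartition: restrained site at 300 K", {
  topo <- free_sites_topology(1)
  cfg <- oscillator_config(k = 1000, temperature = 300, seed = 7L,
                           inverse_friction = 0.2, stride = 10L)
  tr <- run_cg_md(topo, tbl2()$tables, empty_bonded(), cfg, 1e6,
                  matrix(0, 1, 3))
  burn <- seq_len(2e3)
  x <- tr$positions[1, 1, -burn]
  x2 <- mean(x^2)
  expect_gt(length(x), 9e4)
  # <x^2> = kT/k within 3 standard errors (correlation time ~ gamma/k ...
  # conservatively ~0.5 ps = 25 recorded samples)
  n_eff <- length(x) / 25
  se <- sqrt(2 / n_eff) * mscg::KB * 300 / 1000
  expect_lt(abs(x2 - mscg::KB * 300 / 1000), 3 * se)
  # kinetic temperature within 2% of the set point
  Tk <- mean(tr$energies$kinetic[-seq_len(200)]) / (1.5 * mscg::KB)
  expect_lt(abs(Tk - 300) / 300, 0.02)
})

test_that("restraints bound the backbone deviation", {
  tp <- toy_peptide("AAAAA")
  bb <- which(tp$topology$sites$site_type == "backbone")
  k_rst <- 1000
  cfg <- sim_config(temperature = 300, seed = 3L, stride = 100L,
                    restraints = data.frame(site = bb, k = k_rst,
                                            x = tp$positions[bb, 1],
                                            y = tp$positions[bb, 2],
                                            z = tp$positions[bb, 3]))
  bonded <- default_bonded_terms(tp$topology)
  traj <- run_cg_md(tp$topology, tbl2()$tables, bonded, cfg, 2e4,
                    tp$positions)
  # harmonic estimate: <dr^2> = 3kT/k per site; allow 4x for the tail
  final_dev <- sqrt(mean(rowSums((traj$final_pos[bb, ] -
                                    tp$positions[bb, ])^2)))
  expect_lt(final_dev, 4 * sqrt(3 * mscg::KB * 300 / k_rst))
})

test_that("randomize_chain yields valid, seed-dependent extended starts", {
  tp <- toy_peptide("AAAAAAAAAA")
  ff <- tbl2()
  bonded <- default_bonded_terms(tp$topology)
  r1 <- randomize_chain(tp$topology, ff$tables, bonded, tp$positions,
                        steps = 5000L, seed = 1L)
  r2 <- randomize_chain(tp$topology, ff$tables, bonded, tp$positions,
                        steps = 5000L, seed = 2L)
  expect_gt(rmsd(r1, r2), 0)
  # no nonbonded pair below the table inner wall
  ex <- topology_exclusions(tp$topology)
  n <- nrow(r1)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ek <- ex[, 1] + n * ex[, 2]
  keep <- !(ij[, 1] + n * ij[, 2]) %in% ek
  d <- sqrt(rowSums((r1[ij[keep, 1], ] - r1[ij[keep, 2], ])^2))
  expect_gt(min(d), 0.04)
  # hot runs are more expanded on average than cold runs
  cfg_hot <- sim_config(temperature = 700, seed = 5L, stride = 200L)
  cfg_cold <- sim_config(temperature = 150, seed = 5L, stride = 200L)
  hot <- run_cg_md(tp$topology, ff$tables, bonded, cfg_hot, 3e4,
                   tp$positions)
  cold <- run_cg_md(tp$topology, ff$tables, bonded, cfg_cold, 3e4,
                    tp$positions)
  rg_of <- function(traj) {
    mean(frame_metric(traj$positions, radius_of_gyration)[-(1:50)])
  }
  expect_gt(rg_of(hot), rg_of(cold))
})

test_that("non-finite forces abort with a diagnostic", {
  hd <- harmonic_dimer(k = 1e12)  # absurd stiffness blows up the integrator
  cfg <- sim_config(inverse_friction = Inf, stride = 10L, seed = 1L)
  expect_error(
    run_cg_md(hd$topology, tbl2()$tables, hd$bonded, cfg, 1000L,
              rbind(c(0, 0, 0), c(0.9, 0, 0))),
    "non-finite")
})
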