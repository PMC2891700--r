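# shared small fluid fixture for the solver tests (piecewise-linear law in
# the basis span, so recovery is exact up to numerics)
fm_basis <- spline_basis(0.3, 1.2, 0.05)
fm_vals <- c(80, 50, 25, 10, -2, -8, -6, -3, -1.5, -0.8, -0.4, -0.2,
             -0.1, -0.05, 0, 0, 0, 0, 0)
fm_law <- piecewise_linear_force(fm_basis$knots, fm_vals)
fm_frames <- make_oracle_fluid(27, fm_law, temperature = 300,
                               n_frames = 200, seed = 2)

test_that("spline basis invariants hold", {
  expect_true(all(diff(fm_basis$knots) > 0))
  expect_error(spline_basis(1.0, 0.5))
  # hat weights of any distance sum to 1 (checked via a two-particle system)
  r <- 0.437
  fr <- list(pos = rbind(c(0, 0, 0), c(r, 0, 0)),
             forces = rbind(c(-1, 0, 0), c(1, 0, 0)), box = NULL)
  sys <- build_block(list(fr), fm_basis, "apolar")
  expect_equal(sum(sys$samples), 1, tolerance = 1e-12)
})

test_that("single pair at a knot is solved exactly; exclusions empty the system", {
  # separation exactly on a knot, known equal/opposite force
  d <- fm_basis$knots[6]
  f0 <- -8
  fr <- list(pos = rbind(c(0, 0, 0), c(d, 0, 0)),
             forces = rbind(c(-f0, 0, 0), c(f0, 0, 0)), box = NULL)
  sol <- solve_block(build_block(list(fr), fm_basis, "apolar"))
  expect_equal(unname(sol$f[6, 1]), f0, tolerance = 1e-10)
  expect_lt(sol$residual, 1e-8)
  # all pairs excluded -> error
  expect_error(build_block(list(fr), fm_basis, "apolar",
                           exclusions = cbind(1L, 2L)), "no interacting")
})

test_that("noiseless synthetic fluid is recovered to numerical precision", {
  curves <- solve_mscg(fm_frames[1:50], fm_basis, "apolar", block_size = 50)
  cu <- curves[["apolar|apolar"]]
  mask <- cu$n_samples > 20
  expect_gt(sum(mask), 10)
  expect_lt(max(abs(cu$f[mask] - fm_vals[mask])), 1e-8)
  # well-sampled RMS deviation < 2% of the max force magnitude
  expect_lt(sqrt(mean((cu$f[mask] - fm_vals[mask])^2)),
            0.02 * max(abs(fm_vals)))
})

test_that("solve_block: duplicate frames, permutation invariance, min-norm", {
  s1 <- solve_block(build_block(fm_frames[1:20], fm_basis, "apolar"))
  s2 <- solve_block(build_block(c(fm_frames[1:20], fm_frames[1:20]),
                                fm_basis, "apolar"))
  expect_equal(s1$f, s2$f, tolerance = 1e-9)
  s3 <- solve_block(build_block(rev(fm_frames[1:20]), fm_basis, "apolar"))
  expect_equal(s1$f, s3$f, tolerance = 1e-9)
  # unsampled knots resolved to zero by the minimum-norm convention
  # (single-pair system leaves most knots unsampled)
  one <- solve_block(build_block(list(list(
    pos = rbind(c(0, 0, 0), c(0.55, 0, 0)),
    forces = rbind(c(-2, 0, 0), c(2, 0, 0)), box = NULL)),
    fm_basis, "apolar"))
  expect_true(any(!one$sampled[, 1]))
  expect_equal(unname(one$f[!one$sampled[, 1], 1]),
               rep(0, sum(!one$sampled[, 1])))
  expect_error(solve_block(structure(list(samples = 0), class = "mscg_system")),
               "empty")
})

test_that("design matrix encodes Newton's third law", {
  # each pair contributes with opposite signs to its two sites' rows, so
  # any column of A sums to zero over each coordinate: a net-translation
  # force pattern (identical forces on both partners) projects to b = 0
  d <- 0.55
  fsym <- rbind(c(2, -1, 3), c(2, -1, 3))
  sys <- build_block(list(list(pos = rbind(c(0, 0, 0), c(0, d, 0)),
                               forces = fsym, box = NULL)),
                     fm_basis, "apolar")
  expect_equal(max(abs(sys$b)), 0, tolerance = 1e-12)
  # while the antisymmetric pattern is fit exactly
  f0 <- 3
  fr2 <- list(pos = rbind(c(0, 0, 0), c(0, d, 0)),
              forces = rbind(c(0, -f0, 0), c(0, f0, 0)), box = NULL)
  sol2 <- solve_block(build_block(list(fr2), fm_basis, "apolar"))
  expect_equal(sum(sol2$f[, 1] * sol2$samples[, 1]), f0, tolerance = 1e-9)
  expect_lt(sol2$residual, 1e-8)
})

test_that("block averaging: mean, cancellation, 1/sqrt(n) error shrinkage", {
  sols <- lapply(split(seq_len(200), rep(1:10, each = 20)), function(ii) {
    solve_block(build_block(fm_frames[ii], fm_basis, "apolar"))
  })
  # identical blocks: mean equals the block, stderr 0
  avg_same <- average_blocks(list(sols[[1]], sols[[1]], sols[[1]]))
  cu <- avg_same[["apolar|apolar"]]
  expect_equal(cu$f[sols[[1]]$sampled[, 1]],
               sols[[1]]$f[sols[[1]]$sampled[, 1], 1], tolerance = 1e-12)
  expect_equal(max(cu$stderr), 0)
  # v and -v average to 0
  sneg <- sols[[2]]
  sneg$f <- -sneg$f
  avg0 <- average_blocks(list(sols[[2]], sneg))
  expect_equal(max(abs(avg0[["apolar|apolar"]]$f), na.rm = TRUE), 0,
               tolerance = 1e-12)
  # noiseless fluid: all blocks agree, so stderr is at numerical zero and
  # the 10-block average equals the direct solution
  avg10 <- average_blocks(sols)[["apolar|apolar"]]
  mask <- avg10$n_blocks == 10
  expect_lt(max(avg10$stderr[mask]), 1e-9)
  expect_error(average_blocks(list(sols[[1]],
                                   solve_block(build_block(fm_frames[1:5],
                                                           spline_basis(0.3, 1.2, 0.1),
                                                           "apolar")))),
               "basis mismatch")
})

test_that("stderr shrinks ~1/sqrt(10) for genuinely noisy blocks", {
  # add reproducible noise to the stored forces so blocks disagree
  set.seed(99)
  noisy <- lapply(fm_frames, function(fr) {
    fr$forces <- fr$forces + matrix(rnorm(length(fr$forces), sd = 5),
                                    nrow(fr$forces), 3)
    fr
  })
  sols <- lapply(split(seq_len(200), rep(1:10, each = 20)), function(ii) {
    solve_block(build_block(noisy[ii], fm_basis, "apolar"))
  })
  avg <- average_blocks(sols)[["apolar|apolar"]]
  mask <- avg$n_blocks == 10 & avg$n_samples > 100
  spread <- apply(sapply(sols, function(s) s$f[, 1]), 1, sd)[mask]
  ratio <- avg$stderr[mask] / spread
  expect_equal(mean(ratio), 1 / sqrt(10), tolerance = 0.05)
})

test_that("half-data convergence check reports masked deviations", {
  # deterministic duplicated data: zero deviation
  conv0 <- check_convergence(c(fm_frames[1:10], fm_frames[1:10]),
                             fm_basis, "apolar")
  expect_equal(conv0$max_dev, 0, tolerance = 1e-9)
  conv <- check_convergence(fm_frames, fm_basis, "apolar")
  expect_lt(conv$rms_dev, 0.02 * max(abs(fm_vals)))
  expect_error(check_convergence(fm_frames[1], fm_basis, "apolar"),
               "too few")
  # disjoint sampling ranges: unsampled knots excluded, reported separately
  near <- list(pos = rbind(c(0, 0, 0), c(0.35, 0, 0)),
               forces = rbind(c(-fm_law$f(0.35), 0, 0),
                              c(fm_law$f(0.35), 0, 0)), box = NULL)
  far <- list(pos = rbind(c(0, 0, 0), c(1.05, 0, 0)),
              forces = rbind(c(-fm_law$f(1.05), 0, 0),
                             c(fm_law$f(1.05), 0, 0)), box = NULL)
  convd <- check_convergence(list(near, near, far, far), fm_basis, "apolar")
  expect_equal(convd$n_compared, 0L)
  expect_gt(convd$n_only_one_half, 0L)
})

test_that("grid refinement does not hurt recovery on well-sampled regions", {
  fine <- spline_basis(0.3, 1.2, 0.025)
  law_on_fine <- piecewise_linear_force(
    fine$knots, approx(fm_basis$knots, fm_vals, fine$knots)$y)
  frames <- make_oracle_fluid(27, law_on_fine, 300, 100, seed = 4)
  coarse_cu <- solve_mscg(frames, fm_basis, "apolar",
                          block_size = 100)[["apolar|apolar"]]
  fine_cu <- solve_mscg(frames, fine, "apolar",
                        block_size = 100)[["apolar|apolar"]]
  ref_c <- approx(fine$knots, law_on_fine$f(fine$knots), fm_basis$knots)$y
  mc <- coarse_cu$n_samples > 30
  mf <- fine_cu$n_samples > 30
  rms_c <- sqrt(mean((coarse_cu$f[mc] - ref_c[mc])^2))
  rms_f <- sqrt(mean((fine_cu$f[mf] - law_on_fine$f(fine$knots)[mf])^2))
  expect_lte(rms_f, rms_c + 1e-9)
})

test_that("force curve serialization writes the sampled range", {
  cu <- solve_mscg(fm_frames[1:20], fm_basis, "apolar",
                   block_size = 20)[["apolar|apolar"]]
  p <- withr::local_tempfile()
  write_force_curve(cu, p)
  df <- read.table(p, comment.char = "#")
  expect_equal(nrow(df), sum(cu$sampled))
  expect_equal(df$V1, cu$knots[cu$sampled], tolerance = 1e-6)
})
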