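#' Linear spline basis for pair-force matching
#'
#' Hat-function (linear spline) basis on a uniform knot grid over
#' `(r_min, r_max]`. Any pair distance inside the range contributes linear
#' weights to its two bracketing knots; the weights sum to one. The default
#' range ends at 2 nm, the force-matching cutoff, with 0.02 nm spacing (fine
#' enough to resolve ~0.1 nm-wide attractive wells).
#'
#' @param r_min,r_max basis range, nm.
#' @param spacing knot spacing, nm.
#' @return a `spline_basis` with `knots` (strictly increasing) and `spacing`.
#' @export
spline_basis <- function(r_min = 0.2, r_max = 2.0, spacing = 0.02) {
  stopifnot(r_min > 0, r_max > r_min, spacing > 0)
  knots <- seq(r_min, r_max, by = spacing)
  structure(list(knots = knots, spacing = spacing, r_min = r_min,
                 r_max = r_max), class = "spline_basis")
}

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' All unordered pair keys among a set of site types
#' @param types character vector of site types.
#' @export
pair_keys <- function(types = SITE_TYPES) {
  u <- sort(unique(types))
  keys <- outer(u, u, .pair_key)
  sort(unique(keys[upper.tri(keys, diag = TRUE)]))
}

.minimum_image <- function(d, box) {
  if (is.null(box)) return(d)
  sweep(d, 2, box, function(x, L) x - L * round(x / L))
}

.frame_pairs <- function(pos, box, excl_key, r_max) {
  n <- nrow(pos)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (!is.null(excl_key) && length(excl_key)) {
    pk <- ij[, 1] + n * ij[, 2]
    ij <- ij[!(pk %in% excl_key), , drop = FALSE]
  }
  d <- .minimum_image(pos[ij[, 1], , drop = FALSE] -
                        pos[ij[, 2], , drop = FALSE], box)
  r <- sqrt(rowSums(d^2))
  keep <- r <= r_max
  list(i = ij[keep, 1], j = ij[keep, 2], d = d[keep, , drop = FALSE],
       r = r[keep], n_below = sum(r < 1e-12))
}

#' Assemble the MS-CG least-squares system for a block of frames
#'
#' Each nonbonded pair within basis range contributes its hat-function
#' weights, times the unit separation vector, to the three force rows of both
#' partner sites with opposite signs (Newton's third law is built into the
#' design matrix). Excluded pairs contribute nothing. The system is
#' accumulated as normal equations G = A'A, b = A'y so the full design matrix
#' is never materialised across frames.
#'
#' @param frames list of CG frames, each a list with `pos` (n x 3, nm),
#'   `forces` (n x 3, kJ/mol/nm) and optional `box` (length-3, nm). Frames
#'   supplied here must contain nonbonded forces only (bonded contributions
#'   are derived by Boltzmann inversion, not fit); see `subtract_bonded`.
#' @param basis a [spline_basis()].
#' @param site_types character vector, one per site; a single type may be
#'   given for homogeneous systems.
#' @param exclusions 2-column matrix of excluded site pairs (e.g. from
#'   [topology_exclusions()]), or `NULL`.
#' @param subtract_bonded optional function(frame) returning an n x 3 matrix
#'   of bonded forces to subtract from `frame$forces` before matching (hook
#'   for real data whose recorded forces include bonded terms).
#' @return an `mscg_system`: normal equations plus per-knot sampling counts.
#' @export
build_block <- function(frames, basis, site_types, exclusions = NULL,
                        subtract_bonded = NULL) {
  stopifnot(length(frames) >= 1L)
  n <- nrow(frames[[1]]$pos)
  if (length(site_types) == 1L) site_types <- rep(site_types, n)
  stopifnot(length(site_types) == n)
  keys <- pair_keys(site_types)
  nk <- length(basis$knots)
  ncol_tot <- nk * length(keys)
  excl_key <- if (!is.null(exclusions) && nrow(exclusions)) {
    i <- pmin(exclusions[, 1], exclusions[, 2])
    j <- pmax(exclusions[, 1], exclusions[, 2])
    i + n * j
  } else integer()
  G <- matrix(0, ncol_tot, ncol_tot)
  bvec <- numeric(ncol_tot)
  yty <- 0
  samples <- numeric(ncol_tot)
  n_pairs <- 0L
  for (fr in frames) {
    stopifnot(nrow(fr$pos) == n, nrow(fr$forces) == n)
    y <- fr$forces
    if (!is.null(subtract_bonded)) y <- y - subtract_bonded(fr)
    pr <- .frame_pairs(fr$pos, fr$box, excl_key, basis$r_max)
    keep <- pr$r > basis$r_min
    if (!any(keep)) next
    i <- pr$i[keep]; j <- pr$j[keep]; d <- pr$d[keep, , drop = FALSE]
    r <- pr$r[keep]
    kcol <- match(.pair_key(site_types[i], site_types[j]), keys)
    pos_in_grid <- (r - basis$knots[1]) / basis$spacing
    k0 <- pmin(floor(pos_in_grid), nk - 2)
    t <- pos_in_grid - k0
    A <- matrix(0, 3L * n, ncol_tot)
    u <- d / r
    c1 <- (kcol - 1L) * nk + k0 + 1L
    for (p in seq_along(r)) {
      ri <- 3L * (i[p] - 1L) + 1:3
      rj <- 3L * (j[p] - 1L) + 1:3
      w <- c(1 - t[p], t[p])
      cols <- c(c1[p], c1[p] + 1L)
      A[ri, cols] <- A[ri, cols] + outer(u[p, ], w)
      A[rj, cols] <- A[rj, cols] - outer(u[p, ], w)
      samples[cols] <- samples[cols] + w
    }
    G <- G + crossprod(A)
    yv <- as.vector(t(y))
    bvec <- bvec + drop(crossprod(A, yv))
    yty <- yty + sum(yv^2)
    n_pairs <- n_pairs + length(r)
  }
  if (n_pairs == 0L) stop("no interacting pairs in range")
  structure(list(G = G, b = bvec, yty = yty, samples = samples,
                 n_rows = 3L * n * length(frames), n_frames = length(frames),
                 keys = keys, basis = basis), class = "mscg_system")
}

#' Solve one block of the MS-CG system
#'
#' Minimum-norm least-squares solution of the accumulated normal equations
#' via eigendecomposition; knots never sampled in the block are
#' rank-deficient directions, resolved to zero by the minimum-norm convention
#' and flagged in `sampled`.
#'
#' @param system an `mscg_system` from [build_block()].
#' @param rtol relative eigenvalue cutoff for the pseudoinverse.
#' @return a `block_solution`: per-pair-key force values at the knots
#'   (kJ/mol/nm), `sampled` mask, residual norm, frame count.
#' @export
solve_block <- function(system, rtol = 1e-10) {
  if (all(system$samples == 0)) stop("empty system")
  eg <- eigen(system$G, symmetric = TRUE)
  pos <- eg$values > rtol * max(eg$values)
  coef <- eg$vectors[, pos, drop = FALSE] %*%
    ((t(eg$vectors[, pos, drop = FALSE]) %*% system$b) / eg$values[pos])
  coef <- drop(coef)
  res2 <- max(0, system$yty - 2 * sum(coef * system$b) +
                drop(t(coef) %*% system$G %*% coef))
  nk <- length(system$basis$knots)
  f <- matrix(coef, nrow = nk, dimnames = list(NULL, system$keys))
  sampled <- matrix(system$samples > 0, nrow = nk,
                    dimnames = list(NULL, system$keys))
  samples <- matrix(system$samples, nrow = nk,
                    dimnames = list(NULL, system$keys))
  structure(list(f = f, sampled = sampled, samples = samples,
                 residual = sqrt(res2), n_frames = system$n_frames,
                 basis = system$basis, keys = system$keys),
            class = "block_solution")
}

#' Average block solutions into force curves
#'
#' Per-knot frame-count-weighted mean across blocks with the standard error
#' over blocks; a knot unsampled in some block is excluded from that block's
#' contribution to the average.
#'
#' @param solutions list of `block_solution`s with congruent bases.
#' @return named list of `force_curve`s (`key`, `knots`, `f`, `stderr`,
#'   `n_samples`, `sampled`), one per pair key.
#' @export
average_blocks <- function(solutions) {
  stopifnot(length(solutions) >= 1L)
  b0 <- solutions[[1]]$basis
  for (s in solutions[-1]) {
    if (!isTRUE(all.equal(s$basis$knots, b0$knots))) stop("basis mismatch")
  }
  keys <- solutions[[1]]$keys
  nk <- length(b0$knots)
  out <- list()
  for (key in keys) {
    vals <- sapply(solutions, function(s) {
      v <- s$f[, key]
      v[!s$sampled[, key]] <- NA
      v
    })
    vals <- matrix(vals, nrow = nk)
    wts <- matrix(sapply(solutions, function(s) s$n_frames), nrow = nk,
                  ncol = length(solutions), byrow = TRUE)
    wts[is.na(vals)] <- 0
    wsum <- rowSums(wts)
    mean_f <- ifelse(wsum > 0, rowSums(vals * wts, na.rm = TRUE) / wsum, NA)
    n_contrib <- rowSums(!is.na(vals))
    stderr <- apply(vals, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(0)
      sd(v) / sqrt(length(v))
    })
    n_samples <- rowSums(sapply(solutions, function(s) s$samples[, key]))
    out[[key]] <- structure(
      list(key = key, knots = b0$knots, f = mean_f, stderr = stderr,
           n_samples = n_samples, sampled = n_contrib > 0,
           n_blocks = n_contrib),
      class = "force_curve")
  }
  out
}

#' End-to-end MS-CG solve with block averaging
#'
#' Splits frames into blocks, assembles and solves each block, and averages.
#' Blocks of 2000+ frames are the reference protocol; smaller systems can use
#' smaller blocks.
#'
#' @inheritParams build_block
#' @param block_size frames per block.
#' @return list of `force_curve`s (see [average_blocks()]).
#' @export
solve_mscg <- function(frames, basis, site_types, exclusions = NULL,
                       block_size = 2000L, subtract_bonded = NULL) {
  idx <- split(seq_along(frames),
               ceiling(seq_along(frames) / block_size))
  sols <- lapply(idx, function(ii) {
    solve_block(build_block(frames[ii], basis, site_types, exclusions,
                            subtract_bonded))
  })
  average_blocks(sols)
}

#' Half-data convergence check
#'
#' Repeats the MS-CG solve on the first and second halves of the frames and
#' reports, per pair key, the max and RMS deviation between the two force
#' curves over knots well-sampled in both halves (high-frequency noise at
#' poorly sampled knots is reported separately via the masks).
#'
#' @inheritParams build_block
#' @return data.frame with one row per pair key: `max_dev`, `rms_dev`,
#'   `n_compared`, `n_only_one_half`.
#' @export
check_convergence <- function(frames, basis, site_types, exclusions = NULL) {
  if (length(frames) < 2L) stop("too few frames to split")
  half <- length(frames) %/% 2L
  s1 <- solve_block(build_block(frames[seq_len(half)], basis, site_types,
                                exclusions))
  s2 <- solve_block(build_block(frames[seq(half + 1L, length(frames))],
                                basis, site_types, exclusions))
  rows <- lapply(s1$keys, function(key) {
    both <- s1$sampled[, key] & s2$sampled[, key]
    one <- xor(s1$sampled[, key], s2$sampled[, key])
    dev <- abs(s1$f[both, key] - s2$f[both, key])
    data.frame(key = key,
               max_dev = if (any(both)) max(dev) else NA_real_,
               rms_dev = if (any(both)) sqrt(mean(dev^2)) else NA_real_,
               n_compared = sum(both), n_only_one_half = sum(one),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a force curve as a text table
#'
#' Columns: r (nm), f (kJ/mol/nm), stderr, n_samples; `#` header carries the
#' pair key.
#' @param curve a `force_curve`.
#' @param path file path.
#' @export
write_force_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# force_curve key=%s", curve$key), con)
  writeLines("# r f stderr n_samples", con)
  keep <- curve$sampled
  writeLines(sprintf("%.6f %.8g %.8g %.3f", curve$knots[keep],
                     curve$f[keep], curve$stderr[keep],
                     curve$n_samples[keep]), con)
  invisible(path)
}
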