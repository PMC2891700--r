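#' Heat capacity curve from per-temperature energy series
#'
#' Configurational heat capacity from potential-energy fluctuations,
#' C_v(T) = (<U^2> - <U>^2) / (k_B T^2), per temperature, after discarding
#' an equilibration fraction of each series. Uncertainties come from block
#' averaging (the C_v of each of `n_blocks` contiguous blocks; the quoted
#' error is the standard error over blocks). The transition temperature
#' T_f is the ladder temperature maximising C_v. Including kinetic terms
#' would add the constant N_dof k_B / 2 and shift no peak; a flag is
#' provided.
#'
#' @param energy_series list of numeric potential-energy series (kJ/mol),
#'   one per temperature.
#' @param temperatures numeric vector of the same length.
#' @param discard_fraction initial fraction of each series dropped as
#'   equilibration (default 0.2).
#' @param n_blocks blocks for the uncertainty estimate (>= 5).
#' @param include_kinetic add N_dof k_B/2 (requires `n_dof`).
#' @param n_dof number of degrees of freedom, for `include_kinetic`.
#' @param min_samples minimum retained samples per temperature.
#' @return a `heat_capacity_curve` data.frame (`temperature`, `cv`,
#'   `cv_err`) with attributes `T_f` and `T_f_ties`.
#' @export
heat_capacity <- function(energy_series, temperatures,
                          discard_fraction = 0.2, n_blocks = 5L,
                          include_kinetic = FALSE, n_dof = NULL,
                          min_samples = 100L) {
  stopifnot(length(energy_series) == length(temperatures))
  cv <- cv_err <- numeric(length(temperatures))
  for (k in seq_along(temperatures)) {
    u <- energy_series[[k]]
    n_drop <- floor(length(u) * discard_fraction)
    if (n_drop > 0L) u <- u[-seq_len(n_drop)]
    if (length(u) < min_samples) {
      stop("insufficient samples at T = ", temperatures[k], " (",
           length(u), " after discard, need ", min_samples, ")")
    }
    kT2 <- KB * temperatures[k]^2
    n <- length(u)
    cv[k] <- (mean(u^2) - mean(u)^2) / kT2
    blocks <- split(u, cut(seq_len(n), n_blocks, labels = FALSE))
    bc <- vapply(blocks, function(b) (mean(b^2) - mean(b)^2) / kT2, 0.0)
    cv_err[k] <- sd(bc) / sqrt(length(bc))
  }
  if (include_kinetic) {
    if (is.null(n_dof)) stop("include_kinetic requires n_dof")
    cv <- cv + n_dof * KB / 2
  }
  out <- data.frame(temperature = temperatures, cv = cv, cv_err = cv_err)
  peak <- which(cv == max(cv))
  attr(out, "T_f") <- temperatures[peak[1]]
  attr(out, "T_f_ties") <- temperatures[peak]
  class(out) <- c("heat_capacity_curve", "data.frame")
  out
}

#' Reference temperature from a heat-capacity curve
#'
#' The model's reference temperature is the folding transition temperature
#' T_f, the argmax of C_v(T); native-state simulations are run at 0.6 T_f.
#' A flat curve (no unique maximum within error, or exact ties) is flagged.
#'
#' @param curve a `heat_capacity_curve`.
#' @return list(`T_f`, `T_low = 0.6 * T_f`, `flat`, `ties`).
#' @export
reference_temperature <- function(curve) {
  ties <- attr(curve, "T_f_ties")
  T_f <- attr(curve, "T_f")
  flat <- length(ties) > 1L ||
    all(abs(curve$cv - max(curve$cv)) <= curve$cv_err)
  list(T_f = T_f, T_low = 0.6 * T_f, flat = flat, ties = ties)
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Superimposes `fit_selection` sites by the optimal proper rotation
#' (Kabsch, determinant +1 enforced) plus translation, then evaluates the
#' RMSD over `measure_selection`. Selections index sites and must be
#' congruent between the two structures. Input coordinates are nm; the
#' result is reported in Angstrom, the field's convention for structural
#' deviations.
#'
#' @param conformation,reference `n x 3` coordinate matrices, nm.
#' @param fit_selection indices of sites used for superposition (>= 3);
#'   default all.
#' @param measure_selection indices over which the RMSD is evaluated;
#'   default `fit_selection`.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(conformation, reference,
                 fit_selection = seq_len(nrow(reference)),
                 measure_selection = fit_selection) {
  conformation <- as.matrix(conformation)
  reference <- as.matrix(reference)
  if (!all(dim(conformation) == dim(reference))) {
    stop("selection mismatch: structures have different site counts")
  }
  if (length(fit_selection) < 3L) stop("need at least 3 fit sites")
  fitted <- kabsch_superpose(conformation, reference, fit_selection)
  d <- fitted[measure_selection, , drop = FALSE] -
    reference[measure_selection, , drop = FALSE]
  nm_to_ang(sqrt(mean(rowSums(d^2))))
}

#' @rdname rmsd
#' @return `kabsch_superpose`: the conformation rigidly transformed onto the
#'   reference (all sites moved; fit on `fit_selection`).
#' @export
kabsch_superpose <- function(conformation, reference, fit_selection) {
  A <- conformation[fit_selection, , drop = FALSE]
  B <- reference[fit_selection, , drop = FALSE]
  ca <- colMeans(A)
  cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(conformation, 2, ca) %*% t(R), 2, cb, `+`)
}

#' Difference-of-RMSD reaction coordinate
#'
#' Delta-D_RMSD = RMSD(conformation, open) - RMSD(conformation, closed);
#' negative values are open-like, positive closed-like
#' (antisymmetric under swapping the references). At the endpoints,
#' Delta-D_RMSD(open) = -RMSD(open, closed) and
#' Delta-D_RMSD(closed) = +RMSD(open, closed).
#'
#' @param conformation coordinates, nm.
#' @param open_ref,closed_ref reference coordinates, nm.
#' @param selection site indices used for both fit and measure.
#' @return Delta-D_RMSD in Angstrom.
#' @export
delta_d_rmsd <- function(conformation, open_ref, closed_ref,
                         selection = seq_len(nrow(conformation))) {
  rmsd(conformation, open_ref, selection) -
    rmsd(conformation, closed_ref, selection)
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of sites from their center of
#' mass, optionally reported relative to a native-structure value.
#'
#' @param positions `n x 3` matrix, nm.
#' @param masses site masses (default equal).
#' @param relative_to optional native Rg (same units) to report a ratio.
#' @return Rg in nm, or the dimensionless ratio when `relative_to` is given.
#' @export
radius_of_gyration <- function(positions, masses = NULL,
                               relative_to = NULL) {
  positions <- as.matrix(positions)
  if (is.null(masses)) masses <- rep(1, nrow(positions))
  if (sum(masses) <= 0) stop("zero total mass")
  com <- colSums(positions * masses) / sum(masses)
  rg <- sqrt(sum(masses * rowSums(sweep(positions, 2, com)^2)) /
               sum(masses))
  if (is.null(relative_to)) rg else rg / relative_to
}

#' Nonbonded C-alpha radial distribution function
#'
#' g(r) over eligible backbone-site pairs: intramolecular pairs separated by
#' at least `min_separation` bonds plus all intermolecular pairs.
#' Shell-volume and density normalised; minimum-image convention when a
#' periodic box is given (without a box the ideal-gas density uses the
#' supplied `volume`).
#'
#' @param frames list of `n x 3` coordinate matrices (nm), or one matrix.
#' @param topology a `cg_topology` for the bond-separation rule; sites other
#'   than backbone are ignored. `NULL` treats all rows as one molecule of
#'   free particles (all pairs eligible).
#' @param molecule_id integer per backbone site assigning molecules
#'   (intermolecular pairs are always eligible); default all one molecule.
#' @param breaks histogram bin edges over (0, r_max], nm.
#' @param box periodic box (length-3, nm) or `NULL`.
#' @param volume system volume for density normalisation when `box` is
#'   `NULL`.
#' @return data.frame `r`, `g`, `count` with `attr(,"n_pairs")` (eligible
#'   pairs per frame) and `attr(,"n_frames")`.
#' @export
rdf_nonbonded_ca <- function(frames, topology = NULL, molecule_id = NULL,
                             breaks = seq(0, 2, by = 0.02), box = NULL,
                             volume = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  n_all <- nrow(frames[[1]])
  if (!is.null(topology)) {
    ca <- which(topology$sites$site_type == "backbone")
    excl <- topology_exclusions_at(topology, min_sep = 3L)
  } else {
    ca <- seq_len(n_all)
    excl <- matrix(integer(), 0, 2)
  }
  if (is.null(molecule_id)) molecule_id <- rep(1L, length(ca))
  idx <- t(utils::combn(seq_along(ca), 2L))
  same_mol <- molecule_id[idx[, 1]] == molecule_id[idx[, 2]]
  gi <- ca[idx[, 1]]; gj <- ca[idx[, 2]]
  if (nrow(excl)) {
    n <- nrow(topology$sites)
    ek <- pmin(excl[, 1], excl[, 2]) + n * pmax(excl[, 1], excl[, 2])
    pk <- pmin(gi, gj) + n * pmax(gi, gj)
    drop <- same_mol & (pk %in% ek)
  } else drop <- rep(FALSE, length(gi))
  gi <- gi[!drop]; gj <- gj[!drop]
  if (!length(gi)) stop("no eligible pairs")
  counts <- numeric(length(breaks) - 1L)
  for (fr in frames) {
    d <- fr[gi, , drop = FALSE] - fr[gj, , drop = FALSE]
    d <- .minimum_image(d, box)
    r <- sqrt(rowSums(d^2))
    counts <- counts + tabulate(findInterval(r, breaks, left.open = TRUE),
                                nbins = length(breaks) - 1L)
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  shell <- 4 / 3 * pi * diff(breaks^3)
  V <- if (!is.null(box)) prod(box) else volume
  g <- if (is.null(V)) {
    rep(NA_real_, length(mids))
  } else {
    counts / (length(frames) * length(gi)) / (shell / V)
  }
  out <- data.frame(r = mids, g = g, count = counts)
  attr(out, "n_pairs") <- length(gi)
  attr(out, "n_frames") <- length(frames)
  out
}

# exclusions for an arbitrary separation rule (the RDF always uses >= 3
# bonds regardless of the topology's nonbonded setting)
topology_exclusions_at <- function(topology, min_sep) {
  t2 <- topology
  t2$min_separation <- as.integer(min_sep)
  topology_exclusions(t2)
}

#' Per-temperature structural metric series
#'
#' Convenience wrapper computing RMSD (to a reference), Rg or Delta-D_RMSD
#' for every frame of a trajectory array.
#'
#' @param positions `n x 3 x n_frames` array.
#' @param fun function(`n x 3` matrix) -> scalar.
#' @return numeric vector over frames.
#' @export
frame_metric <- function(positions, fun) {
  apply(positions, 3, fun)
}
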