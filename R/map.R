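#' Map an all-atom structure to CG sites
#'
#' Places one backbone site per residue at the C-alpha coordinate and each
#' sidechain site at the mass center of its member heavy atoms. Site masses
#' follow the hydrogen-inclusive convention by default (member heavy atoms
#' plus their bonded hydrogens); set `include_hydrogens = FALSE` for heavy
#' atoms only. The backbone site carries the C-alpha atom alone for position,
#' force and mass bookkeeping; amide and carbonyl atoms are deliberately
#' unmapped.
#'
#' @param structure a `pdb_structure` from [read_pdb()], or any data.frame
#'   with columns `atom`, `resname`, `residue_index`, `x`, `y`, `z` (nm).
#' @param scheme a [mapping_scheme][read_mapping_scheme].
#' @param include_hydrogens include bonded hydrogens in site masses.
#' @param skip_incomplete silently drop sidechain sites whose member atoms are
#'   missing from the structure instead of erroring.
#' @return a `cg_config`: data.frame with one row per site (`site_id`,
#'   `residue_index`, `resname`, `site_index` (0 = backbone), `site_type`,
#'   `mass`, `x`, `y`, `z`), with the atom-to-site assignment kept in
#'   `attr(, "atom_index")` for force mapping.
#' @export
map_structure <- function(structure, scheme = default_mapping_scheme(),
                          include_hydrogens = TRUE, skip_incomplete = FALSE) {
  stopifnot(all(c("atom", "resname", "residue_index", "x", "y", "z") %in%
                  names(structure)))
  out <- list(); atom_index <- list(); sid <- 0L
  for (ri in sort(unique(structure$residue_index))) {
    rows <- which(structure$residue_index == ri)
    res <- structure[rows, , drop = FALSE]
    resname <- toupper(res$resname[1])
    if (!resname %in% names(scheme)) {
      stop("residue ", resname, " (index ", ri, ") not in mapping scheme")
    }
    ica <- which(res$atom == "CA")
    if (length(ica) == 0L) stop("residue index ", ri, " has no CA atom")
    ica <- ica[1]
    sid <- sid + 1L
    out[[length(out) + 1L]] <- data.frame(
      site_id = sid, residue_index = ri, resname = resname, site_index = 0L,
      site_type = "backbone",
      mass = .site_mass("CA", if (include_hydrogens) 1L else 0L,
                        include_hydrogens),
      x = res$x[ica], y = res$y[ica], z = res$z[ica],
      stringsAsFactors = FALSE)
    atom_index[[sid]] <- rows[ica]
    defs <- scheme[[resname]]
    for (k in seq_len(nrow(defs))) {
      atoms <- .scheme_atoms(defs[k, ])
      idx <- match(atoms, res$atom)
      if (anyNA(idx)) {
        if (skip_incomplete) next
        stop("residue ", resname, " (index ", ri, "): missing atom(s) ",
             paste(atoms[is.na(idx)], collapse = ", "))
      }
      w <- vapply(atoms, .atom_mass, 0.0)
      sid <- sid + 1L
      out[[length(out) + 1L]] <- data.frame(
        site_id = sid, residue_index = ri, resname = resname,
        site_index = defs$site_index[k], site_type = defs$site_type[k],
        mass = .site_mass(atoms, defs$nH[k], include_hydrogens),
        x = sum(w * res$x[idx]) / sum(w),
        y = sum(w * res$y[idx]) / sum(w),
        z = sum(w * res$z[idx]) / sum(w),
        stringsAsFactors = FALSE)
      atom_index[[sid]] <- rows[idx]
    }
  }
  cfg <- do.call(rbind, out)
  rownames(cfg) <- NULL
  attr(cfg, "atom_index") <- atom_index
  class(cfg) <- c("cg_config", "data.frame")
  cfg
}

#' Map per-atom forces to CG sites
#'
#' A sidechain site's force is the vector sum of the instantaneous forces on
#' its member atoms; the backbone site's force is the force on the C-alpha
#' atom alone. The mapping is linear in the atomistic forces.
#'
#' @param atom_forces numeric matrix, one row per atom of the structure the
#'   configuration was mapped from (kJ/mol/nm).
#' @param config a `cg_config` from [map_structure()].
#' @return matrix `n_sites x 3` of site forces.
#' @export
map_forces <- function(atom_forces, config) {
  atom_index <- attr(config, "atom_index")
  if (is.null(atom_index)) stop("config carries no atom assignment")
  atom_forces <- as.matrix(atom_forces)
  need <- max(unlist(atom_index))
  if (nrow(atom_forces) < need) {
    stop("force frame has ", nrow(atom_forces), " atoms; mapping needs ", need)
  }
  t(vapply(atom_index,
           function(ii) colSums(atom_forces[ii, , drop = FALSE]),
           numeric(3)))
}

#' @export
print.cg_config <- function(x, ...) {
  cat("CG configuration:", nrow(x), "sites,",
      length(unique(x$residue_index)), "residues\n")
  print.data.frame(head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Site coordinates as a matrix
#' @param config a `cg_config`.
#' @return `n x 3` matrix in nm.
#' @export
cg_positions <- function(config) {
  as.matrix(config[, c("x", "y", "z")])
}
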