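#' CG site types
#'
#' The five interaction classes a coarse-grained site can carry: one backbone
#' class (the C-alpha site) and four sidechain classes describing the polarity
#' of the mapped functional group.
#'
#' @export
SITE_TYPES <- c("backbone", "apolar", "polar", "positive", "negative")

# heavy-atom masses, amu; element inferred from the first letter of the
# stripped atom name (PDB convention for protein heavy atoms)
.ATOM_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)
.H_MASS <- 1.008

.element_of <- function(atom_name) {
  el <- substr(gsub("[0-9']", "", trimws(atom_name)), 1L, 1L)
  bad <- !el %in% names(.ATOM_MASS)
  if (any(bad)) {
    stop("cannot infer element for atom name(s): ",
         paste(unique(atom_name[bad]), collapse = ", "))
  }
  el
}

.atom_mass <- function(atom_name) unname(.ATOM_MASS[.element_of(atom_name)])

#' Read a residue-to-site mapping scheme
#'
#' A mapping scheme assigns every standard residue's sidechain heavy atoms to
#' typed CG sites (at most four per residue, two or three heavy atoms per site
#' as a target; single-heavy-atom sites occur for short sidechains and are a
#' documented exception). The backbone site is always the C-alpha atom alone.
#' No heavy atom may appear in more than one site.
#'
#' The file format is whitespace-separated with `#` comments, one sidechain
#' site per line:
#' \preformatted{residue  site_index  site_type  parent  nH  atom1,atom2,...}
#' `parent` is 0 for sites bonded to the backbone site, otherwise the
#' `site_index` of the earlier sidechain site it is bonded to. `nH` is the
#' number of hydrogens attached to the member heavy atoms (used for the
#' hydrogen-inclusive mass convention). Residues with no sidechain sites
#' (glycine) may be declared with a single line whose atom list is `-`.
#'
#' @param path path to a mapping file; default is the scheme shipped with the
#'   package, a reconstruction covering the 20 standard amino acids.
#' @return an object of class `mapping_scheme`: a named list of per-residue
#'   site-definition data frames.
#' @export
read_mapping_scheme <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mapping_default.txt", package = "mscg",
                        mustWork = TRUE)
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(toks) != 6L
  if (any(bad)) stop("malformed mapping line: ", lines[which(bad)[1]])
  df <- data.frame(
    residue = toupper(vapply(toks, `[`, "", 1L)),
    site_index = as.integer(vapply(toks, `[`, "", 2L)),
    site_type = vapply(toks, `[`, "", 3L),
    parent = as.integer(vapply(toks, `[`, "", 4L)),
    nH = as.integer(vapply(toks, `[`, "", 5L)),
    atoms = vapply(toks, `[`, "", 6L),
    stringsAsFactors = FALSE
  )
  scheme <- lapply(split(df, df$residue), function(d) {
    d <- d[order(d$site_index), , drop = FALSE]
    d <- d[d$atoms != "-", , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  validate_mapping_scheme(scheme)
  structure(scheme, class = "mapping_scheme")
}

#' @rdname read_mapping_scheme
#' @param scheme a mapping scheme to validate.
#' @export
validate_mapping_scheme <- function(scheme) {
  for (res in names(scheme)) {
    d <- scheme[[res]]
    if (nrow(d) == 0L) next
    if (nrow(d) > 4L) stop(res, ": more than 4 sidechain sites")
    bad_type <- !d$site_type %in% setdiff(SITE_TYPES, "backbone")
    if (any(bad_type)) stop(res, ": invalid sidechain site type")
    atoms <- unlist(strsplit(d$atoms, ","))
    if (anyDuplicated(atoms)) {
      stop(res, ": atom assigned to more than one site: ",
           atoms[duplicated(atoms)][1])
    }
    if ("CA" %in% atoms) stop(res, ": CA belongs to the backbone site")
    n_per <- lengths(strsplit(d$atoms, ","))
    if (any(n_per > 3L)) stop(res, ": site with more than 3 heavy atoms")
    if (any(d$parent >= d$site_index)) {
      stop(res, ": site parent must be an earlier site (or 0 for backbone)")
    }
  }
  invisible(TRUE)
}

#' @rdname read_mapping_scheme
#' @export
default_mapping_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_mapping_scheme()
    cache
  }
})

.scheme_atoms <- function(site_row) strsplit(site_row$atoms, ",")[[1]]

.site_mass <- function(atoms, nH, include_hydrogens = TRUE) {
  m <- sum(vapply(atoms, .atom_mass, 0.0))
  if (include_hydrogens) m <- m + nH * .H_MASS
  m
}
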