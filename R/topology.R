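#' Build a CG topology from a residue sequence
#'
#' Generates sites, bonds, angles, pseudo-torsions and impropers for a single
#' chain. Consecutive backbone sites are bonded; sidechain sites are bonded
#' according to the scheme's intra-residue parent connectivity. Angles are
#' tagged: `backbone` for C-alpha triples, `to_previous`/`to_next` for the
#' sidechain-backbone angles of residue i toward backbone residue i-1 and
#' i+1 (treated as distinct interactions), `sidechain_internal` otherwise.
#' Backbone pseudo-torsions over four successive C-alpha sites are keyed by
#' the names of their middle two residues; sidechain torsions are left
#' unrestricted except for tryptophan and tyrosine, whose four ring sites get
#' a planarity improper.
#'
#' @param sequence character vector of residue names, three-letter
#'   (case-insensitive) or a single one-letter string.
#' @param scheme a [mapping_scheme][read_mapping_scheme].
#' @param min_separation minimum bond-graph separation for a site pair to
#'   interact nonbondedly (3: 1-2 and 1-3 excluded, 1-4 included; 4 also
#'   excludes 1-4).
#' @param include_hydrogens hydrogen-inclusive site masses.
#' @return a `cg_topology` list: `sites` (data.frame), `bonds` (2-col matrix),
#'   `angles` (data.frame `i,j,k,tag`), `torsions` (data.frame
#'   `i,j,k,l,res1,res2`), `impropers` (4-col matrix), `min_separation`.
#' @export
build_topology <- function(sequence, scheme = default_mapping_scheme(),
                           min_separation = 3L, include_hydrogens = TRUE) {
  sequence <- parse_sequence(sequence)
  if (length(sequence) == 0L) stop("empty sequence")
  unknown <- setdiff(sequence, names(scheme))
  if (length(unknown)) stop("residue(s) not in scheme: ",
                            paste(unknown, collapse = ", "))
  n_res <- length(sequence)
  sites <- list(); bonds <- list(); impropers <- list()
  bb_id <- integer(n_res)
  sid <- 0L
  for (i in seq_len(n_res)) {
    rn <- sequence[i]
    sid <- sid + 1L
    bb_id[i] <- sid
    sites[[length(sites) + 1L]] <- data.frame(
      site_id = sid, residue_index = i, resname = rn, site_index = 0L,
      site_type = "backbone",
      mass = .site_mass("CA", if (include_hydrogens) 1L else 0L,
                        include_hydrogens),
      stringsAsFactors = FALSE)
    defs <- scheme[[rn]]
    res_sid <- integer(max(0L, nrow(defs)))
    for (k in seq_len(nrow(defs))) {
      sid <- sid + 1L
      res_sid[defs$site_index[k]] <- sid
      atoms <- .scheme_atoms(defs[k, ])
      sites[[length(sites) + 1L]] <- data.frame(
        site_id = sid, residue_index = i, resname = rn,
        site_index = defs$site_index[k], site_type = defs$site_type[k],
        mass = .site_mass(atoms, defs$nH[k], include_hydrogens),
        stringsAsFactors = FALSE)
      parent <- if (defs$parent[k] == 0L) bb_id[i] else res_sid[defs$parent[k]]
      bonds[[length(bonds) + 1L]] <- c(parent, sid)
    }
    if (rn %in% c("TRP", "TYR") && nrow(defs) == 4L) {
      impropers[[length(impropers) + 1L]] <- res_sid[1:4]
    }
    if (i > 1L) bonds[[length(bonds) + 1L]] <- c(bb_id[i - 1L], bb_id[i])
  }
  sites <- do.call(rbind, sites)
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    matrix(integer(), 0, 2)
  bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  impropers <- if (length(impropers)) do.call(rbind, impropers) else
    matrix(integer(), 0, 4)

  adj <- .adjacency(nrow(sites), bonds)
  angles <- .enumerate_angles(adj, sites, bb_id)
  torsions <- .backbone_torsions(bb_id, sequence)

  topo <- structure(list(sites = sites, bonds = bonds, angles = angles,
                         torsions = torsions, impropers = impropers,
                         min_separation = as.integer(min_separation)),
                    class = "cg_topology")
  topo
}

parse_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  if (length(sequence) == 1L && nchar(sequence) > 1L &&
      !sequence %in% .AA3) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  if (all(nchar(sequence) == 1L)) {
    bad <- !sequence %in% names(.AA3)
    if (any(bad)) stop("unknown one-letter code: ",
                       paste(unique(sequence[bad]), collapse = ""))
    sequence <- unname(.AA3[sequence])
  }
  sequence
}

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

.adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

.enumerate_angles <- function(adj, sites, bb_id) {
  out <- list()
  for (j in seq_along(adj)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    for (a in seq_len(length(nb) - 1L)) {
      for (b in seq(a + 1L, length(nb))) {
        i <- nb[a]; k <- nb[b]
        tag <- .angle_tag(i, j, k, sites, bb_id)
        out[[length(out) + 1L]] <- data.frame(i = i, j = j, k = k, tag = tag,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      tag = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

.angle_tag <- function(i, j, k, sites, bb_id) {
  is_bb <- sites$site_type[c(i, j, k)] == "backbone"
  if (all(is_bb)) return("backbone")
  if (is_bb[2]) {
    # centered at a backbone site: sidechain-to-neighbouring-backbone angle
    sc <- if (is_bb[1]) k else i
    bb <- if (is_bb[1]) i else k
    if (!is_bb[1] && !is_bb[3]) return("sidechain_internal")
    rj <- sites$residue_index[j]
    rb <- sites$residue_index[bb]
    if (rb < rj) return("to_previous")
    if (rb > rj) return("to_next")
  }
  "sidechain_internal"
}

.backbone_torsions <- function(bb_id, sequence) {
  n <- length(bb_id)
  if (n < 4L) {
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      l = integer(), res1 = character(), res2 = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- seq_len(n - 3L)
  data.frame(i = bb_id[idx], j = bb_id[idx + 1L], k = bb_id[idx + 2L],
             l = bb_id[idx + 3L],
             res1 = sequence[idx + 1L], res2 = sequence[idx + 2L],
             stringsAsFactors = FALSE)
}

#' Nonbonded exclusions from the bond graph
#'
#' Returns all unordered site pairs whose bond-graph separation is below the
#' topology's `min_separation` (the default 3 excludes 1-2 and 1-3 pairs;
#' bonded terms never double as nonbonded interactions). Derivable from the
#' bond list alone.
#'
#' @param topology a `cg_topology`.
#' @return 2-column integer matrix of excluded pairs (i < j).
#' @export
topology_exclusions <- function(topology) {
  n <- nrow(topology$sites)
  adj <- .adjacency(n, topology$bonds)
  maxd <- topology$min_separation - 1L
  out <- list()
  for (s in seq_len(n)) {
    dist <- rep.int(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    for (d in seq_len(maxd)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (!length(nxt)) break
      dist[nxt] <- d
      frontier <- nxt
    }
    reached <- which(!is.na(dist) & dist > 0L & seq_len(n) > s)
    if (length(reached)) out[[length(out) + 1L]] <- cbind(s, reached)
  }
  if (!length(out)) return(matrix(integer(), 0, 2))
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("CG topology:", nrow(x$sites), "sites,", nrow(x$bonds), "bonds,",
      nrow(x$angles), "angles,", nrow(x$torsions), "torsions,",
      nrow(x$impropers), "impropers; min_separation =",
      x$min_separation, "\n")
  invisible(x)
}

#' Serialize / read a CG topology
#'
#' Plain-text sectioned format (`[sites]`, `[bonds]`, `[angles]`,
#' `[torsions]`, `[impropers]`) with the exclusion rule in the header.
#' `read_topology(write_topology(t))` reproduces `t` exactly.
#'
#' @param topology a `cg_topology`.
#' @param path file path.
#' @export
write_topology <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# mscg CG topology",
               paste("min_separation", topology$min_separation)), con)
  writeLines("[sites]", con)
  s <- topology$sites
  writeLines(sprintf("%d %d %s %d %s %.6f", s$site_id, s$residue_index,
                     s$resname, s$site_index, s$site_type, s$mass), con)
  writeLines("[bonds]", con)
  b <- topology$bonds
  if (nrow(b)) writeLines(sprintf("%d %d", b[, 1], b[, 2]), con)
  writeLines("[angles]", con)
  a <- topology$angles
  if (nrow(a)) writeLines(sprintf("%d %d %d %s", a$i, a$j, a$k, a$tag), con)
  writeLines("[torsions]", con)
  t <- topology$torsions
  if (nrow(t)) writeLines(sprintf("%d %d %d %d %s %s", t$i, t$j, t$k, t$l,
                                  t$res1, t$res2), con)
  writeLines("[impropers]", con)
  im <- topology$impropers
  if (nrow(im)) writeLines(sprintf("%d %d %d %d", im[, 1], im[, 2],
                                   im[, 3], im[, 4]), con)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  ms <- as.integer(strsplit(lines[grep("^min_separation", lines)[1]],
                            " ")[[1]][2])
  sec <- cumsum(grepl("^\\[", lines))
  labs <- sub("\\]$", "", sub("^\\[", "", lines[grepl("^\\[", lines)]))
  body <- function(name) {
    k <- match(name, labs)
    lines[sec == k & !grepl("^\\[", lines)]
  }
  tok <- function(x) strsplit(x, "[[:space:]]+")
  st <- tok(body("sites"))
  sites <- data.frame(
    site_id = as.integer(vapply(st, `[`, "", 1L)),
    residue_index = as.integer(vapply(st, `[`, "", 2L)),
    resname = vapply(st, `[`, "", 3L),
    site_index = as.integer(vapply(st, `[`, "", 4L)),
    site_type = vapply(st, `[`, "", 5L),
    mass = as.numeric(vapply(st, `[`, "", 6L)),
    stringsAsFactors = FALSE)
  bt <- tok(body("bonds"))
  bonds <- if (length(bt)) {
    cbind(as.integer(vapply(bt, `[`, "", 1L)),
          as.integer(vapply(bt, `[`, "", 2L)))
  } else matrix(integer(), 0, 2)
  at <- tok(body("angles"))
  angles <- if (length(at)) {
    data.frame(i = as.integer(vapply(at, `[`, "", 1L)),
               j = as.integer(vapply(at, `[`, "", 2L)),
               k = as.integer(vapply(at, `[`, "", 3L)),
               tag = vapply(at, `[`, "", 4L), stringsAsFactors = FALSE)
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    tag = character(), stringsAsFactors = FALSE)
  tt <- tok(body("torsions"))
  torsions <- if (length(tt)) {
    data.frame(i = as.integer(vapply(tt, `[`, "", 1L)),
               j = as.integer(vapply(tt, `[`, "", 2L)),
               k = as.integer(vapply(tt, `[`, "", 3L)),
               l = as.integer(vapply(tt, `[`, "", 4L)),
               res1 = vapply(tt, `[`, "", 5L),
               res2 = vapply(tt, `[`, "", 6L), stringsAsFactors = FALSE)
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    l = integer(), res1 = character(), res2 = character(),
                    stringsAsFactors = FALSE)
  it <- tok(body("impropers"))
  impropers <- if (length(it)) {
    cbind(as.integer(vapply(it, `[`, "", 1L)),
          as.integer(vapply(it, `[`, "", 2L)),
          as.integer(vapply(it, `[`, "", 3L)),
          as.integer(vapply(it, `[`, "", 4L)))
  } else matrix(integer(), 0, 4)
  structure(list(sites = sites, bonds = bonds, angles = angles,
                 torsions = torsions, impropers = impropers,
                 min_separation = ms), class = "cg_topology")
}
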