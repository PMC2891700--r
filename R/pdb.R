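#' Read a PDB file
#'
#' Minimal fixed-width reader for standard PDB coordinate records. By default
#' only the first MODEL is read, only the first altLoc variant of each atom is
#' kept and HETATM records are ignored. Coordinates are converted from
#' Angstrom to nm on input. Insertion codes are preserved in the residue
#' indexing (`resid` combines chain, residue number and insertion code;
#' `residue_index` is a 1-based dense index in order of appearance).
#'
#' @param path PDB file path.
#' @param model model number to keep (default 1).
#' @param keep_hetatm keep HETATM records (default `FALSE`).
#' @return a data.frame of class `pdb_structure` with columns `atom`,
#'   `resname`, `chain`, `resseq`, `icode`, `residue_index`, `x`, `y`, `z`
#'   (nm).
#' @export
read_pdb <- function(path, model = 1L, keep_hetatm = FALSE) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  model_no <- 0L
  keep <- logical(length(lines))
  cur <- 1L
  in_model <- TRUE
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      model_no <- model_no + 1L
      in_model <- model_no == model
    } else if (startsWith(r, "ENDMDL")) {
      in_model <- FALSE
    } else if ((r == "ATOM  " || (keep_hetatm && r == "HETATM")) &&
               (model_no == 0L || in_model)) {
      keep[i] <- TRUE
    }
  }
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no ATOM records found in ", path)
  fx <- function(a, b) substr(lines, a, b)
  atom <- trimws(fx(13, 16))
  altloc <- fx(17, 17)
  resname <- trimws(fx(18, 20))
  chain <- fx(22, 22)
  resseq <- as.integer(fx(23, 26))
  icode <- fx(27, 27)
  x <- as.numeric(fx(31, 38))
  y <- as.numeric(fx(39, 46))
  z <- as.numeric(fx(47, 54))
  df <- data.frame(atom = atom, altloc = altloc, resname = resname,
                   chain = chain, resseq = resseq, icode = icode,
                   x = x / 10, y = y / 10, z = z / 10,
                   stringsAsFactors = FALSE)
  # first altLoc only: one record per (chain, resseq, icode, atom), first wins
  df <- df[!duplicated(paste(df$chain, df$resseq, df$icode, df$atom)), ]
  df$altloc <- NULL
  resid <- paste0(df$chain, df$resseq, trimws(df$icode))
  df$residue_index <- as.integer(factor(resid, levels = unique(resid)))
  rownames(df) <- NULL
  class(df) <- c("pdb_structure", "data.frame")
  df
}

#' Write C-alpha traces as a multi-model PDB
#'
#' Exports the backbone-site coordinates of one or more CG frames as CA-only
#' PDB MODEL blocks, for visualisation. Coordinates are converted nm to
#' Angstrom.
#'
#' @param frames a matrix `n x 3` (nm) or list of such matrices.
#' @param resnames residue names, recycled to the number of sites.
#' @param path output file.
#' @export
write_pdb_ca <- function(frames, resnames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  n <- nrow(frames[[1]])
  resnames <- rep_len(toupper(resnames), n)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frames[[m]] * 10
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), resnames, seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
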