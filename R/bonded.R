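#' Histogram a bonded coordinate
#'
#' Bins samples of a bond length (nm), bending angle (degrees) or torsion
#' (degrees) for Boltzmann inversion. Default bin widths: 0.002 nm for bonds,
#' 2 degrees for angles, 5 degrees for torsions. Torsion binning is periodic
#' on (-180, 180].
#'
#' @param samples numeric vector of coordinate samples.
#' @param kind one of `"bond"`, `"angle"`, `"torsion"`.
#' @param temperature sampling temperature, K.
#' @param binwidth bin width (nm or degrees); `NULL` for the kind default.
#' @param range coordinate range to cover; defaults to the sample range
#'   (bonds), (0, 180) for angles, (-180, 180] for torsions.
#' @return a `coordinate_histogram`: list with `kind`, `breaks`, `mids`,
#'   `counts`, `temperature`.
#' @export
coordinate_histogram <- function(samples, kind = c("bond", "angle", "torsion"),
                                 temperature, binwidth = NULL, range = NULL) {
  kind <- match.arg(kind)
  if (is.null(binwidth)) {
    binwidth <- switch(kind, bond = 0.002, angle = 2, torsion = 5)
  }
  if (kind == "torsion") {
    samples <- ((samples + 180) %% 360) - 180
    range <- c(-180, 180)
  }
  if (is.null(range)) {
    range <- if (kind == "angle") c(0, 180) else
      c(floor(min(samples) / binwidth) * binwidth,
        ceiling(max(samples) / binwidth) * binwidth)
  }
  breaks <- seq(range[1], range[2], by = binwidth)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  counts <- tabulate(findInterval(samples, breaks, left.open = TRUE,
                                  all.inside = TRUE),
                     nbins = length(breaks) - 1L)
  structure(list(kind = kind, breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = as.numeric(counts), temperature = temperature),
            class = "coordinate_histogram")
}

.check_hist <- function(hist, kind) {
  if (!inherits(hist, "coordinate_histogram") || hist$kind != kind) {
    stop("expected a coordinate_histogram of kind '", kind, "'")
  }
  if (all(hist$counts == 0)) stop("all-zero histogram")
}

.new_inverted <- function(grid, values, kind, normalization, temperature,
                          counts) {
  sup <- is.finite(values)
  values <- values - min(values[sup])
  structure(list(grid = grid, values = values, kind = kind,
                 normalization = normalization, temperature = temperature,
                 counts = counts, supported = sup),
            class = "inverted_potential")
}

#' Boltzmann inversion of bonded coordinate distributions
#'
#' Converts an observed coordinate distribution p into a potential of mean
#' force: V(r) = -kT ln\[p(r)/r^2\] for bonds, V(theta) =
#' -kT ln\[p(theta)/sin(theta)\] for angles, V(phi) = -kT ln p(phi) for
#' torsions. The r^2 and sin(theta) Jacobian volume factors are required for
#' distributions collected in three dimensions. Potentials are shifted so
#' their minimum over supported bins is zero; empty bins are marked
#' unsupported (no pseudo-counts are added, so barrier heights are never
#' fabricated).
#'
#' @param hist a [coordinate_histogram()] of the matching kind.
#' @param temperature inversion temperature, K; defaults to the histogram's.
#' @return an `inverted_potential`: `grid` (bin midpoints), `values` (kJ/mol,
#'   `Inf` on unsupported bins), `supported`, `normalization`, plus the bin
#'   counts for weighting downstream fits.
#' @export
invert_bond <- function(hist, temperature = hist$temperature) {
  .check_hist(hist, "bond")
  stopifnot(temperature > 0)
  p <- hist$counts / sum(hist$counts)
  v <- -KB * temperature * log(p / hist$mids^2)
  .new_inverted(hist$mids, v, "bond", "r2", temperature, hist$counts)
}

#' @rdname invert_bond
#' @param min_sin regularization floor for sin(theta) in bins touching 0 or
#'   180 degrees (their Jacobian vanishes; the floor keeps the inversion
#'   finite and the affected bins are ordinarily empty anyway).
#' @export
invert_angle <- function(hist, temperature = hist$temperature,
                         min_sin = 1e-6) {
  .check_hist(hist, "angle")
  stopifnot(temperature > 0)
  p <- hist$counts / sum(hist$counts)
  s <- pmax(sin(hist$mids * pi / 180), min_sin)
  v <- -KB * temperature * log(p / s)
  .new_inverted(hist$mids, v, "angle", "sin", temperature, hist$counts)
}

#' @rdname invert_bond
#' @export
invert_torsion <- function(hist, temperature = hist$temperature) {
  .check_hist(hist, "torsion")
  stopifnot(temperature > 0)
  p <- hist$counts / sum(hist$counts)
  v <- -KB * temperature * log(p)
  .new_inverted(hist$mids, v, "torsion", "none", temperature, hist$counts)
}

#' Fit a polynomial to an inverted potential
#'
#' Weighted least squares (weights = bin counts) over supported bins only,
#' using a basis centered on the count-weighted mean coordinate for
#' conditioning. `order = 2` is the harmonic special case. When the RMS
#' residual over supported bins exceeds `table_threshold` the fit is flagged
#' `use_table = TRUE`, signalling that a custom tabulated potential should be
#' used instead of the polynomial.
#'
#' @param pot an `inverted_potential`.
#' @param order polynomial order, 2 or 4.
#' @param table_threshold RMS residual (kJ/mol) above which the tabulated
#'   fallback is flagged.
#' @return a `polynomial_potential`: `x0` (expansion center), `coefficients`
#'   (c0..c_order of sum c_k (x - x0)^k), `kind`, `rms_residual`,
#'   `use_table`.
#' @export
fit_polynomial <- function(pot, order = 4L, table_threshold = 1.0) {
  stopifnot(order %in% c(2L, 4L))
  sup <- pot$supported
  if (sum(sup) < order + 1L) stop("underdetermined fit: ", sum(sup),
                                  " supported bins for order ", order)
  x <- pot$grid[sup]; y <- pot$values[sup]
  w <- if (is.null(pot$counts)) rep(1, length(x)) else pot$counts[sup]
  x0 <- sum(w * x) / sum(w)
  X <- outer(x - x0, 0:order, `^`)
  fit <- lm.fit(X * sqrt(w), y * sqrt(w))
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  resid <- y - drop(X %*% coef)
  rms <- sqrt(sum(w * resid^2) / sum(w))
  structure(list(x0 = x0, coefficients = unname(coef), kind = pot$kind,
                 order = order, rms_residual = rms,
                 use_table = rms > table_threshold,
                 domain = range(x)),
            class = "polynomial_potential")
}

#' Evaluate bonded potential fits
#' @param pot a `polynomial_potential` or `cosine_series`.
#' @param x coordinate values (nm or degrees, matching the fit).
#' @export
eval_polynomial <- function(pot, x) {
  drop(outer(x - pot$x0, seq_along(pot$coefficients) - 1L, `^`) %*%
         pot$coefficients)
}

#' Fit a cosine series to a periodic torsion potential
#'
#' Least-squares fit of V(phi) = sum_{n=0..max_order} a_n cos(n phi) over
#' supported bins (count-weighted). The pure-cosine basis is symmetric about
#' phi = 0; set `sine = TRUE` to add b_n sin(n phi) terms when the source
#' distribution is asymmetric.
#'
#' @param pot an `inverted_potential` of kind torsion.
#' @param max_order highest harmonic (default 4).
#' @param sine include sine terms.
#' @return a `cosine_series` with fields `a` (length max_order+1), optional
#'   `b`, and `rms_residual`.
#' @export
fit_cosine_series <- function(pot, max_order = 4L, sine = FALSE) {
  stopifnot(pot$kind == "torsion")
  sup <- pot$supported
  x <- pot$grid[sup] * pi / 180
  y <- pot$values[sup]
  w <- if (is.null(pot$counts)) rep(1, length(x)) else pot$counts[sup]
  X <- outer(x, 0:max_order, function(p, n) cos(n * p))
  if (sine) X <- cbind(X, outer(x, seq_len(max_order),
                                function(p, n) sin(n * p)))
  fit <- lm.fit(X * sqrt(w), y * sqrt(w))
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  resid <- y - drop(X %*% coef)
  rms <- sqrt(sum(w * resid^2) / sum(w))
  a <- unname(coef[seq_len(max_order + 1L)])
  b <- if (sine) unname(coef[max_order + 1L + seq_len(max_order)]) else NULL
  structure(list(a = a, b = b, rms_residual = rms), class = "cosine_series")
}

#' @rdname eval_polynomial
#' @export
eval_cosine_series <- function(pot, x) {
  phi <- x * pi / 180
  v <- drop(outer(phi, seq_along(pot$a) - 1L, function(p, n) cos(n * p)) %*%
              pot$a)
  if (!is.null(pot$b)) {
    v <- v + drop(outer(phi, seq_along(pot$b),
                        function(p, n) sin(n * p)) %*% pot$b)
  }
  v
}

#' Sequence-dependent backbone torsion library
#'
#' Builds the 20 x 20 library of fourth-order cosine series for the backbone
#' pseudo-torsion between four successive C-alpha sites, keyed by the ordered
#' middle residue pair. Input is either a coefficient table (columns
#' `res1 res2 a0 a1 a2 a3 a4`, as read by [read_torsion_coefficients()]) or a
#' named list of torsion `inverted_potential`s (names `"RES1 RES2"`) which
#' are fit on the fly. Every stored series is multiplied by `scale`
#' (default 0.54, the empirical factor that matches statistical potentials to
#' the polyalanine distribution from all-atom MD); multiplying all
#' coefficients scales V - min V by exactly `scale`.
#'
#' @param input data.frame of coefficients, or named list of inverted
#'   potentials.
#' @param scale positive scale factor applied to every series.
#' @param residues residue names the library must cover (default the 20
#'   standard amino acids; the full library has 400 entries).
#' @param fallback optional `cosine_series` (unscaled) used for pairs missing
#'   from the input; missing pairs without a fallback are an error. Use of
#'   the fallback is recorded in `attr(, "fallback_pairs")`.
#' @return a `torsion_library`: named list (`"RES1 RES2"`) of `cosine_series`
#'   with the scale stored in `attr(, "scale")`.
#' @export
build_torsion_library <- function(input, scale = 0.54,
                                  residues = unname(.AA3), fallback = NULL) {
  if (scale <= 0) stop("scale must be positive")
  pairs <- as.vector(t(outer(residues, residues, paste)))
  series <- list()
  if (is.data.frame(input)) {
    key <- paste(toupper(input$res1), toupper(input$res2))
    for (i in seq_len(nrow(input))) {
      series[[key[i]]] <- structure(
        list(a = as.numeric(input[i, c("a0", "a1", "a2", "a3", "a4")]),
             b = NULL, rms_residual = NA_real_),
        class = "cosine_series")
    }
  } else if (is.list(input)) {
    series <- lapply(input, fit_cosine_series)
    names(series) <- toupper(names(input))
  } else stop("input must be a coefficient data.frame or list of potentials")
  missing <- setdiff(pairs, names(series))
  if (length(missing) && is.null(fallback)) {
    stop(length(missing), " residue pair(s) missing and no fallback given, ",
         "e.g. ", missing[1])
  }
  for (p in missing) series[[p]] <- fallback
  lib <- lapply(series[pairs], function(s) {
    s$a <- s$a * scale
    if (!is.null(s$b)) s$b <- s$b * scale
    s
  })
  structure(lib, scale = scale, fallback_pairs = missing,
            class = "torsion_library")
}

#' Read/write a torsion library coefficient file
#'
#' Keyed text format, one line per ordered residue pair:
#' `RES1 RES2 a0 a1 a2 a3 a4`.
#'
#' @param path file path.
#' @export
read_torsion_coefficients <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("res1", "res2", "a0", "a1", "a2", "a3",
                                 "a4"),
                   stringsAsFactors = FALSE)
  df
}

#' @rdname read_torsion_coefficients
#' @param library a `torsion_library`.
#' @export
write_torsion_library <- function(library, path) {
  keys <- strsplit(names(library), " ")
  lines <- vapply(seq_along(library), function(i) {
    sprintf("%s %s %s", keys[[i]][1], keys[[i]][2],
            paste(sprintf("%.10g", library[[i]]$a), collapse = " "))
  }, "")
  writeLines(c("# RES1 RES2 a0 a1 a2 a3 a4", lines), path)
  invisible(path)
}

#' Sequence-independent backbone angle potential
#'
#' Pools C-alpha--C-alpha--C-alpha angle histograms from all sources (they
#' must share binning), inverts with the sin(theta) Jacobian and fits one
#' fourth-order polynomial used for every backbone angle regardless of
#' sequence. The quartic admits the double-well shape needed to stabilise
#' both alpha-helical and beta-sheet angle values.
#'
#' @param hists a single angle `coordinate_histogram` or list of them.
#' @param temperature inversion temperature; defaults to the first
#'   histogram's.
#' @param table_threshold passed to [fit_polynomial()].
#' @return a `polynomial_potential` of order 4.
#' @export
backbone_angle_potential <- function(hists, temperature = NULL,
                                     table_threshold = Inf) {
  if (inherits(hists, "coordinate_histogram")) hists <- list(hists)
  h0 <- hists[[1]]
  for (h in hists[-1]) {
    if (!isTRUE(all.equal(h$breaks, h0$breaks))) {
      stop("pooled histograms must share binning")
    }
    h0$counts <- h0$counts + h$counts
  }
  if (is.null(temperature)) temperature <- h0$temperature
  inv <- invert_angle(h0, temperature)
  fit_polynomial(inv, order = 4L, table_threshold = table_threshold)
}
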