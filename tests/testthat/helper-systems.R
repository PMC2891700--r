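# shared toy systems for the test suite; everything is built in code

# a bare topology of n free sites of one type (no bonded terms)
free_sites_topology <- function(n, type = "backbone", mass = 12) {
  topo <- list(
    sites = data.frame(site_id = seq_len(n), residue_index = seq_len(n),
                       resname = "GLY", site_index = 0L, site_type = type,
                       mass = mass, stringsAsFactors = FALSE),
    bonds = matrix(integer(), 0, 2),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        tag = character(), stringsAsFactors = FALSE),
    torsions = data.frame(i = integer(), j = integer(), k = integer(),
                          l = integer(), res1 = character(),
                          res2 = character(), stringsAsFactors = FALSE),
    impropers = matrix(integer(), 0, 4),
    min_separation = 3L)
  class(topo) <- "cg_topology"
  topo
}

# harmonic-bond dimer topology + bonded terms
harmonic_dimer <- function(k = 1000, r0 = 0.38, mass = 12) {
  topo <- free_sites_topology(2, mass = mass)
  topo$bonds <- matrix(c(1L, 2L), 1)
  bonded <- mscg:::.empty_bonded()
  bonded$bonds_idx <- matrix(c(1L, 2L), 1)
  bonded$bonds_coef <- matrix(c(r0, 0, 0, k / 2, 0, 0), 1)
  list(topology = topo, bonded = bonded)
}

empty_bonded <- function() mscg:::.empty_bonded()

# cached Table 2 force field (built once per test run)
tbl2 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- table2_forcefield()
    cache
  }
})

# restrained single free particle: 3D harmonic oscillator via restraints
oscillator_config <- function(k = 1000, temperature = 300, seed = 1L,
                              inverse_friction = 0.5, stride = 10L) {
  sim_config(temperature = temperature, seed = seed, stride = stride,
             inverse_friction = inverse_friction,
             restraints = data.frame(site = 1L, k = k, x = 0, y = 0, z = 0))
}

# an inverted_potential directly from known values (bypasses histogramming)
synthetic_inverted <- function(grid, values, kind, counts = NULL) {
  if (is.null(counts)) counts <- rep(1000, length(grid))
  structure(list(grid = grid, values = values - min(values), kind = kind,
                 normalization = "none", temperature = 300, counts = counts,
                 supported = is.finite(values)),
            class = "inverted_potential")
}
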