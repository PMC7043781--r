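# Reference-system generators: the ordered (lattice) and disordered
# (ideal polymer) systems against which protein scaling is compared.

#' Generate a near-spherical fcc lattice cluster
#'
#' Carves the `n` face-centered-cubic lattice sites closest to a lattice
#' site at the origin, giving a near-spherical cluster. The fcc lattice is
#' realized as the integer points with even coordinate sum, scaled so the
#' nearest-neighbor distance equals `spacing`; interior sites then have 12
#' first neighbors at `spacing` and 6 second neighbors at `spacing * sqrt(2)`.
#' The construction is deterministic; ties in the distance-to-origin rank
#' are broken lexicographically.
#'
#' @param n number of sites (>= 8).
#' @param spacing nearest-neighbor distance, Angstrom (default 3.8 so that
#'   protein-scale cutoffs transfer unchanged).
#' @return A [coord_chain()] with `is_chain = FALSE`.
#' @export
generate_fcc_cluster <- function(n, spacing = 3.8) {
  stopifnot(n >= 8L)
  # half of integer sites belong to the fcc sublattice -> radius bound
  m <- ceiling((2 * n * 3 / (4 * pi))^(1 / 3)) + 3L
  g <- as.matrix(expand.grid(x = -m:m, y = -m:m, z = -m:m))
  g <- g[rowSums(g) %% 2L == 0L, , drop = FALSE]
  d2 <- rowSums(g^2)
  ord <- order(d2, g[, 1L], g[, 2L], g[, 3L])
  sites <- g[ord[seq_len(n)], , drop = FALSE] * (spacing / sqrt(2))
  coord_chain(sites, source_id = sprintf("fcc_n%d", n), is_chain = FALSE)
}

#' Generate a full rectangular cubic lattice
#'
#' @param dims integer vector of three grid dimensions (each >= 2);
#'   `N = prod(dims)`.
#' @param spacing lattice constant, Angstrom.
#' @return A [coord_chain()] with `is_chain = FALSE`.
#' @export
generate_cubic_lattice <- function(dims, spacing = 3.8) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 2L))
  g <- as.matrix(expand.grid(x = seq_len(dims[1L]),
                             y = seq_len(dims[2L]),
                             z = seq_len(dims[3L])))
  coord_chain(g * spacing,
              source_id = sprintf("cubic_%dx%dx%d", dims[1L], dims[2L], dims[3L]),
              is_chain = FALSE)
}

#' Generate an ideal (freely-jointed) polymer chain
#'
#' Non-self-avoiding random walk with fixed bond length: each bond is an
#' independent direction drawn uniformly on the sphere. This is the ideal
#' polymer reference — no excluded volume, so `<R^2> = (n-1) b^2`. The bond
#' length defaults to the Calpha virtual-bond scale so protein cutoff
#' distances apply directly.
#'
#' @param n number of beads (>= 2).
#' @param bond_length fixed bond length `b`, Angstrom.
#' @param seed integer seed; the same `(n, bond_length, seed)` always yields
#'   the same conformation, and the caller's RNG stream is left untouched.
#' @return A [coord_chain()] with `is_chain = TRUE`.
#' @export
generate_ideal_chain <- function(n, bond_length = 3.8, seed = NULL) {
  stopifnot(n >= 2L, bond_length > 0)
  steps <- with_seed(seed, {
    z <- stats::runif(n - 1L, -1, 1)
    phi <- stats::runif(n - 1L, 0, 2 * pi)
    rho <- sqrt(1 - z^2)
    cbind(rho * cos(phi), rho * sin(phi), z) * bond_length
  })
  pts <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
  coord_chain(pts,
              source_id = sprintf("chain_n%d_seed%s", n, seed %||% "NA"),
              is_chain = TRUE)
}
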