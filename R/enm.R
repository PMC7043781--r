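# Elastic-network construction and normal mode analysis: Kirchhoff
# matrices, normalized graph Laplacians, eigen-spectra, covariances.

#' Build a Gaussian-network Kirchhoff matrix
#'
#' Constructs the residue-residue contact network and its Kirchhoff (graph
#' Laplacian) matrix from a coordinate set. Two models are supported:
#'
#' * `gnm_cutoff` — unit-strength springs between every pair closer than
#'   `r_cut`: `Gamma_ij = -1` if `r_ij <= r_cut`, 0 beyond, and diagonal
#'   `Gamma_ii = degree(i)` so each row sums to zero.
#' * `pf_gnm` — the parameter-free variant: springs between *all* pairs
#'   with distance-dependent strength `r_ij^-2` and no cutoff.
#'
#' @param points a [coord_chain()].
#' @param r_cut cutoff distance in Angstrom, required for `gnm_cutoff` and
#'   restricted to the physically sensible 4–20 A band used for proteins;
#'   ignored by `pf_gnm`.
#' @param model `"gnm_cutoff"` (default) or `"pf_gnm"`.
#'
#' @return An object of class `contact_network`: `n_nodes`, `edges` (m x 2
#'   matrix, i < j), `weights`, `r_cut`, `kirchhoff` (sparse symmetric
#'   `Matrix`), `degrees` (contact counts), `model`, `source_id`.
#' @export
build_kirchhoff <- function(points, r_cut = NULL,
                            model = c("gnm_cutoff", "pf_gnm")) {
  model <- match.arg(model)
  stopifnot(inherits(points, "coord_chain"))
  n <- nrow(points$points)
  if (n < 2L) stop("need at least 2 points")
  if (model == "gnm_cutoff") {
    if (is.null(r_cut)) stop("gnm_cutoff requires `r_cut`")
    if (r_cut < 4 || r_cut > 20)
      stop("r_cut must lie in [4, 20] Angstrom for protein-scale networks")
    net <- kirchhoff_from_cutoff(points$points, r_cut, points$source_id)
    if (any(net$degrees == 0L)) {
      comp <- network_components(net)
      warning(sprintf(
        "network has %d isolated node(s) and %d connected component(s) at r_cut = %g",
        sum(net$degrees == 0L), comp$no, r_cut))
    }
    return(net)
  }
  # pf_gnm: all pairs, weight r^-2
  D <- pair_dists(points$points)
  if (any(D[upper.tri(D)] == 0))
    stop("pf_gnm requires all pairwise distances > 0")
  W <- 1 / D^2
  diag(W) <- 0
  gamma <- -W
  diag(gamma) <- rowSums(W)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  structure(
    list(n_nodes = n, edges = ut, weights = W[ut], r_cut = NULL,
         kirchhoff = Matrix::Matrix(gamma, sparse = FALSE),
         degrees = rep.int(n - 1L, n), model = "pf_gnm",
         source_id = points$source_id),
    class = "contact_network")
}

# cutoff-network Kirchhoff without the protein-range gate (lattice springs
# use sub-protein cutoffs when the spacing is not residue-scale)
kirchhoff_from_cutoff <- function(pts, r_cut, source_id = "") {
  n <- nrow(pts)
  D <- pair_dists(pts)
  A <- (D <= r_cut) & (D > 0)
  ut <- which(upper.tri(A) & A, arr.ind = TRUE)
  deg <- rowSums(A)
  gamma <- Matrix::sparseMatrix(
    i = c(ut[, 1L], ut[, 2L], seq_len(n)),
    j = c(ut[, 2L], ut[, 1L], seq_len(n)),
    x = c(rep.int(-1, 2L * nrow(ut)), deg),
    dims = c(n, n))
  structure(
    list(n_nodes = n, edges = ut, weights = rep.int(1, nrow(ut)),
         r_cut = r_cut, kirchhoff = gamma, degrees = as.integer(deg),
         model = "gnm_cutoff", source_id = source_id),
    class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("<contact_network> %s: %d nodes, %d edges, model %s%s\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              x$n_nodes, nrow(x$edges), x$model,
              if (!is.null(x$r_cut)) sprintf(", r_cut %g A", x$r_cut) else ""))
  invisible(x)
}

#' Connect lattice sites to their first neighbor shells
#'
#' Spring topology for lattice reference systems: every site is connected
#' to its first `shells` neighbor shells. The shell radii are found by
#' ranking the distinct pairwise distances present in the input (so the
#' construction is spacing-agnostic), and the cutoff is placed midway
#' between shell `shells` and shell `shells + 1`.
#'
#' @param points a [coord_chain()] from a lattice generator.
#' @param shells 1 or 2 neighbor shells.
#' @return A `contact_network` (see [build_kirchhoff()]).
#' @export
build_lattice_springs <- function(points, shells = 2L) {
  stopifnot(inherits(points, "coord_chain"), shells %in% c(1L, 2L))
  d <- sort(stats::dist(points$points))
  shell_d <- d[!duplicated(round(d, 6L))]
  if (length(shell_d) <= shells)
    stop("input has too few distinct distances to define the shells")
  r_cut <- (shell_d[shells] + shell_d[shells + 1L]) / 2
  kirchhoff_from_cutoff(points$points, r_cut, points$source_id)
}

#' Symmetric normalized graph Laplacian
#'
#' `L = D^{-1/2} Gamma D^{-1/2}` where `D` is the diagonal of the Kirchhoff
#' matrix. The result has unit diagonal and spectrum in `[0, 2]`, which
#' makes mode distributions comparable across systems of different size.
#'
#' @param net a `contact_network`.
#' @return sparse symmetric `Matrix` with attribute `normalized = TRUE`.
#' @export
normalized_laplacian <- function(net) {
  d <- Matrix::diag(net$kirchhoff)
  if (any(d <= 0)) {
    bad <- which(d <= 0)
    stop(sprintf("zero-degree node(s): %s; normalized Laplacian undefined",
                 paste(utils::head(bad, 10L), collapse = ", ")))
  }
  S <- Matrix::Diagonal(x = 1 / sqrt(d))
  L <- Matrix::forceSymmetric(S %*% net$kirchhoff %*% S)
  attr(L, "normalized") <- TRUE
  L
}

#' Eigen-decomposition of a (normalized) Kirchhoff matrix
#'
#' Returns the ascending eigen-spectrum of a symmetric positive
#' semi-definite matrix, with zero modes counted at a relative tolerance of
#' `1e-9 * lambda_max`. For partial decompositions (`n_modes < N`) a sparse
#' Lanczos solver on the shifted operator is used; the full decomposition
#' uses the dense LAPACK path. The smallest *nonzero* eigenvalue is
#' `values[n_zero + 1]` (see [lambda1()]).
#'
#' @param m symmetric PSD matrix (base or `Matrix`), e.g. a Kirchhoff
#'   matrix or a [normalized_laplacian()].
#' @param n_modes `"all"` (default) or the number of smallest modes wanted.
#' @param solver `"auto"` picks sparse Lanczos for partial requests on
#'   matrices larger than 256, dense otherwise; `"dense"`/`"sparse"` force
#'   the choice. The sparse path falls back to dense if the iteration does
#'   not converge.
#'
#' @return An object of class `mode_spectrum`: `values` (ascending),
#'   `vectors` (orthonormal columns matching `values`), `n_zero`,
#'   `normalized` (TRUE when the input was a normalized Laplacian).
#' @export
eigenmodes <- function(m, n_modes = "all", solver = c("auto", "dense", "sparse")) {
  solver <- match.arg(solver)
  n <- nrow(m)
  partial <- !identical(n_modes, "all")
  if (partial) {
    n_modes <- as.integer(n_modes)
    if (n_modes > n) stop(sprintf("requested %d modes from a %d-node system",
                                  n_modes, n))
  }
  normalized <- isTRUE(attr(m, "normalized"))

  # Gershgorin upper bound on the spectrum; also anchors the zero tolerance
  # when only part of the spectrum is computed.
  msp <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  lam_hi <- max(Matrix::rowSums(abs(msp)))

  use_sparse <- solver == "sparse" ||
    (solver == "auto" && partial && n > 256L && n_modes < n / 2L)
  if (use_sparse && partial && n_modes < n) {
    res <- tryCatch(
      eigs_sym_smallest_cpp(msp, n_modes, shift = lam_hi * 1.01,
                            subdim = max(40L, 4L * n_modes), maxiter = 10000L),
      error = function(e) NULL)
    if (!is.null(res)) {
      return(new_mode_spectrum(res$values, res$vectors, lam_hi, normalized))
    }
    # fall through to dense on non-convergence
  }
  ed <- eigen(as.matrix(m), symmetric = TRUE)
  ord <- order(ed$values)
  vals <- ed$values[ord]
  vecs <- ed$vectors[, ord, drop = FALSE]
  if (partial) {
    vals <- vals[seq_len(n_modes)]
    vecs <- vecs[, seq_len(n_modes), drop = FALSE]
  }
  new_mode_spectrum(vals, vecs, lam_hi, normalized)
}

new_mode_spectrum <- function(values, vectors, lam_hi, normalized) {
  tol <- 1e-9 * lam_hi
  values[abs(values) < tol] <- pmax(values[abs(values) < tol], 0)
  structure(
    list(values = values, vectors = vectors,
         n_zero = sum(values < tol), normalized = normalized),
    class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat(sprintf("<mode_spectrum> %d modes (%d zero), %s; lambda1 = %.6g\n",
              length(x$values), x$n_zero,
              if (x$normalized) "normalized Laplacian" else "raw Kirchhoff",
              lambda1(x)))
  invisible(x)
}

#' Smallest nonzero eigenvalue (slowest mode)
#'
#' Convenience accessor for the slowest nonzero normal mode, the quantity
#' whose size dependence `lambda1 ~ N^-zeta` discriminates ordered,
#' disordered and protein-like systems.
#'
#' @param x a `mode_spectrum`, or a `contact_network` (in which case the
#'   normalized Laplacian spectrum is computed, by default with the sparse
#'   partial solver on large systems).
#' @param normalized for `contact_network` input: use the normalized
#'   Laplacian (default) or the raw Kirchhoff matrix.
#' @return numeric scalar.
#' @export
lambda1 <- function(x, normalized = TRUE) {
  if (inherits(x, "contact_network")) {
    m <- if (normalized) normalized_laplacian(x) else x$kirchhoff
    k <- min(6L, nrow(m) - 1L)
    x <- eigenmodes(m, n_modes = if (nrow(m) > 256L) k else "all")
  }
  stopifnot(inherits(x, "mode_spectrum"))
  if (x$n_zero >= length(x$values))
    stop("no nonzero mode in the computed spectrum")
  x$values[x$n_zero + 1L]
}

#' Residue-fluctuation covariance from a connected network
#'
#' Moore–Penrose pseudoinverse of the Kirchhoff matrix, the GNM covariance
#' with the physical prefactor `3 k_B T / kappa` absorbed into the units
#' (set to 1): every downstream quantity (cross-correlation, correlation
#' length, susceptibility) is scale-free in it. For a connected network the
#' pseudoinverse is computed exactly as `solve(Gamma + J/n) - J/n` with `J`
#' the all-ones matrix, which is fast and satisfies the pseudoinverse
#' identities to machine precision.
#'
#' @param net a connected `contact_network`.
#' @return dense symmetric covariance matrix with zero row sums.
#' @export
covariance_from_network <- function(net) {
  comp <- network_components(net)
  if (comp$no > 1L)
    stop(sprintf("network has %d connected components; covariance is defined for connected networks only",
                 comp$no))
  n <- net$n_nodes
  gamma <- as.matrix(net$kirchhoff)
  C <- solve(gamma + 1 / n) - 1 / n
  (C + t(C)) / 2
}

#' Normalized eigenvalue density g(lambda)
#'
#' Histogram of the nonzero eigenvalues of a normalized spectrum, scaled to
#' unit area, for comparing mode distributions across systems.
#'
#' @param spec a `mode_spectrum` from a normalized Laplacian.
#' @param bin_edges increasing vector of bin edges covering `[0, 2]` by
#'   default.
#' @return data.frame with `mid`, `density`, `count` per bin.
#' @export
mode_density <- function(spec, bin_edges = seq(0, 2, by = 0.05)) {
  stopifnot(inherits(spec, "mode_spectrum"))
  vals <- spec$values[(spec$n_zero + 1L):length(spec$values)]
  h <- graphics::hist(vals, breaks = bin_edges, plot = FALSE)
  data.frame(mid = h$mids, density = h$density, count = h$counts)
}

# connected components of the binary contact graph
network_components <- function(net) {
  igraph::components(as_igraph(net))
}

# binary (unweighted) igraph view of a contact network
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = net$n_nodes, directed = FALSE)
  igraph::add_edges(g, t(net$edges))
}
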