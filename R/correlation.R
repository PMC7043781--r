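# Cross-correlations, distance-dependent correlation functions,
# correlation lengths and finite-size susceptibilities.

#' Pairwise cross-correlation matrix
#'
#' Normalizes a fluctuation covariance to `phi_ij = C_ij / sqrt(C_ii C_jj)`:
#' symmetric, unit diagonal, entries in `[-1, 1]`.
#'
#' @param cov dense covariance matrix with strictly positive diagonal (see
#'   [covariance_from_network()]).
#' @return cross-correlation matrix.
#' @export
cross_correlation <- function(cov) {
  d <- diag(cov)
  if (any(d <= 0)) {
    bad <- which(d <= 0)
    stop(sprintf("non-positive covariance diagonal at node(s): %s",
                 paste(utils::head(bad, 10L), collapse = ", ")))
  }
  s <- 1 / sqrt(d)
  phi <- cov * tcrossprod(s)
  diag(phi) <- 1
  phi
}

#' Distance-dependent correlation function phi(r)
#'
#' Averages the pairwise cross-correlations over all unordered residue
#' pairs falling in half-open distance bins `[k w, (k+1) w)`: the discrete
#' realization of the delta-function pair selection. A pair sitting exactly
#' on a bin edge belongs to the upper bin.
#'
#' @param phi_matrix cross-correlation matrix.
#' @param distances matching pairwise distance matrix (or `dist` object),
#'   Angstrom.
#' @param bin_width bin width `w` in Angstrom (default 1).
#' @param rescaled logical flag recording whether `distances` were already
#'   divided by the radius of gyration (the `r/Rg` collapse axis).
#'
#' @return An object of class `correlation_profile`: `bin_centers`, `phi`
#'   (per-bin mean), `counts` (pairs per bin; empty bins are dropped),
#'   `bin_width`, `rescaled`.
#' @export
correlation_function <- function(phi_matrix, distances, bin_width = 1,
                                 rescaled = FALSE) {
  stopifnot(bin_width > 0)
  D <- if (inherits(distances, "dist")) as.matrix(distances) else as.matrix(distances)
  if (!all(dim(D) == dim(phi_matrix)))
    stop("`distances` and `phi_matrix` dimensions differ")
  ut <- upper.tri(D)
  r <- D[ut]
  v <- phi_matrix[ut]
  idx <- floor(r / bin_width)  # half-open [k w, (k+1) w)
  agg_mean <- tapply(v, idx, mean)
  agg_n <- tapply(v, idx, length)
  k <- as.numeric(names(agg_mean))
  ord <- order(k)
  structure(
    list(bin_centers = (k[ord] + 0.5) * bin_width,
         phi = unname(agg_mean[ord]),
         counts = unname(as.integer(agg_n[ord])),
         bin_width = bin_width, rescaled = isTRUE(rescaled)),
    class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("<correlation_profile> %d occupied bins (width %g%s), r in [%g, %g]\n",
              length(x$bin_centers), x$bin_width,
              if (x$rescaled) ", r/Rg axis" else " A",
              min(x$bin_centers), max(x$bin_centers)))
  invisible(x)
}

#' Correlation length: first zero crossing of phi(r)
#'
#' The distance at which the binned correlation function first decays to
#' zero, located by linear interpolation between the last positive bin and
#' the first non-positive bin. Profiles that never cross zero are censored:
#' the largest occupied bin center is returned with attribute
#' `censored = TRUE` (such profiles are excluded from scaling fits).
#'
#' @param profile a `correlation_profile` with at least 2 occupied bins.
#' @return numeric scalar (Angstrom, or `r/Rg` units for rescaled
#'   profiles) with logical attribute `censored`.
#' @export
correlation_length <- function(profile) {
  stopifnot(inherits(profile, "correlation_profile"))
  ctr <- profile$bin_centers
  phi <- profile$phi
  if (length(ctr) < 2L) stop("need at least 2 occupied bins")
  j <- which(phi <= 0)[1L]
  if (is.na(j)) {
    xi <- ctr[length(ctr)]
    attr(xi, "censored") <- TRUE
    return(xi)
  }
  if (j == 1L || phi[j] == 0) {
    xi <- ctr[j]
  } else {
    xi <- ctr[j - 1L] + (ctr[j] - ctr[j - 1L]) * phi[j - 1L] / (phi[j - 1L] - phi[j])
  }
  attr(xi, "censored") <- FALSE
  xi
}

#' Finite-size susceptibility chi
#'
#' Total correlation per residue within the correlation length, weighted by
#' the shape factor: `chi = (s / N) * sum_{i<j} phi_ij * theta(xi - r_ij)`,
#' with a strict Heaviside step (pairs at exactly `r_ij = xi` are
#' excluded).
#'
#' @param phi_matrix cross-correlation matrix.
#' @param distances matching pairwise distance matrix (or `dist`), Angstrom.
#' @param xi correlation length, Angstrom (> 0).
#' @param s shape factor (> 0).
#' @param n chain length `N`.
#' @return numeric scalar, dimensionless.
#' @export
susceptibility <- function(phi_matrix, distances, xi, s, n) {
  stopifnot(xi > 0, s > 0, n >= 1)
  D <- as.matrix(distances)
  ut <- upper.tri(D)
  sel <- ut & (D < xi)
  (s / n) * sum(phi_matrix[sel])
}

#' Group-averaged correlation function for a size window
#'
#' Averages the correlation profiles of all structures whose radius of
#' gyration falls in the half-open 1-Angstrom window
#' `[center - 0.5, center + 0.5)`, weighting each structure equally. For
#' each distance bin the mean runs over the member profiles that have that
#' bin occupied.
#'
#' @param profiles list of `correlation_profile`s (all with the same bin
#'   width and the same axis convention).
#' @param rg_values radius of gyration per profile, Angstrom.
#' @param rg_bin_center window center, Angstrom.
#' @return A `correlation_profile` whose `counts` give the number of member
#'   structures contributing to each bin.
#' @export
group_average <- function(profiles, rg_values, rg_bin_center) {
  stopifnot(length(profiles) == length(rg_values))
  sel <- rg_values >= rg_bin_center - 0.5 & rg_values < rg_bin_center + 0.5
  if (!any(sel))
    stop(sprintf("no structure with Rg in [%g, %g); available Rg range is [%g, %g]",
                 rg_bin_center - 0.5, rg_bin_center + 0.5,
                 min(rg_values), max(rg_values)))
  members <- profiles[sel]
  w <- unique(vapply(members, function(p) p$bin_width, numeric(1L)))
  if (length(w) != 1L) stop("member profiles have differing bin widths")
  resc <- unique(vapply(members, function(p) p$rescaled, logical(1L)))
  if (length(resc) != 1L) stop("member profiles mix r and r/Rg axes")
  centers <- sort(unique(unlist(lapply(members, function(p) p$bin_centers))))
  phi <- vapply(centers, function(ctr) {
    vals <- unlist(lapply(members, function(p) {
      hit <- which(abs(p$bin_centers - ctr) < 1e-9)
      if (length(hit)) p$phi[hit] else NULL
    }))
    mean(vals)
  }, numeric(1L))
  counts <- vapply(centers, function(ctr) {
    sum(vapply(members, function(p) any(abs(p$bin_centers - ctr) < 1e-9),
               logical(1L)))
  }, integer(1L))
  structure(
    list(bin_centers = centers, phi = phi, counts = counts,
         bin_width = w, rescaled = resc),
    class = "correlation_profile")
}
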