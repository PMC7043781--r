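# Finite-size scaling: size-binning of per-structure descriptors and
# power-law exponent extraction by log-log regression.

#' Fit a power law by log-log least squares
#'
#' Ordinary least squares on `(log10 x, log10 y)`. The fitted slope is
#' returned as the exponent (callers apply their sign convention, e.g.
#' `lambda1 ~ N^-zeta` stores `zeta = -slope`), the back-transformed
#' intercept as the prefactor.
#'
#' @param x,y strictly positive vectors, length >= 3.
#' @return An object of class `power_law_fit`: `exponent`, `prefactor`,
#'   `stderr_exponent`, `r_squared`, `n_points`.
#' @export
fit_power_law <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 points for a power-law fit")
  bad <- which(!(x > 0) | !(y > 0))
  if (length(bad))
    stop("non-positive value(s) at position(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  fit <- stats::lm(ly ~ lx, data = data.frame(lx = log10(x), ly = log10(y)))
  # summary.lm warns on exact log-linear data; the zero stderr is correct
  sm <- suppressWarnings(summary(fit))
  structure(
    list(exponent = unname(stats::coef(fit)[2L]),
         prefactor = 10^unname(stats::coef(fit)[1L]),
         stderr_exponent = unname(sm$coefficients[2L, 2L]),
         r_squared = sm$r.squared,
         n_points = length(x)),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> exponent = %.4f +/- %.4f, prefactor = %.4g, R^2 = %.4f (n = %d)\n",
              x$exponent, x$stderr_exponent, x$prefactor, x$r_squared,
              x$n_points))
  invisible(x)
}

#' Fit the modularity finite-size scaling law
#'
#' Fits `Q = 1 - K * N^-eta` by applying [fit_power_law()] to `(N, 1 - Q)`.
#' The returned fit stores the positive exponent `eta` and the prefactor
#' `K`.
#'
#' @param n_values system sizes.
#' @param q_values Louvain-maximized modularities, all `< 1`.
#' @return A `power_law_fit` with `exponent = eta > 0` and
#'   `prefactor = K`.
#' @export
fit_modularity_scaling <- function(n_values, q_values) {
  if (any(q_values >= 1)) stop("modularity values must be < 1")
  f <- fit_power_law(n_values, 1 - q_values)
  f$exponent <- -f$exponent
  f
}

#' Effective dimension from the modularity exponent
#'
#' Inverts the lattice modularity-scaling relation `eta = 1 / (d + 1)`:
#' `d_eff = 1 / eta - 1`. A 3D cubic lattice (`eta = 1/4`) maps to 3; the
#' ideal-polymer value 0.465 maps to about 1.15.
#'
#' @param eta modularity scaling exponent in `(0, 1)`.
#' @return effective dimension, dimensionless.
#' @export
effective_dimension <- function(eta) {
  if (!is.finite(eta) || eta <= 0 || eta >= 1)
    stop("eta must lie strictly between 0 and 1")
  1 / eta - 1
}

#' Bin per-structure records by size
#'
#' Half-open size bins `[lo, hi)` over a chosen key column, returning
#' per-bin means of every numeric descriptor plus member counts; bins with
#' fewer than `min_count` members are flagged (they are typically excluded
#' from fits).
#'
#' @param records data.frame of per-structure descriptor rows (e.g. from
#'   [run_dataset()]).
#' @param key name of the size column to bin on, `"N"` or `"rg"`.
#' @param breaks increasing vector of bin edges.
#' @param min_count minimum members for an unflagged bin (default 5).
#' @return data.frame with `bin_lo`, `bin_hi`, `bin_mid`, `n_members`,
#'   `flagged`, and the per-bin mean of each numeric column.
#' @export
bin_by_size <- function(records, key = c("N", "rg"), breaks, min_count = 5L) {
  key <- match.arg(key)
  if (!key %in% names(records)) stop("records lack column ", key)
  v <- records[[key]]
  idx <- findInterval(v, breaks, rightmost.closed = FALSE, left.open = FALSE)
  keep <- idx >= 1L & idx < length(breaks)  # [lo, hi) half-open bins
  idx <- idx[keep]
  recs <- records[keep, , drop = FALSE]
  num_cols <- names(recs)[vapply(recs, is.numeric, logical(1L))]
  out <- do.call(rbind, lapply(sort(unique(idx)), function(b) {
    rows <- recs[idx == b, , drop = FALSE]
    means <- lapply(num_cols, function(cc) mean(rows[[cc]], na.rm = TRUE))
    names(means) <- num_cols
    cbind(data.frame(bin_lo = breaks[b], bin_hi = breaks[b + 1L],
                     bin_mid = (breaks[b] + breaks[b + 1L]) / 2,
                     n_members = nrow(rows),
                     flagged = nrow(rows) < min_count),
          as.data.frame(means))
  }))
  rownames(out) <- NULL
  out
}
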