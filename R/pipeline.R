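# End-to-end orchestration: one structure (or generated system) in, one
# descriptor row out; a dataset in, a descriptor table plus scaling fits
# out.

#' Analysis configuration
#'
#' One declarative bundle of every tunable the pipeline uses, echoed into
#' the output for provenance. The two cutoffs are carried simultaneously so
#' a single pass yields both the correlation-family quantities (9 A
#' convention) and the topology-family quantities (8 A convention).
#'
#' @param r_cut_corr cutoff for the correlation/spectrum network, Angstrom.
#' @param r_cut_topo cutoff for the topology network, Angstrom.
#' @param bin_width phi(r) bin width, Angstrom.
#' @param min_n,max_n chain-length filter applied to inputs (the dataset
#'   convention is 30 <= N <= 1200 for proteins; generated reference
#'   systems may raise `max_n`).
#' @param louvain_restarts restarts for [best_partition()].
#' @param seed base seed for all stochastic steps (Louvain order, path
#'   sampling).
#' @param springs `"cutoff"` for distance-cutoff networks (proteins,
#'   polymers) or `"shells"` for lattice shell springs (1st + 2nd neighbor
#'   shells); with `"shells"` a single network serves both families.
#' @param a residue size constant for the shape factor, Angstrom.
#' @param compute which descriptor families to evaluate; dropping
#'   `"correlation"` skips the O(N^3) covariance step in topology-only
#'   sweeps.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(r_cut_corr = 9, r_cut_topo = 8, bin_width = 1,
                            min_n = 30L, max_n = 1200L,
                            louvain_restarts = 10L, seed = 1L,
                            springs = c("cutoff", "shells"), a = 3.8,
                            compute = c("geometry", "spectrum",
                                        "correlation", "topology")) {
  springs <- match.arg(springs)
  compute <- match.arg(compute, several.ok = TRUE)
  structure(as.list(environment()), class = "analysis_config")
}

#' Analyze a single structure or generated system
#'
#' Runs the full per-structure pipeline: parse/accept coordinates, build
#' the contact network(s), compute the slowest nonzero normalized-Laplacian
#' mode, the covariance-derived correlation statistics (phi(r), xi, chi),
#' the topology descriptors (average path length, Louvain modularity) and
#' the geometric descriptors (Rg, shape factor). Partial failures are
#' recorded per field (NA plus a reason code) and the row is still emitted;
#' structures outside the chain-length filter return `NULL` with a message.
#'
#' @param x a [coord_chain()] or a path to a PDB file.
#' @param config an [analysis_config()].
#' @return one-row data.frame with columns `source_id`, `N`, `rg`,
#'   `mean_path`, `lambda1`, `s`, `chi`, `q`, `n_communities`, `xi`,
#'   `censored_xi`, `r_cut_corr`, `r_cut_topo`, `reason`; or `NULL` when
#'   the size filter rejects the input.
#' @export
run_structure <- function(x, config = analysis_config()) {
  chain <- if (inherits(x, "coord_chain")) x else parse_structure(x)
  n <- chain_length(chain)
  if (n < config$min_n || n > config$max_n) {
    message(sprintf("skipping %s: N = %d outside [%d, %d]",
                    chain$source_id, n, config$min_n, config$max_n))
    return(NULL)
  }
  row <- data.frame(source_id = chain$source_id, N = n, rg = NA_real_,
                    mean_path = NA_real_, lambda1 = NA_real_, s = NA_real_,
                    chi = NA_real_, q = NA_real_, n_communities = NA_integer_,
                    xi = NA_real_, censored_xi = NA,
                    r_cut_corr = config$r_cut_corr,
                    r_cut_topo = config$r_cut_topo,
                    reason = "", stringsAsFactors = FALSE)
  reasons <- character(0L)
  note <- function(msg) reasons <<- c(reasons, msg)

  shape <- NULL
  if ("geometry" %in% config$compute) {
    row$rg <- radius_of_gyration(chain)
    shape <- tryCatch(shape_factor(chain, a = config$a),
                      error = function(e) {
                        note(paste0("shape:", conditionMessage(e)))
                        NULL
                      })
    if (!is.null(shape)) row$s <- shape$s
  }

  if (config$springs == "shells") {
    net_corr <- net_topo <- build_lattice_springs(chain, shells = 2L)
    row$r_cut_corr <- row$r_cut_topo <- net_corr$r_cut
  } else {
    net_corr <- build_kirchhoff(chain, r_cut = config$r_cut_corr)
    net_topo <- build_kirchhoff(chain, r_cut = config$r_cut_topo)
  }
  corr_connected <- network_components(net_corr)$no == 1L
  topo_connected <- network_components(net_topo)$no == 1L

  if ("spectrum" %in% config$compute) {
    if (corr_connected) {
      row$lambda1 <- lambda1(net_corr)
    } else note("lambda1:disconnected")
  }

  if ("correlation" %in% config$compute) {
    if (corr_connected) {
      C <- covariance_from_network(net_corr)
      phi <- cross_correlation(C)
      D <- pair_dists(chain$points)
      prof <- correlation_function(phi, D, bin_width = config$bin_width)
      xi <- correlation_length(prof)
      row$xi <- as.numeric(xi)
      row$censored_xi <- isTRUE(attr(xi, "censored"))
      if (!is.null(shape) && !row$censored_xi) {
        row$chi <- susceptibility(phi, D, xi = row$xi, s = shape$s, n = n)
      } else if (is.null(shape)) {
        note("chi:no shape factor")
      } else note("chi:censored xi")
    } else note("chi/xi:disconnected")
  }

  if ("topology" %in% config$compute) {
    if (topo_connected) {
      row$mean_path <- as.numeric(
        average_path_length(net_topo, seed = config$seed))
      part <- best_partition(net_topo, n_restarts = config$louvain_restarts,
                             seed = config$seed)
      row$q <- part$q
      row$n_communities <- part$n_communities
    } else note("topology:disconnected")
  }

  row$reason <- paste(reasons, collapse = ";")
  row
}

#' Analyze a dataset and extract scaling fits
#'
#' Applies [run_structure()] to every input, concatenates the descriptor
#' rows, and fits the finite-size scaling laws on per-size means:
#' `lambda1 ~ N^-zeta`, `<l> ~ N^alpha`, `1 - Q ~ N^-eta`, `chi ~ N^c`,
#' and `xi ~ Rg` (censored xi rows are excluded). Individual rows are
#' retained so per-seed realizations remain inspectable.
#'
#' @param inputs list of [coord_chain()] objects and/or PDB paths.
#' @param config an [analysis_config()].
#' @return list of class `dataset_report`: `records` (data.frame), `fits`
#'   (named list of `power_law_fit`s; a fit is `NULL` when fewer than 3
#'   usable sizes exist), `n_skipped`, `config`.
#' @export
run_dataset <- function(inputs, config = analysis_config()) {
  if (length(inputs) == 0L) stop("empty input list")
  rows <- lapply(inputs, function(x)
    tryCatch(run_structure(x, config), error = function(e) {
      warning(sprintf("structure failed: %s", conditionMessage(e)))
      NULL
    }))
  skipped <- sum(vapply(rows, is.null, logical(1L)))
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) stop("all structures failed or were filtered out")
  records <- do.call(rbind, rows)

  size_mean <- function(col, filter = rep(TRUE, nrow(records))) {
    use <- filter & !is.na(records[[col]])
    if (!any(use)) return(NULL)
    agg <- tapply(records[[col]][use], records$N[use], mean)
    list(n = as.numeric(names(agg)), y = unname(agg))
  }
  safe_fit <- function(sm, negate = FALSE) {
    if (is.null(sm) || length(sm$n) < 3L) return(NULL)
    f <- tryCatch(fit_power_law(sm$n, sm$y), error = function(e) NULL)
    if (!is.null(f) && negate) f$exponent <- -f$exponent
    f
  }
  fits <- list(
    zeta = safe_fit(size_mean("lambda1"), negate = TRUE),
    alpha = safe_fit(size_mean("mean_path")),
    eta = {
      sm <- size_mean("q")
      if (is.null(sm) || length(sm$n) < 3L || any(sm$y >= 1)) NULL
      else fit_modularity_scaling(sm$n, sm$y)
    },
    chi_exponent = safe_fit(size_mean("chi")),
    xi_vs_rg = {
      use <- !is.na(records$xi) & records$censored_xi %in% FALSE &
        !is.na(records$rg)
      if (sum(use) >= 3L)
        tryCatch(fit_power_law(records$rg[use], records$xi[use]),
                 error = function(e) NULL)
      else NULL
    })
  structure(list(records = records, fits = fits, n_skipped = skipped,
                 config = config),
            class = "dataset_report")
}

#' @export
print.dataset_report <- function(x, ...) {
  cat(sprintf("<dataset_report> %d structure(s), %d skipped\n",
              nrow(x$records), x$n_skipped))
  for (nm in names(x$fits)) {
    if (!is.null(x$fits[[nm]]))
      cat(sprintf("  %-12s exponent %.4f +/- %.4f (R^2 = %.3f, n = %d)\n",
                  nm, x$fits[[nm]]$exponent, x$fits[[nm]]$stderr_exponent,
                  x$fits[[nm]]$r_squared, x$fits[[nm]]$n_points))
  }
  invisible(x)
}
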