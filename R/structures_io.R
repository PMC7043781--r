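# Coordinate input and geometric descriptors: Calpha chains, radius of
# gyration, and the inertia-ellipsoid shape factor.

#' Ordered 3D point set
#'
#' Container for an ordered set of 3D coordinates (in Angstrom): the Calpha
#' trace of a protein chain, the sites of a generated lattice cluster, or
#' the beads of a generated polymer. All analysis operations in the package
#' take one of these as input.
#'
#' @param points numeric matrix with one row per point and three columns
#'   (x, y, z), in Angstrom.
#' @param labels optional per-point identifiers (residue number plus
#'   insertion code, or lattice/bead index). Defaults to `1:N`.
#' @param source_id free-text origin tag, e.g. `"1abc_A"` or `"fcc_n500"`.
#' @param is_chain logical; `TRUE` when the point order is a covalent
#'   backbone (consecutive points are bonded).
#'
#' @return An object of class `coord_chain` with fields `points`, `labels`,
#'   `source_id`, `is_chain`.
#' @export
coord_chain <- function(points, labels = NULL, source_id = "", is_chain = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("`points` must have three columns (x, y, z)")
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    stop("`points` contains non-finite coordinates")
  n <- nrow(points)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (length(labels) != n)
    stop("`labels` length must match the number of points")
  if (is_chain && n >= 2L) {
    bl <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                          points[-n, , drop = FALSE])^2))
    if (any(bl <= 0))
      stop("is_chain = TRUE but some consecutive points coincide")
  }
  structure(
    list(points = points, labels = as.character(labels),
         source_id = source_id, is_chain = isTRUE(is_chain)),
    class = "coord_chain")
}

#' @export
print.coord_chain <- function(x, ...) {
  cat(sprintf("<coord_chain> %s: N = %d, %s\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              nrow(x$points),
              if (x$is_chain) "backbone chain" else "unordered point set"))
  invisible(x)
}

#' Number of points in a coordinate chain
#' @param chain a [coord_chain()].
#' @return integer point count.
#' @export
chain_length <- function(chain) nrow(chain$points)

#' Parse Calpha coordinates from a PDB entry
#'
#' Reads the Calpha trace of one chain of a fixed-column PDB file (ATOM
#' records, wwPDB v3.3 columns), one point per residue in residue order.
#' HETATM records are ignored. When a residue carries alternate-location
#' duplicates, the highest-occupancy copy wins; occupancy ties resolve to
#' the alphabetically first altloc (i.e. 'A').
#'
#' @param pdb path to a PDB file, or a character scalar/vector holding PDB
#'   text (detected by embedded newlines or multiple elements).
#' @param chain_id one-letter chain identifier. `NULL` (default) selects the
#'   first chain that contains Calpha atoms.
#' @param model_index 1-based model number for multi-model (e.g. NMR)
#'   entries; the default first model is the convention for X-ray entries.
#'
#' @return A [coord_chain()] with `is_chain = TRUE`, labelled by residue
#'   number (plus insertion code when present).
#' @export
parse_structure <- function(pdb, chain_id = NULL, model_index = 1L) {
  path <- pdb
  if (length(pdb) > 1L || any(grepl("\n", pdb, fixed = TRUE))) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), path)
    on.exit(unlink(path))
  }
  if (!file.exists(path)) stop("cannot read PDB input: ", path)
  pdbobj <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atoms <- pdbobj$atom
  ca <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no Calpha ATOM records found")
  available <- unique(ca$chain)
  if (is.null(chain_id)) chain_id <- available[1L]
  if (!chain_id %in% available)
    stop(sprintf("chain '%s' not found; available chains with Calpha atoms: %s",
                 chain_id, paste(available, collapse = ", ")))
  ca <- ca[ca$chain == chain_id, , drop = FALSE]

  # resolve altloc duplicates per residue (resno + insertion code)
  ins <- ca$insert
  ins[is.na(ins)] <- ""
  key <- paste(ca$resno, ins, sep = "_")
  occ <- ca$o
  occ[is.na(occ)] <- 1
  alt <- ca$alt
  alt[is.na(alt)] <- ""
  keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(key, levels = unique(key))),
                        function(idx) {
                          idx[order(-occ[idx], alt[idx])][1L]
                        }), use.names = FALSE)
  keep <- sort(keep)  # preserve file order
  ca <- ca[keep, , drop = FALSE]
  if (nrow(ca) < 2L)
    stop(sprintf("chain '%s' has fewer than 2 Calpha atoms", chain_id))

  n_models <- if (is.matrix(pdbobj$xyz)) nrow(pdbobj$xyz) else 1L
  if (model_index < 1L || model_index > n_models)
    stop(sprintf("model_index %d out of range (entry has %d model(s))",
                 model_index, n_models))
  if (model_index == 1L) {
    xyz <- cbind(ca$x, ca$y, ca$z)
  } else {
    # pull the selected model's coordinates for the kept atom rows
    atom_rows <- as.integer(rownames(ca))
    cols <- as.vector(t(outer(atom_rows - 1L, 1:3, function(i, k) 3L * i + k)))
    xyz <- matrix(pdbobj$xyz[model_index, cols], ncol = 3L, byrow = TRUE)
  }

  ins2 <- ins[keep]
  labels <- paste0(ca$resno, ifelse(nzchar(ins2), ins2, ""))
  src <- paste0(sub("\\.pdb$", "", basename(path)), "_", chain_id)
  coord_chain(xyz, labels = labels, source_id = src, is_chain = TRUE)
}

#' Write a coordinate chain as minimal PDB text
#'
#' Emits fixed-column ATOM records (one CA pseudo-atom per point) so that
#' generated systems can be inspected with standard structure viewers and
#' round-tripped through [parse_structure()]. Coordinates are written with
#' the PDB's fixed 3-decimal precision.
#'
#' @param chain a [coord_chain()].
#' @param path output file; when `NULL` the text is returned invisibly as a
#'   character vector instead.
#' @param chain_id one-letter chain identifier to stamp on the records.
#' @return Invisibly, the PDB lines.
#' @export
write_pdb_ca <- function(chain, path = NULL, chain_id = "A") {
  pts <- chain$points
  n <- nrow(pts)
  if (n > 9999L) stop("PDB fixed columns cannot hold more than 9999 residues")
  lines <- sprintf(
    "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), chain_id, seq_len(n), pts[, 1L], pts[, 2L], pts[, 3L])
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read/write the internal xyz table
#'
#' Whitespace-delimited table with one point per line (`index x y z`), the
#' package's plain-text interchange format for generated systems.
#'
#' @param path file path.
#' @param chain a [coord_chain()] (for writing).
#' @param source_id origin tag attached on reading.
#' @param is_chain backbone flag attached on reading.
#' @return `read_xyz` returns a [coord_chain()].
#' @export
read_xyz <- function(path, source_id = basename(path), is_chain = FALSE) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("index", "x", "y", "z"))
  coord_chain(as.matrix(tab[, c("x", "y", "z")]), labels = tab$index,
              source_id = source_id, is_chain = is_chain)
}

#' @rdname read_xyz
#' @export
write_xyz <- function(chain, path) {
  tab <- data.frame(index = chain$labels,
                    x = chain$points[, 1L],
                    y = chain$points[, 2L],
                    z = chain$points[, 3L])
  utils::write.table(tab, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Radius of gyration
#'
#' Root-mean-square distance of the points from their centroid, in Angstrom.
#'
#' @param chain a [coord_chain()] (or a bare coordinate matrix).
#' @return numeric scalar, Angstrom.
#' @export
radius_of_gyration <- function(chain) {
  pts <- if (inherits(chain, "coord_chain")) chain$points else as.matrix(chain)
  ctr <- colMeans(pts)
  sqrt(mean(rowSums(sweep(pts, 2L, ctr)^2)))
}

#' Inertia-ellipsoid shape factor
#'
#' Residue packing density within the inertia ellipsoid of the molecule:
#' `s = N a^3 / (L1 L2 L3)` with `a` the residue size and `L1 >= L2 >= L3`
#' the principal semi-axes of the equivalent uniform solid ellipsoid,
#' obtained from the gyration-tensor eigenvalues `mu_i` as
#' `L_i = sqrt(5 mu_i)`. Compact globular folds give larger `s`; elongated
#' or multi-domain architectures with linkers give smaller `s`.
#'
#' @param chain a [coord_chain()] with at least 4 non-coplanar points.
#' @param a residue size constant, Angstrom (default 3.8, the Calpha
#'   virtual-bond length).
#'
#' @return An object of class `shape_descriptor`: list with `rg` (radius of
#'   gyration, A), `axes` (the three semi-axes `L1 >= L2 >= L3`, A), `s`
#'   (dimensionless shape factor) and `a`.
#' @export
shape_factor <- function(chain, a = 3.8) {
  pts <- if (inherits(chain, "coord_chain")) chain$points else as.matrix(chain)
  n <- nrow(pts)
  if (n < 4L) stop("shape factor needs at least 4 points")
  ctr <- sweep(pts, 2L, colMeans(pts))
  gyr <- crossprod(ctr) / n
  mu <- sort(eigen(gyr, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (mu[3L] <= 1e-10 * mu[1L])
    stop("degenerate gyration tensor (collinear or coplanar points); ",
         "shape factor is undefined")
  axes <- sqrt(5 * mu)
  structure(
    list(rg = sqrt(sum(mu)), axes = axes,
         s = n * a^3 / prod(axes), a = a),
    class = "shape_descriptor")
}

#' @export
print.shape_descriptor <- function(x, ...) {
  cat(sprintf(
    "<shape_descriptor> s = %.3f  Rg = %.2f A  semi-axes = %.2f, %.2f, %.2f A\n",
    x$s, x$rg, x$axes[1L], x$axes[2L], x$axes[3L]))
  invisible(x)
}
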