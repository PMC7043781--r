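test_that("cutoff Kirchhoff matrices match hand-built cases", {
  two <- coord_chain(rbind(c(0, 0, 0), c(5, 0, 0)))
  g2 <- build_kirchhoff(two, r_cut = 9)
  expect_equal(as.matrix(g2$kirchhoff), rbind(c(1, -1), c(-1, 1)),
               ignore_attr = TRUE)

  three <- coord_chain(cbind(c(0, 5, 10), 0, 0))
  g3 <- build_kirchhoff(three, r_cut = 9)
  expect_equal(as.matrix(g3$kirchhoff),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)

  # row sums zero, symmetric, off-diagonals <= 0 on a generated system
  net <- build_kirchhoff(generate_ideal_chain(80, seed = 1), r_cut = 9)
  G <- as.matrix(net$kirchhoff)
  expect_equal(rowSums(G), rep(0, 80), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(G, t(G))
  expect_true(all(G[row(G) != col(G)] <= 0))
})

test_that("lattice shell springs give the textbook coordination numbers", {
  fcc <- generate_fcc_cluster(300)
  expect_equal(max(build_lattice_springs(fcc, shells = 2)$degrees), 18L)
  cub <- generate_cubic_lattice(c(7, 7, 7))
  expect_equal(max(build_lattice_springs(cub, shells = 1)$degrees), 6L)
  expect_equal(max(build_lattice_springs(cub, shells = 2)$degrees), 18L)
  # equivalent to a cutoff between the 2nd and 3rd shell distances
  net2 <- build_lattice_springs(fcc, shells = 2)
  expect_gt(net2$r_cut, 3.8 * sqrt(2))
  expect_lt(net2$r_cut, 3.8 * sqrt(3))
})

test_that("pf_gnm connects all pairs with inverse-square weights", {
  ch <- generate_ideal_chain(20, seed = 3)
  net <- build_kirchhoff(ch, model = "pf_gnm")
  G <- as.matrix(net$kirchhoff)
  D <- as.matrix(dist(ch$points))
  i <- 2; j <- 17
  expect_equal(G[i, j], -1 / D[i, j]^2)
  expect_equal(rowSums(G), rep(0, 20), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(nrow(net$edges), choose(20, 2))
  # the full downstream pipeline runs on the variant
  expect_no_error(lambda1(net))
  expect_no_error(covariance_from_network(net))
})

test_that("normalized Laplacian has unit diagonal and known small-graph forms", {
  two <- build_kirchhoff(coord_chain(rbind(c(0, 0, 0), c(5, 0, 0))), r_cut = 9)
  expect_equal(as.matrix(normalized_laplacian(two)),
               rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)

  # complete graph K4: off-diagonals -1/3
  k4 <- net_from_edges(4, t(combn(4, 2)))
  L4 <- as.matrix(normalized_laplacian(k4))
  expect_equal(diag(L4), rep(1, 4), ignore_attr = TRUE)
  expect_equal(L4[upper.tri(L4)], rep(-1 / 3, 6), tolerance = 1e-12)

  # star S3: center-leaf entries -1/sqrt(3)
  star <- net_from_edges(4, cbind(1, 2:4))
  Ls <- as.matrix(normalized_laplacian(star))
  expect_equal(Ls[1, 2:4], rep(-1 / sqrt(3), 3), tolerance = 1e-12)

  iso <- net_from_edges(3, rbind(c(1, 2)))
  expect_error(normalized_laplacian(iso), "zero-degree")
})

test_that("eigenmodes reproduce exact small-graph spectra and count zero modes", {
  p3 <- net_from_edges(3, rbind(c(1, 2), c(2, 3)))
  sp <- eigenmodes(p3$kirchhoff)
  expect_equal(sp$values, c(0, 1, 3), tolerance = 1e-10)
  expect_equal(sp$n_zero, 1L)
  expect_equal(crossprod(sp$vectors), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)

  k4 <- net_from_edges(4, t(combn(4, 2)))
  expect_equal(eigenmodes(k4$kirchhoff)$values, c(0, 4, 4, 4),
               tolerance = 1e-10)

  two_edges <- net_from_edges(4, rbind(c(1, 2), c(3, 4)))
  expect_equal(eigenmodes(two_edges$kirchhoff)$n_zero, 2L)

  expect_error(eigenmodes(p3$kirchhoff, n_modes = 5), "3-node")
})

test_that("normalized spectra lie in [0, 2] and lambda1 skips zero modes", {
  net <- build_lattice_springs(generate_fcc_cluster(150), shells = 2)
  sp <- eigenmodes(normalized_laplacian(net))
  expect_gte(min(sp$values), -1e-12)
  expect_lte(max(sp$values), 2 + 1e-12)
  expect_equal(lambda1(sp), sp$values[2])
  expect_gt(lambda1(sp), 0)
})

test_that("dense and sparse solvers agree on the slowest nonzero mode", {
  net <- build_lattice_springs(generate_fcc_cluster(320), shells = 2)
  L <- normalized_laplacian(net)
  dense <- eigenmodes(L, solver = "dense")
  sparse <- eigenmodes(L, n_modes = 4, solver = "sparse")
  expect_equal(lambda1(sparse), lambda1(dense), tolerance = 1e-8)
  expect_equal(sparse$values[1], 0, tolerance = 1e-10)
})

test_that("normalized-Laplacian lambda1 is invariant to coordinate rescaling", {
  fcc <- generate_fcc_cluster(180, spacing = 3.8)
  fcc2 <- generate_fcc_cluster(180, spacing = 7.6)
  l1a <- lambda1(build_lattice_springs(fcc, shells = 2))
  l1b <- lambda1(build_lattice_springs(fcc2, shells = 2))
  expect_equal(l1a, l1b, tolerance = 1e-10)
})

test_that("covariance is the Kirchhoff pseudoinverse", {
  rc <- random_connected_chain(20, seed = 42)
  C <- covariance_from_network(rc$net)
  G <- as.matrix(rc$net$kirchhoff)
  expect_equal(G %*% C %*% G, G, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(C %*% G %*% C, C, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rowSums(C), rep(0, 20), tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diag(C) > 0))

  # independent spectral-sum oracle on the path graph P3
  p3 <- net_from_edges(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(covariance_from_network(p3), oracle_pinv(p3$kirchhoff),
               tolerance = 1e-10, ignore_attr = TRUE)

  disc <- net_from_edges(4, rbind(c(1, 2), c(3, 4)))
  expect_error(covariance_from_network(disc), "2 connected components")
})

test_that("mode density integrates to one and lands in the right bins", {
  net <- build_lattice_springs(generate_fcc_cluster(100), shells = 2)
  sp <- eigenmodes(normalized_laplacian(net))
  h <- mode_density(sp)
  expect_equal(sum(h$density * diff(seq(0, 2, by = 0.05))), 1, tolerance = 1e-9)

  k4 <- net_from_edges(4, t(combn(4, 2)))
  spk <- eigenmodes(normalized_laplacian(k4))
  hk <- mode_density(spk, bin_edges = seq(0, 2, by = 0.1))
  expect_equal(sum(hk$count > 0), 1L)   # all nonzero modes at 4/3
  occ <- hk[hk$count > 0, ]
  expect_equal(occ$density, 1 / 0.1, tolerance = 1e-9)
})
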