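test_that("cross-correlation is a unit-diagonal normalization of the covariance", {
  rc <- random_connected_chain(15, seed = 8)
  C <- covariance_from_network(rc$net)
  phi <- cross_correlation(C)
  expect_equal(diag(phi), rep(1, 15), ignore_attr = TRUE)
  expect_true(all(phi >= -1 - 1e-12 & phi <= 1 + 1e-12))
  expect_equal(phi, t(phi))
  expect_equal(cross_correlation(diag(4)), diag(4))

  # element-wise brute force on P3
  p3 <- net_from_edges(3, rbind(c(1, 2), c(2, 3)))
  Cp <- covariance_from_network(p3)
  ref <- Cp
  for (i in 1:3) for (j in 1:3) ref[i, j] <- Cp[i, j] / sqrt(Cp[i, i] * Cp[j, j])
  expect_equal(cross_correlation(Cp), ref, tolerance = 1e-12)

  bad <- diag(3); bad[2, 2] <- 0
  expect_error(cross_correlation(bad), "node\\(s\\): 2")
})

test_that("phi(r) equals a brute-force pair loop with half-open bins", {
  rc <- random_connected_chain(10, seed = 21)
  phi <- cross_correlation(covariance_from_network(rc$net))
  D <- as.matrix(dist(rc$chain$points))
  prof <- correlation_function(phi, D, bin_width = 2)

  ref <- list()
  for (i in 1:9) for (j in (i + 1):10) {
    k <- as.character(floor(D[i, j] / 2))
    ref[[k]] <- c(ref[[k]], phi[i, j])
  }
  ks <- sort(as.numeric(names(ref)))
  expect_equal(prof$bin_centers, (ks + 0.5) * 2)
  expect_equal(prof$phi, vapply(as.character(ks), function(k) mean(ref[[k]]),
                                numeric(1)), ignore_attr = TRUE)
  expect_equal(prof$counts, vapply(as.character(ks), function(k) length(ref[[k]]),
                                   integer(1)), ignore_attr = TRUE)

  # a pair exactly on a bin edge goes to the upper bin
  phi2 <- matrix(c(1, .5, .5, 1), 2)
  D2 <- matrix(c(0, 4, 4, 0), 2)
  p2 <- correlation_function(phi2, D2, bin_width = 2)
  expect_equal(p2$bin_centers, 5)  # bin [4, 6)

  # all pairs in one bin with constant phi -> that constant
  phic <- matrix(0.3, 4, 4); diag(phic) <- 1
  Dc <- matrix(1, 4, 4); diag(Dc) <- 0
  pc <- correlation_function(phic, Dc, bin_width = 5)
  expect_equal(pc$phi, 0.3)
  expect_equal(pc$counts, 6L)
})

test_that("correlation length interpolates the first zero crossing", {
  mk <- function(centers, phi) structure(
    list(bin_centers = centers, phi = phi, counts = rep(10L, length(phi)),
         bin_width = centers[2] - centers[1], rescaled = FALSE),
    class = "correlation_profile")

  xi <- correlation_length(mk(c(2, 6, 10), c(0.5, 0.1, -0.2)))
  expect_equal(as.numeric(xi), 6 + 4 * (0.1 / 0.3), tolerance = 1e-12)
  expect_false(attr(xi, "censored"))

  cens <- correlation_length(mk(c(2, 6, 10), c(0.5, 0.3, 0.1)))
  expect_equal(as.numeric(cens), 10)
  expect_true(attr(cens, "censored"))

  zero <- correlation_length(mk(c(2, 6, 10), c(0.5, 0.0, -0.2)))
  expect_equal(as.numeric(zero), 6)
  expect_false(attr(zero, "censored"))
})

test_that("susceptibility equals the brute-force Heaviside pair sum", {
  rc <- random_connected_chain(10, seed = 33)
  phi <- cross_correlation(covariance_from_network(rc$net))
  D <- as.matrix(dist(rc$chain$points))
  xi <- median(D[upper.tri(D)])
  s <- 1.4
  ref <- 0
  for (i in 1:9) for (j in (i + 1):10)
    if (D[i, j] < xi) ref <- ref + phi[i, j]
  expect_equal(susceptibility(phi, D, xi, s, 10), s / 10 * ref,
               tolerance = 1e-12)

  # all pairs correlated and within range: chi = (N-1)/2 at s = 1
  n <- 6
  phi1 <- matrix(1, n, n)
  D1 <- matrix(1, n, n); diag(D1) <- 0
  expect_equal(susceptibility(phi1, D1, xi = 2, s = 1, n = n), (n - 1) / 2)
  # xi below all pair distances: empty sum; equality excluded (strict theta)
  expect_equal(susceptibility(phi1, D1, xi = 0.5, s = 1, n = n), 0)
  expect_equal(susceptibility(phi1, D1, xi = 1, s = 1, n = n), 0)
})

test_that("phi(r) is positive at short range on connected GNM networks", {
  for (seed in 1:3) {
    ch <- generate_ideal_chain(120, seed = seed)
    net <- build_kirchhoff(ch, r_cut = 9)
    if (igraph::components(critnet:::as_igraph(net))$no != 1L) next
    phi <- cross_correlation(covariance_from_network(net))
    prof <- correlation_function(phi, dist(ch$points))
    expect_gt(prof$phi[1], 0)
    expect_lte(prof$phi[1], 1)
  }
})

test_that("group averaging uses half-open 1 A windows and equal structure weights", {
  mk <- function(val) structure(
    list(bin_centers = c(0.5, 1.5), phi = c(val, val / 2),
         counts = c(3L, 3L), bin_width = 1, rescaled = FALSE),
    class = "correlation_profile")
  profs <- list(mk(0.8), mk(0.4), mk(0.6))
  rg <- c(12.0, 12.4, 12.5)

  one <- group_average(profs[1], rg[1], 12)
  expect_equal(one$phi, profs[[1]]$phi)

  two <- group_average(profs, rg, 12)     # 12.5 falls in the 13 window
  expect_equal(two$phi, c(0.6, 0.3))
  thirteen <- group_average(profs, rg, 13)
  expect_equal(thirteen$phi, c(0.6, 0.3))

  expect_error(group_average(profs, rg, 20), "available Rg range")
})

test_that("xi/Rg is approximately constant across fcc cluster sizes", {
  ns <- c(100, 200, 400, 800)
  ratio <- vapply(ns, function(n) {
    fcc <- generate_fcc_cluster(n)
    net <- build_lattice_springs(fcc, shells = 2)
    phi <- cross_correlation(covariance_from_network(net))
    prof <- correlation_function(phi, dist(fcc$points))
    xi <- correlation_length(prof)
    expect_false(attr(xi, "censored"))
    as.numeric(xi) / radius_of_gyration(fcc)
  }, numeric(1))
  expect_lt((max(ratio) - min(ratio)) / mean(ratio), 0.25)
})

test_that("polymer susceptibility grows monotonically with chain length", {
  ns <- c(50, 100, 200, 400)
  chi_mean <- vapply(ns, function(n) {
    vals <- vapply(1:5, function(s) {
      ch <- generate_ideal_chain(n, seed = 100 * n + s)
      net <- suppressWarnings(build_kirchhoff(ch, r_cut = 9))
      if (igraph::components(critnet:::as_igraph(net))$no != 1L) return(NA_real_)
      phi <- cross_correlation(covariance_from_network(net))
      D <- as.matrix(dist(ch$points))
      xi <- correlation_length(correlation_function(phi, D))
      if (attr(xi, "censored")) return(NA_real_)
      s_ <- shape_factor(ch)$s
      susceptibility(phi, D, as.numeric(xi), s_, n)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(chi_mean) > 0))
})
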