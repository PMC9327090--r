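test_that("the averaged model is the centered vertex-wise mean", {
  sph <- make_icosphere(60, 1)
  avg <- average_model(list(sph, sph))
  ctr <- colMeans(sph$vertices)
  expect_equal(avg$vertices, sweep(sph$vertices, 2, ctr), tolerance = 1e-12)
  # translations are removed by the centering
  m1 <- transform_mesh(sph, diag(3), c(100, 0, 0))
  m2 <- transform_mesh(sph, diag(3), c(-250, 40, 7))
  avg2 <- average_model(list(m1, m2))
  expect_equal(avg2$vertices, avg$vertices, tolerance = 1e-9)
  # averaging phantoms with half-axes a and 3a gives half-axes 2a
  lay <- default_layout()
  phA <- generate_phantom(phantom_config(lay, a0 = 100, b0 = 100,
                                         quiet_duration = 4,
                                         sample_rate = 20, jitter_sd = 0))
  phB <- generate_phantom(phantom_config(lay, a0 = 300, b0 = 300,
                                         quiet_duration = 4,
                                         sample_rate = 20, jitter_sd = 0))
  mA <- phantom_trunk_mesh(phA, 1L)
  mB <- phantom_trunk_mesh(phB, 1L)
  avg3 <- average_model(list(mA, mB))
  # the averaged mediolateral diameter is the mean of the two (centering
  # shifts cancel in marker-to-marker distances): 2*(100+300)/2 = 400 mm
  iR <- which(lay$markers$label == "R4")
  iL <- which(lay$markers$label == "L4")
  ml <- sqrt(sum((avg3$vertices[iR, ] - avg3$vertices[iL, ])^2))
  expect_equal(ml, 400, tolerance = 1e-9)
})

test_that("triangle magnitudes average absolute vertex moduli", {
  tri_mesh <- make_tetra()
  vf <- build_vector_field(tri_mesh, tri_mesh)
  vf$modulus <- c(1, 2, 3, 10)
  tm <- triangle_magnitudes(vf)
  expect_equal(tm[1], mean(c(1, 3, 2)))
  vf$modulus <- c(-1, -2, -3, -10)
  expect_equal(triangle_magnitudes(vf), tm)
  vf$modulus <- rep(0, 4)
  expect_true(all(triangle_magnitudes(vf) == 0))
})

test_that("exact MWU reproduces enumerated worked examples", {
  expect_equal(mwu_exact(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)
  expect_equal(mwu_exact(c(1, 2, 3, 4), c(5, 6, 7, 8)), 2 / 70,
               tolerance = 1e-12)
  expect_equal(mwu_exact(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(mwu_exact(1:5, 6:10), 2 / choose(10, 5), tolerance = 1e-12)
  expect_error(mwu_exact(numeric(0), 1:3), "non-empty")
})

test_that("exact MWU agrees with brute force and with wilcox.test", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    x <- sample(1:9, n, replace = TRUE)
    y <- sample(1:9, m, replace = TRUE)
    expect_equal(mwu_exact(x, y), mwu_brute_force(x, y), tolerance = 1e-12)
  }
  # untied data: cross-check against the standard library implementation
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    expect_equal(mwu_exact(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("significance maps color separated regions and only those", {
  sph <- make_icosphere(60, 1)
  nt <- nrow(sph$faces)
  mk_vf <- function(base, bump_faces = integer(0), bump = 0, noise_seed) {
    vf <- build_vector_field(sph, sph)
    set.seed(noise_seed)
    mod <- rep(base, length(vf$modulus)) + rnorm(length(vf$modulus), 0, 0.01)
    vf$modulus <- mod
    vf$signed <- TRUE
    if (length(bump_faces)) {
      vids <- unique(as.vector(sph$faces[bump_faces, ]))
      vf$modulus[vids] <- vf$modulus[vids] + bump
    }
    vf
  }
  region <- 1:10
  g1 <- lapply(1:5, function(s) mk_vf(1, region, 2, s))
  g2 <- lapply(6:10, function(s) mk_vf(1, integer(0), 0, s))
  map <- significance_map(g1, g2, alpha = 0.05)
  expect_equal(sort(unique(map$direction[region])), "group1_greater")
  expect_equal(min(map$p_values[region]), 2 / 252, tolerance = 1e-12)
  # swapping the groups flips colors, p-values unchanged
  map2 <- significance_map(g2, g1, alpha = 0.05)
  expect_equal(map2$p_values, map$p_values, tolerance = 1e-12)
  expect_equal(sort(unique(map2$direction[region])), "group2_greater")
  # joint rescaling of all fields does not change the map
  g1s <- lapply(g1, function(v) { v$modulus <- v$modulus * 3.7; v })
  g2s <- lapply(g2, function(v) { v$modulus <- v$modulus * 3.7; v })
  map3 <- significance_map(g1s, g2s, alpha = 0.05)
  expect_equal(map3$p_values, map$p_values, tolerance = 1e-12)
  expect_identical(map3$direction, map$direction)
  expect_error(significance_map(g1[1], g2), "at least 2")
})

test_that("identical constant groups yield an empty map", {
  sph <- make_icosphere(60, 1)
  mk_const <- function() {
    vf <- build_vector_field(sph, sph)
    vf$modulus <- rep(1, length(vf$modulus))
    vf$signed <- TRUE
    vf
  }
  map <- significance_map(lapply(1:3, function(i) mk_const()),
                          lapply(1:3, function(i) mk_const()))
  expect_equal(map$n_significant, 0L)
  expect_true(all(map$p_values == 1))
  expect_true(all(map$direction == "none"))
})
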