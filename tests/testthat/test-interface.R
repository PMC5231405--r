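test_that("an isolated sphere recovers its analytic area within quadrature error", {
  sys <- make_sphere_system(1.7, rbind(c(0, 0, 0)))
  sa <- sasa(sys$structure, sasa_params(n_points = 960),
             radii_override = sys$radii)
  analytic <- sphere_sasa_isolated(1.7)
  expect_equal(analytic, 4 * pi * 3.1^2)
  expect_equal(sa$total, analytic, tolerance = 0.01)
})

test_that("far-apart atoms are additive and bury nothing", {
  sys <- make_sphere_system(c(1.7, 1.7), rbind(c(0, 0, 0), c(100, 0, 0)))
  sa <- sasa(sys$structure, radii_override = sys$radii)
  expect_equal(sa$total, 2 * sphere_sasa_isolated(1.7), tolerance = 1e-6)
  bur <- buried_surface(sys$structure, selection(chains = "A"),
                        selection(chains = "B"),
                        radii_override = sys$radii)
  expect_equal(bur$bsa_total, 0, tolerance = 1e-6)
})

test_that("overlapping spheres match the spherical-cap closed form", {
  for (d in c(2.0, 3.0, 4.5)) {
    sys <- make_sphere_system(c(1.7, 1.9), rbind(c(0, 0, 0), c(d, 0, 0)))
    sa <- sasa(sys$structure, sasa_params(n_points = 1920),
               radii_override = sys$radii)
    expect_equal(sa$total, sys$truth$total,
                 tolerance = 0.02, label = sprintf("separation %.1f", d))
    bur <- buried_surface(sys$structure, selection(chains = "A"),
                          selection(chains = "B"),
                          p = sasa_params(n_points = 1920),
                          radii_override = sys$radii)
    expect_equal(bur$bsa_total, sum(sys$truth$buried_per_sphere),
                 tolerance = max(0.02 * sum(sys$truth$buried_per_sphere),
                                 0.5))
  }
})

test_that("burial is symmetric in the two partners and splits per partner", {
  sys <- make_sphere_system(c(1.7, 1.7, 1.9), rbind(
    c(0, 0, 0), c(10, 0, 0), c(1.5, 1.5, 0)))
  pa <- selection(chains = "A")  # spheres 1 and 3
  pb <- selection(chains = "B")  # sphere 2
  sys2 <- sys
  bur_ab <- buried_surface(sys$structure, pa, pb, radii_override = sys$radii)
  bur_ba <- buried_surface(sys$structure, pb, pa, radii_override = sys$radii)
  expect_equal(bur_ab$bsa_total, bur_ba$bsa_total, tolerance = 1e-9)
  expect_equal(bur_ab$bsa_a, bur_ba$bsa_b, tolerance = 1e-9)
  expect_equal(bur_ab$bsa_total, bur_ab$bsa_a + bur_ab$bsa_b,
               tolerance = 1e-9)
})

test_that("burial decreases monotonically to zero with separation", {
  prev <- Inf
  for (d in c(2.5, 3.0, 3.5, 4.5, 6.0, 7.0)) {
    sys <- make_sphere_system(c(1.7, 1.7), rbind(c(0, 0, 0), c(d, 0, 0)))
    bur <- buried_surface(sys$structure, selection(chains = "A"),
                          selection(chains = "B"),
                          radii_override = sys$radii)
    expect_lte(bur$bsa_total, prev + 1e-6)
    prev <- bur$bsa_total
  }
  expect_equal(prev, 0, tolerance = 1e-6)  # beyond 2r + 2*probe
})

test_that("overlapping partner selections are a precondition error", {
  sys <- make_sphere_system(c(1.7, 1.7), rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_error(buried_surface(sys$structure, selection(chains = c("A", "B")),
                              selection(chains = "B"),
                              radii_override = sys$radii),
               "overlap")
})

test_that("unknown elements fall back with a warning or error on request", {
  at <- data.frame(serial = 1L, name = "XX", element = "XX", resname = "UNK",
                   chain = "A", resnum = 1L, icode = "", altloc = "",
                   occ = 1, b = 0, x = 0, y = 0, z = 0, het = TRUE)
  s <- structure_model(at)
  expect_warning(sasa(s), "fallback")
  expect_error(sasa(s, sasa_params(fallback_radius = NA)), "XX")
})

test_that("the interaction footprint lists exactly the contacting residues", {
  # two CA chains 100 A apart: empty footprint
  far <- make_sphere_system(c(1.7, 1.7), rbind(c(0, 0, 0), c(100, 0, 0)))
  fp <- interface_footprint(far$structure, selection(chains = "A"),
                            selection(chains = "B"))
  expect_equal(nrow(fp), 0L)
  # a constructed single contact
  at <- data.frame(
    serial = 1:4, name = "CA", element = "C",
    resname = "GLY", chain = c("A", "A", "B", "B"),
    resnum = c(1L, 2L, 1L, 2L), icode = "", altloc = "", occ = 1, b = 0,
    x = c(0, 20, 3.5, 40), y = 0, z = 0, het = FALSE)
  s <- structure_model(at)
  fp2 <- interface_footprint(s, selection(chains = "A"),
                             selection(chains = "B"), cutoff = 4.0)
  expect_equal(nrow(fp2), 1L)
  expect_equal(fp2$resnum, 1L)
  expect_equal(fp2$min_dist, 3.5)
  expect_gt(fp2$buried_area, 0)
})

test_that("surface areas are invariant under rigid motion to quadrature error", {
  fx <- make_reaction_center(7.6, 3.0, 6.38)
  s0 <- fx$structure
  sa0 <- sasa(s0)
  tf <- rigid_transform(rotation_about_axis(c(3, 1, 2), 67), c(12, -8, 3))
  sa1 <- sasa(apply_transform(s0, tf))
  expect_equal(sa1$total, sa0$total, tolerance = 0.01)
})

test_that("flat complementary walls approach the ideal score as dots densify", {
  fx <- make_sc_surfaces(gap = 0.3)
  sc <- do.call(shape_complementarity,
                c(list(fx$structure, selection(chains = "A"),
                       selection(chains = "B"),
                       radii_override = fx$radii), fx$sc_args))
  expect_equal(sc$sc, fx$truth$sc_flat_limit, tolerance = 0.02)
  expect_true(sc$sc >= -1 && sc$sc <= 1)
  expect_gt(sc$n_dots_a, 100)
})

test_that("curvature mismatch lowers the score below the matched-gap limit", {
  fx <- make_sc_surfaces(gap = 0.2, curvature_mismatch = 0.08)
  sc <- do.call(shape_complementarity,
                c(list(fx$structure, selection(chains = "A"),
                       selection(chains = "B"),
                       radii_override = fx$radii), fx$sc_args))
  expect_lt(sc$sc, exp(-0.5 * 0.2^2) - 0.02)
})

test_that("the score equals a brute-force recomputation on the same dot set", {
  fx <- make_sc_surfaces(gap = 0.4, half_extent = 3, spacing = 1.5,
                         r_atom = 8)
  sc <- shape_complementarity(fx$structure, selection(chains = "A"),
                              selection(chains = "B"),
                              n_dots = 4000, trim = 4,
                              radii_override = fx$radii, keep_dots = TRUE)
  brute_side <- function(da, ia, db, ib, w) {
    vapply(ia, function(k) {
      best <- Inf; bj <- NA
      for (j in ib) {
        d2 <- sum((db$xyz[j, ] - da$xyz[k, ])^2)
        if (d2 < best) { best <- d2; bj <- j }
      }
      -sum(da$nrm[k, ] * db$nrm[bj, ]) * exp(-w * best)
    }, numeric(1))
  }
  a_keep <- sc$dots$patch_a$buried
  b_keep <- sc$dots$patch_b$buried
  s_a <- brute_side(sc$dots$a, a_keep, sc$dots$b,
                    sc$dots$patch_b$buried_untrimmed, sc$w)
  s_b <- brute_side(sc$dots$b, b_keep, sc$dots$a,
                    sc$dots$patch_a$buried_untrimmed, sc$w)
  expect_equal(sc$s_a, s_a, tolerance = 1e-12)
  expect_equal(sc$s_b, s_b, tolerance = 1e-12)
  expect_equal(sc$sc, (median(s_a) + median(s_b)) / 2, tolerance = 1e-12)
})

test_that("separated partners have no defined interface score", {
  far <- make_sphere_system(c(1.7, 1.7), rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_error(shape_complementarity(far$structure, selection(chains = "A"),
                                     selection(chains = "B"),
                                     n_dots = 200,
                                     radii_override = far$radii),
               "buried patch|interface")
})
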