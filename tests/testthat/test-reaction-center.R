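test_that("reactive atoms are located, with optional atoms absent not fatal", {
  fx <- make_reaction_center(7.6, 3.0, 6.38)
  loc <- locate_reactive_atoms(fx$structure, fx$spec)
  expect_false(is.na(loc$ne2))
  expect_false(is.na(loc$od))
  expect_false(is.na(loc$mg))
  expect_false(is.na(loc$p))
  expect_equal(loc$p_kind, "phis")
  # no cation in the structure: auto lookup reports absence, no exception
  s2 <- fx$structure
  s2$atoms <- s2$atoms[s2$atoms$name != "MG", ]
  loc2 <- locate_reactive_atoms(s2, fx$spec)
  expect_true(is.na(loc2$mg))
  # missing NE2 is a named error
  s3 <- fx$structure
  s3$atoms <- s3$atoms[s3$atoms$name != "NE2", ]
  expect_error(locate_reactive_atoms(s3, fx$spec), "NE2")
  # missing residue altogether
  expect_error(
    locate_reactive_atoms(fx$structure,
                          reaction_center_spec("A", 999, "B", 54)),
    "999")
})

test_that("measured distances and ratios equal the constructed geometry", {
  fx <- make_reaction_center(6.5, 3.0, 6.0, with_surrogate = FALSE)
  g <- measure_center(fx$structure, fx$spec)
  expect_equal(g$d_his_asp, 6.5, tolerance = 1e-9)
  expect_equal(g$d_mg_asp, 3.0, tolerance = 1e-9)
  expect_equal(g$d_mg_his, 6.0, tolerance = 1e-9)
  expect_equal(g$r_mg, 0.5, tolerance = 1e-9)
  expect_true(is.na(g$d_rxn))
  # with an in-line surrogate the reaction coordinate is defined
  fx2 <- make_reaction_center(7.6, 3.0, 6.38, d_rxn = 5.8)
  g2 <- measure_center(fx2$structure, fx2$spec)
  expect_equal(g2$d_rxn, 5.8, tolerance = 1e-9)
  expect_equal(g2$r_mg, 3.0 / 6.38, tolerance = 1e-9)
})

test_that("the OD policy picks OD1 by default and the nearer oxygen on request", {
  fx <- make_reaction_center(7.0, 3.2, 6.2)
  g1 <- measure_center(fx$structure, fx$spec)
  expect_equal(g1$od_used, "OD1")
  spec_near <- reaction_center_spec("A", 188, "B", 54, od_policy = "nearest")
  g2 <- measure_center(fx$structure, spec_near)
  # the fixture puts OD2 farther from NE2 than OD1
  expect_equal(g2$od_used, "OD1")
  expect_equal(g2$d_his_asp, g1$d_his_asp)
})

test_that("geometry is invariant under rigid motion and symmetry expansion", {
  fx <- make_reaction_center(7.6, 3.0, 6.38)
  g0 <- measure_center(fx$structure, fx$spec)
  tf <- rigid_transform(rotation_about_axis(c(2, 1, 0), 111), c(-6, 9, 4))
  g1 <- measure_center(apply_transform(fx$structure, tf), fx$spec)
  expect_equal(g1$d_his_asp, g0$d_his_asp, tolerance = 1e-9)
  expect_equal(g1$r_mg, g0$r_mg, tolerance = 1e-9)
  s <- fx$structure
  s$cell <- c(40, 40, 60, 90, 90, 120)
  g2 <- measure_center(apply_symmetry_operator(s, "-y,x-y,z+2/3"), fx$spec)
  expect_equal(g2$d_his_asp, g0$d_his_asp, tolerance = 1e-6)
  expect_equal(g2$r_mg, g0$r_mg, tolerance = 1e-6)
})

test_that("the ratio grows strictly with the cation-to-Asp distance", {
  r_prev <- -Inf
  for (dma in seq(2.0, 5.0, by = 0.5)) {
    fx <- make_reaction_center(7.0, dma, 5.0, with_surrogate = FALSE)
    g <- measure_center(fx$structure, fx$spec)
    expect_gt(g$r_mg, r_prev)
    r_prev <- g$r_mg
  }
})

test_that("classification follows the distance and asymmetry thresholds", {
  expect_equal(classify_mechanism(5.7, 0.82)$group, "I")
  expect_equal(classify_mechanism(5.7, 0.82)$mechanism,
               "associative-compatible")
  expect_equal(classify_mechanism(7.6, 0.47)$group, "II")
  expect_equal(classify_mechanism(7.6, 0.47)$mechanism, "dissociative")
  # exact threshold hits are ambiguous by definition
  expect_equal(classify_mechanism(6.5, 0.6)$group, "ambiguous")
  expect_equal(classify_mechanism(6.5, 0.8)$group, "ambiguous")
  expect_equal(classify_mechanism(6.0, 0.6)$group, "ambiguous")
  # mixed signals are ambiguous too
  expect_equal(classify_mechanism(5.0, 0.4)$group, "ambiguous")
  expect_equal(classify_mechanism(8.0, 0.9)$group, "ambiguous")
  # without a cation: distance-only, flagged
  m <- classify_mechanism(7.3, NA_real_)
  expect_equal(m$group, "II")
  expect_equal(m$confidence, "distance-only")
  # dissociation-room note
  m2 <- classify_mechanism(7.6, 0.47, d_rxn = 5.8)
  expect_match(m2$note, "metaphosphate")
  expect_equal(classify_mechanism(5.0, 0.8, d_rxn = 3.3)$note, "")
  # thresholds are parameters, not constants
  expect_equal(classify_mechanism(5.7, 0.82, d_cut = 5.0, r_cut = 0.85)$group,
               "II")
  expect_equal(classify_mechanism(5.7, 0.82, d_cut = 7.0, r_cut = 0.9)$group,
               "ambiguous")
})

test_that("the batch table matches an independent threshold check", {
  set.seed(19)
  ds <- runif(10, 4.5, 9)
  rs <- runif(10, 0.3, 1.0)
  entries <- lapply(1:10, function(i) {
    dmh <- 6.0
    fx <- make_reaction_center(ds[i], rs[i] * dmh, dmh,
                               with_surrogate = FALSE, seed = 100 + i)
    list(structure = fx$structure, spec = fx$spec, label = paste0("syn", i))
  })
  tab <- rc_table(entries)
  expect_equal(nrow(tab), 10L)
  brute <- ifelse(ds < 6.5 & rs > 0.6, "I",
                  ifelse(ds > 6.5 & rs < 0.6, "II", "ambiguous"))
  expect_equal(tab$group, brute)
  # batch order never changes rows
  tab_rev <- rc_table(rev(entries))
  expect_equal(tab_rev[order(tab_rev$label), -1],
               tab[order(tab$label), -1], ignore_attr = TRUE)
  # a failing entry is recorded, others continue
  bad <- entries
  bad[[3]]$spec <- reaction_center_spec("A", 999, "B", 54)
  tab_bad <- rc_table(bad)
  expect_match(tab_bad$error[3], "999")
  expect_equal(tab_bad$group[-3], tab$group[-3])
})

test_that("the published benchmark rows are partitioned exactly as reported", {
  ref <- reference_rc_table()
  got <- vapply(seq_len(nrow(ref)), function(i)
    classify_mechanism(ref$d_his_asp[i], ref$r_mg[i])$group, character(1))
  expect_equal(got, ref$group_published)
  # the two clusters separate in the distance/asymmetry plane
  expect_lt(max(ref$d_his_asp[ref$group_published == "I"]), 6.5)
  expect_gt(min(ref$d_his_asp[ref$group_published == "II"]), 6.5)
  expect_gt(min(ref$r_mg[ref$group_published == "I"]), 0.6)
  expect_lt(max(ref$r_mg[ref$group_published == "II"]), 0.6)
})
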