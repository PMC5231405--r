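test_that("atom pairing matches a brute-force key join, order-free", {
  rp <- make_rigid_pair(20, angle = 25, translation = c(1, 2, 3), seed = 5)
  a <- rp$a; b <- rp$b
  pr <- pair_atoms(a, b)
  expect_equal(nrow(pr), 20L)
  expect_equal(pr$ia, pr$ib)  # identical layout
  # drop one residue from b
  b2 <- b
  b2$atoms <- b$atoms[b$atoms$resnum != 7, ]
  pr2 <- pair_atoms(a, b2)
  expect_equal(nrow(pr2), 19L)
  expect_equal(attr(pr2, "n_unmatched_a"), 1L)
  # scramble b's atom order: same pair set as a brute-force join
  set.seed(1)
  perm <- sample(nrow(b$atoms))
  b3 <- b
  b3$atoms <- b$atoms[perm, ]
  pr3 <- pair_atoms(a, b3)
  key <- function(at) paste(at$chain, at$resnum, at$name)
  brute <- match(key(a$atoms), key(b3$atoms))
  expect_equal(pr3$ib, brute[pr3$ia])
  expect_equal(nrow(pr3), 20L)
})

test_that("chain mapping joins differently labelled partners", {
  rp <- make_rigid_pair(12, angle = 10, seed = 2)
  b <- rp$b
  b$atoms$chain <- "Q"
  expect_error(pair_atoms(rp$a, b), "insufficient")
  pr <- pair_atoms(rp$a, b, chain_map = c(A = "Q"))
  expect_equal(nrow(pr), 12L)
  fit <- kabsch_fit(rp$a, b, chain_map = c(A = "Q"))
  expect_lt(fit$rmsd_fit, 1e-8)
})

test_that("self-superposition returns the identity at zero rmsd", {
  rp <- make_rigid_pair(15, seed = 9)
  fit <- kabsch_fit(rp$a, rp$a)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$transform$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(fit$rmsd_fit, 0, tolerance = 1e-12)
})

test_that("noise-free rigid motions are recovered exactly, even near 180 deg", {
  angles <- c(0.01, 45, 90, 135, 179.5, 179.99, 180)
  for (i in seq_along(angles)) {
    rp <- make_rigid_pair(25, angle = angles[i], axis = c(1, -2, 0.5),
                          translation = c(4, -7, 2), seed = 100 + i)
    fit <- kabsch_fit(rp$a, rp$b)
    expect_lt(fit$rmsd_fit, 1e-8)
    expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-8)
    # recovered transform inverts the imposed motion
    back <- apply_transform(rp$b, fit$transform)
    expect_lt(max(abs(coords(back) - coords(rp$a))), 1e-7)
  }
})

test_that("rmsd is symmetric and the fit is optimal", {
  rp <- make_rigid_pair(40, angle = 33, translation = c(2, 2, -1),
                        noise_sd = 0.4, seed = 21)
  f_ab <- kabsch_fit(rp$a, rp$b)
  f_ba <- kabsch_fit(rp$b, rp$a)
  expect_equal(f_ab$rmsd_fit, f_ba$rmsd_fit, tolerance = 1e-8)
  # never worse than leaving b in place
  rmsd_id <- sqrt(mean(rowSums((coords(rp$a) - coords(rp$b))^2)))
  expect_lte(f_ab$rmsd_fit, rmsd_id)
})

test_that("noisy fits agree with the bio3d reference superposition", {
  rp <- make_rigid_pair(60, angle = 70, axis = c(1, 1, 1),
                        translation = c(5, 0, -3), noise_sd = 0.5, seed = 33)
  mine <- kabsch_fit(rp$a, rp$b)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(coords(rp$a))),
                   mobile = as.vector(t(coords(rp$b)))))
  rmsd_ref <- sqrt(mean(rowSums(
    (matrix(ref, ncol = 3, byrow = TRUE) - coords(rp$a))^2)))
  expect_equal(mine$rmsd_fit, rmsd_ref, tolerance = 1e-6)
})

test_that("evaluation rmsd uses the fitted transform without refitting", {
  # two-domain object: domain 1 identical, domain 2 displaced by 5 A
  set.seed(4)
  d1 <- matrix(runif(45, -8, 8), ncol = 3)
  d2 <- matrix(runif(30, -8, 8), ncol = 3) + 25
  a <- structure_from_xyz(rbind(d1, d2))
  b <- structure_from_xyz(rbind(d1, sweep(d2, 2, c(5, 0, 0), "+")))
  fit <- kabsch_fit(a, b, fit_sel = selection(resnums = 1:15),
                    eval_sel = selection(resnums = 16:25))
  expect_lt(fit$rmsd_fit, 1e-8)
  expect_equal(fit$rmsd_eval, 5, tolerance = 1e-8)
  expect_equal(fit$n_eval, 10L)
})

test_that("transforms form a group and preserve distances", {
  rp <- make_rigid_pair(20, seed = 12)
  tf <- rigid_transform(rotation_about_axis(c(0, 1, 1), 77), c(1, -2, 3))
  s2 <- apply_transform(rp$a, tf)
  back <- apply_transform(s2, invert_transform(tf))
  expect_lt(max(abs(coords(back) - coords(rp$a))), 1e-9)
  expect_equal(as.matrix(dist(coords(s2))), as.matrix(dist(coords(rp$a))),
               tolerance = 1e-9)
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)),
               "determinant")
})

test_that("collinear fit sets are rejected as degenerate", {
  line <- cbind(seq_len(10), 0, 0)
  a <- structure_from_xyz(line)
  b <- structure_from_xyz(line + 1)
  expect_error(kabsch_fit(a, b), "degenerate|collinear")
})
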