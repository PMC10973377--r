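# CV evaluation, analytic rates, rigid-motion invariance, enumeration.

rigid_motion <- function(pos3, seed) {
  # random rotation (QR of a Gaussian matrix) + translation, applied to an
  # n x 3 coordinate matrix
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- rnorm(3, sd = 2)
  sweep(pos3 %*% Q, 2L, -shift)
}

test_that("geometric CVs evaluate to textbook values", {
  d <- cv_def("distance", c(1, 2))
  expect_equal(evaluate_cv(d, c(0, 0, 0, 3, 4, 0)), 5)

  a <- cv_def("angle", c(1, 2, 3))
  expect_equal(evaluate_cv(a, c(1, 0, 0, 0, 0, 0, 0, 1, 0)), pi / 2)
  expect_equal(evaluate_cv(a, c(1, 0, 0, 0, 0, 0, 2, 0, 0)), 0)

  # coplanar quadruples: cis -> 0, trans -> pi (IUPAC convention)
  dih <- cv_def("dihedral", c(1, 2, 3, 4))
  cis <- c(1, 1, 0, 1, 0, 0, 2, 0, 0, 2, 1, 0)
  trans <- c(1, 1, 0, 1, 0, 0, 2, 0, 0, 2, -1, 0)
  expect_equal(evaluate_cv(dih, cis), 0)
  expect_equal(evaluate_cv(dih, trans), pi)

  dd <- cv_def("difference_of_distances", c(1, 2, 3, 4))
  x <- c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 3, 0)
  expect_equal(evaluate_cv(dd, x), 1 - 3)
})

test_that("dihedral sign convention matches an independent implementation", {
  skip_if_not_installed("bio3d")
  set.seed(31)
  dih <- cv_def("dihedral", c(1, 2, 3, 4))
  for (i in 1:20) {
    xyz <- matrix(rnorm(12, sd = 2), 4, 3)
    ours <- tryCatch(evaluate_cv(dih, as.vector(t(xyz))), error = function(e) NA)
    if (is.na(ours)) next
    ref <- bio3d::torsion.xyz(as.vector(t(xyz))) * pi / 180
    # both live in (-pi, pi]; compare on the circle
    expect_lt(abs(Arg(exp(1i * (ours - ref)))), 1e-8)
  }
})

test_that("analytic CV rates match finite-difference rates", {
  set.seed(7)
  cvs <- list(cv_def("distance", c(1, 2)),
              cv_def("angle", c(1, 2, 3)),
              cv_def("dihedral", c(1, 2, 3, 4)),
              cv_def("difference_of_distances", c(1, 2, 3, 4)),
              cv_def("coordinate_projection", 5))
  for (i in 1:15) {
    x <- rnorm(12, sd = 2)
    v <- rnorm(12)
    frm <- frame(x, v)
    for (cv in cvs) {
      rate <- tryCatch(cv_rate(cv, frm, dim = 3L), error = function(e) NULL)
      if (is.null(rate)) next # skipped a randomly degenerate geometry
      h <- 1e-6
      fd <- (evaluate_cv(cv, x + h * v, dim = 3L) -
               evaluate_cv(cv, x - h * v, dim = 3L)) / (2 * h)
      expect_equal(rate, fd, tolerance = 1e-5)
    }
  }
})

test_that("simple kinematics give the expected rates", {
  # two particles receding along their axis: rate = relative speed
  frm <- frame(c(0, 0, 0, 2, 0, 0), c(-0.5, 0, 0, 1, 0, 0))
  expect_equal(cv_rate(cv_def("distance", c(1, 2)), frm), 1.5)
  # rigid rotation about the origin: distance rate = 0
  frm2 <- frame(c(1, 0, 0, -1, 0, 0), c(0, 1, 0, 0, -1, 0))
  expect_equal(cv_rate(cv_def("distance", c(1, 2)), frm2), 0)
})

test_that("CVs are invariant under rigid motions (except projections)", {
  set.seed(19)
  base <- matrix(rnorm(12, sd = 1.5), 4, 3)
  cvs <- list(cv_def("distance", c(1, 3)),
              cv_def("angle", c(1, 2, 4)),
              cv_def("dihedral", c(1, 2, 3, 4)),
              cv_def("difference_of_distances", c(1, 2, 3, 4)))
  ref <- vapply(cvs, evaluate_cv, numeric(1), frm = as.vector(t(base)))
  for (s in 1:10) {
    moved <- rigid_motion(base, seed = 100 + s)
    got <- vapply(cvs, evaluate_cv, numeric(1), frm = as.vector(t(moved)))
    expect_equal(got, ref, tolerance = 1e-10)
  }
  # coordinate projections are documented as frame-fixed
  pr <- cv_def("coordinate_projection", 1)
  expect_false(isTRUE(all.equal(evaluate_cv(pr, as.vector(t(base))),
                                evaluate_cv(pr, as.vector(t(rigid_motion(base, 7)))))))
})

test_that("degenerate geometries raise explicit errors", {
  expect_error(evaluate_cv(cv_def("angle", c(1, 2, 3)),
                           c(0, 0, 0, 0, 0, 0, 1, 0, 0)), "degenerate")
  # collinear backbone makes the dihedral undefined
  expect_error(evaluate_cv(cv_def("dihedral", c(1, 2, 3, 4)),
                           c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 1, 0)), "degenerate")
  expect_error(cv_rate(cv_def("distance", c(1, 2)), frame(rep(0, 6), rep(1, 6))),
               "degenerate")
})

test_that("CV enumeration matches the combinatorial closed form", {
  # 3 atoms, all reactive, all mutually in cutoff:
  # C(3,2)=3 distances + C(3,3)=1 angle + C(C(3,2),2)=3 distance differences
  pos <- c(0, 0, 0, 1, 0, 0, 0, 1, 0)
  cvs <- enumerate_cvs(pos, reactive_atoms = 1:3, cutoff = 2)
  kinds <- table(vapply(cvs, `[[`, "", "kind"))
  expect_equal(unname(kinds[["distance"]]), 3L)
  expect_equal(unname(kinds[["angle"]]), 1L)
  expect_equal(unname(kinds[["difference_of_distances"]]), 3L)
  expect_equal(length(cvs), 7L)

  # a 4th atom outside the cutoff stays excluded; cutoff 0 keeps only the
  # reactive atoms themselves
  pos4 <- c(pos, 50, 50, 50)
  cvs4 <- enumerate_cvs(pos4, reactive_atoms = 1:3, cutoff = 2)
  expect_equal(length(cvs4), length(cvs))
  cvs0 <- enumerate_cvs(pos4, reactive_atoms = c(1, 4), cutoff = 0)
  ats <- sort(unique(unlist(lapply(cvs0, `[[`, "atom_indices"))))
  expect_equal(ats, c(1L, 4L))

  # deterministic ordering
  a <- enumerate_cvs(pos4, 1:3, 2)
  b <- enumerate_cvs(pos4, 1:3, 2)
  expect_identical(vapply(a, `[[`, "", "cv_id"), vapply(b, `[[`, "", "cv_id"))
  expect_error(enumerate_cvs(pos, integer(0), 1), "non-empty")
})

test_that("CV catalogues round-trip through JSON", {
  cvs <- enumerate_cvs(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 1:3, 2)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_cv_catalogue(cvs, path)
  back <- read_cv_catalogue(path)
  expect_equal(lapply(back, unclass), lapply(cvs, unclass))
})
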