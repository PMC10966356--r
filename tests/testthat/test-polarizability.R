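test_that("blend weight follows the exponential proximity formula", {
  c1 <- c(a = 0.5, b = 0.2, c = 0.2, o = 0.1)
  expect_equal(blend_weight(c1, c1, ct = 1), 100)
  c2 <- c(a = 0.505, b = 0.2, c = 0.195, o = 0.1)   # L1 distance 0.01
  expect_equal(blend_weight(c1, c2, ct = 1), 100 * exp(-0.5), tolerance = 1e-12)
  c3 <- c(a = 1, b = 0, c = 0, o = 0)
  c4 <- c(a = 0.5, b = 0.5, c = 0, o = 0)           # L1 distance 1
  expect_equal(blend_weight(c3, c4, ct = 1), 100 * exp(-50), tolerance = 1e-12)
  expect_error(blend_weight(c1, c1, ct = 0), "parameter error")
  expect_error(blend_weight(c1, c1, ct = -2), "parameter error")
})

test_that("blending reduces to the single entry and respects symmetry", {
  lib1 <- const_library(1 + 2i)
  q <- c(a = 0.3, b = 0.3, c = 0.2, o = 0.2)
  ps <- assign_protein_polarizabilities(q, lib1)
  expect_equal(unname(ps$weights), 1)
  expect_true(all(ps$curves == 1 + 2i))

  # two identical entries: result unchanged whatever the weights
  g <- default_grid()
  cv <- matrix(3 - 1i, length(g), 1L, dimnames = list(NULL, "uni"))
  lib2 <- polar_library(g, base = list(
    list(id = "p1", content = c(a = 1, b = 0, c = 0, o = 0), curves = cv),
    list(id = "p2", content = c(a = 0, b = 1, c = 0, o = 0), curves = cv)))
  ps2 <- assign_protein_polarizabilities(q, lib2)
  expect_true(all(abs(ps2$curves - (3 - 1i)) < 1e-12))
  expect_equal(sum(ps2$weights), 1)

  # distinct constant curves, query equidistant -> arithmetic mean
  cv1 <- matrix(1 + 0i, length(g), 1L, dimnames = list(NULL, "uni"))
  cv3 <- matrix(3 + 0i, length(g), 1L, dimnames = list(NULL, "uni"))
  lib3 <- polar_library(g, base = list(
    list(id = "p1", content = c(a = 1, b = 0, c = 0, o = 0), curves = cv1),
    list(id = "p2", content = c(a = 0, b = 0, c = 1, o = 0), curves = cv3)))
  ps3 <- assign_protein_polarizabilities(c(a = 0.5, b = 0, c = 0.5, o = 0), lib3)
  expect_true(all(abs(ps3$curves - (2 + 0i)) < 1e-12))
})

test_that("blended weights are a convex combination after normalization", {
  lib <- lorentz3()
  g <- lib$grid
  lib2 <- polar_library(g, base = c(lib$base, list(
    list(id = "b2", content = c(a = 0.7, b = 0.1, c = 0.1, o = 0.1),
         curves = lib$base[[1]]$curves * (0.5 + 0.1i)))),
    groups = list(list(id = "g1", curves = lib$base[[1]]$curves)),
    group_mass = 0.1)
  for (q in list(c(a = 1, b = 0, c = 0, o = 0),
                 c(a = 0.25, b = 0.25, c = 0.25, o = 0.25))) {
    ps <- assign_protein_polarizabilities(q, lib2)
    expect_true(all(ps$weights >= 0))
    expect_equal(sum(ps$weights), 1, tolerance = 1e-12)
  }
})

test_that("blending is continuous in the query content", {
  lib <- lorentz3()
  g <- lib$grid
  lib2 <- polar_library(g, base = list(
    list(id = "b1", content = c(a = 0.6, b = 0.2, c = 0.1, o = 0.1),
         curves = lib$base[[1]]$curves),
    list(id = "b2", content = c(a = 0.1, b = 0.6, c = 0.2, o = 0.1),
         curves = 2 * lib$base[[1]]$curves)))
  q0 <- c(a = 0.4, b = 0.3, c = 0.2, o = 0.1)
  eps <- 1e-5
  q1 <- c(a = 0.4 + eps, b = 0.3 - eps, c = 0.2, o = 0.1)
  p0 <- assign_protein_polarizabilities(q0, lib2)
  p1 <- assign_protein_polarizabilities(q1, lib2)
  rel <- max(Mod(p1$curves - p0$curves)) / max(Mod(p0$curves))
  expect_lt(rel, 100 * 2 * eps)   # O(eps) with the rate constant 50*2
  expect_gt(rel, 0)
})

test_that("the D flip negates Re, preserves Im and is an involution", {
  pc <- polar_curve("x", 200:205, complex(real = 1:6, imaginary = seq(-3, 2)))
  fl <- flip_for_D(pc)
  expect_equal(Re(fl$values), -(1:6))
  expect_equal(Im(fl$values), seq(-3, 2))
  expect_equal(flip_for_D(fl)$values, pc$values)
  # purely imaginary curve unchanged
  pi_curve <- polar_curve("y", 200:205, complex(imaginary = 1:6))
  expect_equal(flip_for_D(pi_curve)$values, pi_curve$values)
})

test_that("atom typing follows the table with configurable override", {
  tab <- load_typing_table()
  expect_equal(type_atom("N", "N", "H", tab), "N_bb_H")
  expect_equal(type_atom("S", "SD", "C", tab), "S_sc")   # MET thioether
  expect_equal(type_atom("S", "SG", "C", tab), "S_ss")   # CYS sulfur
  expect_equal(type_atom("C", "CA", "E", tab), "C_ca")
  tab3 <- element3_typing()
  expect_equal(type_atom("N", "N", "H", tab3), "N_any")

  s <- assign_ss(make_helix(8))
  s <- assign_atom_types(s, tab)
  expect_true(all(nzchar(s$atoms$type_label)))
  expect_true(all(s$atoms$type_label %in% tab$labels))
  s3 <- assign_atom_types(s, tab3)
  expect_true(all(s3$atoms$type_label %in% tab3$labels))
})

test_that("the default table carries exactly 21 labels", {
  expect_length(load_typing_table()$labels, 21L)
})

test_that("library round-trips through the manifest + TSV format", {
  lib <- lorentz3()
  dir <- withr::local_tempdir()
  write_polar_library(lib, dir)
  lib2 <- read_polar_library(dir)
  expect_equal(lib2$labels, lib$labels)
  expect_equal(lib2$grid, lib$grid)
  expect_equal(lib2$base[[1]]$content, lib$base[[1]]$content, tolerance = 1e-12)
  expect_lt(max(Mod(lib2$base[[1]]$curves - lib$base[[1]]$curves)) /
              max(Mod(lib$base[[1]]$curves)), 1e-9)
})

test_that("mismatched grids and empty libraries are rejected", {
  g <- default_grid()
  cv <- matrix(1 + 0i, length(g), 1L, dimnames = list(NULL, "uni"))
  expect_error(polar_library(g, base = list()), "empty library")
  expect_error(polar_library(g[-1], base = list(
    list(id = "a", content = c(a = 1, b = 0, c = 0, o = 0), curves = cv))),
    "mismatch")
})
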