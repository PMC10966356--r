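# analytic damped-oscillator pair used as the transform oracle
lorentz_pair <- function(lam, center = 215, width = 9) {
  nu <- 1 / lam
  nu0 <- 1 / center
  g <- width / center^2
  1 / (nu0^2 - nu^2 - 1i * g * nu)
}

test_that("Kramers-Kronig transform recovers the dispersive Lorentzian", {
  lam <- seq(150, 320, by = 0.5)
  v <- lorentz_pair(lam)
  re_rec <- kk_real_part(cd_spectrum(lam, Im(v)))
  inb <- lam >= 188 & lam <= 244
  rms <- sqrt(mean((Re(re_rec$values[inb]) - Re(v[inb]))^2)) /
    sqrt(mean(Re(v[inb])^2))
  expect_lt(rms, 0.02)
})

test_that("zero input transforms to zero and the operator is linear", {
  lam <- default_grid()
  z <- kk_real_part(cd_spectrum(lam, rep(0, length(lam))))
  expect_true(all(Re(z$values) == 0))

  v1 <- lorentz_pair(lam, 205, 8); v2 <- lorentz_pair(lam, 225, 10)
  t12 <- kk_real_part(cd_spectrum(lam, Im(v1) + Im(v2)))
  t1 <- kk_real_part(cd_spectrum(lam, Im(v1)))
  t2 <- kk_real_part(cd_spectrum(lam, Im(v2)))
  rel <- max(abs(Re(t12$values) - Re(t1$values) - Re(t2$values))) /
    max(abs(Re(t12$values)))
  expect_lt(rel, 1e-10)
})

test_that("the Lorentzian tail model reduces the band-limited bias", {
  lam <- default_grid()
  v <- lorentz_pair(lam)
  rms_of <- function(ext) {
    rec <- kk_real_part(cd_spectrum(lam, Im(v)), extension = ext)
    sqrt(mean((Re(rec$values) - Re(v))^2)) / sqrt(mean(Re(v)^2))
  }
  bias_zero <- rms_of(list(mode = "zero"))
  bias_lor <- rms_of(list(mode = "lorentz", pad = 1.5))
  expect_lt(bias_lor, bias_zero)
  expect_lt(bias_lor, 0.02)
  expect_error(kk_real_part(cd_spectrum(lam, Im(v)), extension = list(mode = "x")),
               "unknown tail")
  expect_error(kk_real_part(cd_spectrum(lam[1:4], Im(v)[1:4])), "coarse")
})

test_that("forward and inverse transforms round-trip within the tail bias", {
  lam <- seq(150, 320, by = 0.5)
  v <- lorentz_pair(lam)
  re_rec <- kk_real_part(cd_spectrum(lam, Im(v)))
  im_back <- kk_imag_part(re_rec)
  inb <- lam >= 188 & lam <= 244
  rms <- sqrt(mean((Re(im_back$values[inb]) - Im(v[inb]))^2)) /
    sqrt(mean(Im(v[inb])^2))
  expect_lt(rms, 0.15)   # dispersive tails decay slowly; bias documented
})

test_that("mean polarizability is self-consistent with the forward model", {
  lib1 <- make_lorentzian_library(1L, params = data.frame(center = 215, width = 9,
                                                          peak = 2e-9),
                                  labels = "uni")
  s <- prepare_structure(make_helix(8), typing = uniform_typing())
  ps <- assign_protein_polarizabilities(c(a = 1, b = 0, c = 0, o = 0), lib1)
  oa <- optical_activity(s, ps)
  rec <- training_record("h", s, cd_spectrum(oa$grid, Im(oa$values)),
                         o = oa$values)
  mp <- mean_polarizability(rec)
  truth <- ps$curves[, 1L]
  expect_lt(max(Mod(mp$values - truth)) / max(Mod(truth)), 1e-8)

  # square-root homogeneity: o scaled by 4 doubles alpha
  rec4 <- training_record("h", s, cd_spectrum(oa$grid, 4 * Im(oa$values)),
                          o = 4 * oa$values)
  mp4 <- mean_polarizability(rec4)
  expect_lt(max(Mod(mp4$values - 2 * mp$values)) / max(Mod(mp$values)), 1e-10)
})

test_that("two-type mean polarizability lies between the type values", {
  lib <- make_lorentzian_library(2L, params = data.frame(
    center = c(205, 225), width = c(8, 10), peak = c(2e-9, 2e-9)),
    labels = c("C_any", "N_any"))
  tab <- element3_typing()
  s <- prepare_structure(make_helix(10), typing = tab)
  s$atoms$type_label[s$atoms$type_label == "O_any"] <- "C_any"
  ps <- assign_protein_polarizabilities(c(a = 1, b = 0, c = 0, o = 0), lib)
  oa <- optical_activity(s, ps)
  rec <- training_record("h", s, cd_spectrum(oa$grid, Im(oa$values)),
                         o = oa$values)
  mp <- mean_polarizability(rec)
  hull_max <- pmax(Mod(ps$curves[, 1L]), Mod(ps$curves[, 2L]))
  expect_true(all(Mod(mp$values) <= 1.5 * hull_max))
  expect_gt(max(Mod(mp$values)), 0)
})

test_that("the Monte Carlo fit recovers spectra on a noise-free corpus", {
  corpus <- make_synthetic_corpus()
  fit <- fit_atomic_polarizabilities(corpus, config = mc_config(n_iter = 4000L),
                                     seed = 11)
  expect_lte(fit$objective, 0.05)
  expect_true(all(fit$k >= 0) && all(fit$kprime >= 0))
  # determinism: identical seed gives an identical trace and coefficients
  fit2 <- fit_atomic_polarizabilities(corpus, config = mc_config(n_iter = 4000L),
                                      seed = 11)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$k, fit2$k)
})

test_that("a chain started at an optimum stays there at zero temperature", {
  corpus <- make_synthetic_corpus(lengths = c(10L, 12L))
  fit0 <- fit_atomic_polarizabilities(corpus, config = mc_config(n_iter = 1500L),
                                      seed = 3)
  refit <- fit_atomic_polarizabilities(
    corpus, config = mc_config(n_iter = 400L, t0 = 0),
    seed = 4, init = list(k = fit0$k, kprime = fit0$kprime))
  expect_lte(refit$objective, fit0$objective + 1e-12)
  # greedy phase: accepted objectives never increase
  expect_true(all(diff(refit$trace$objective) <= 1e-12))
})

test_that("recovery degrades gracefully with noise", {
  levels <- c(0, 0.05, 0.15)
  objs <- vapply(levels, function(nl) {
    corpus <- make_synthetic_corpus(lengths = c(10L, 14L), noise_sd = nl,
                                    seed = 31)
    fit_atomic_polarizabilities(corpus, config = mc_config(n_iter = 1200L),
                                seed = 7)$objective
  }, numeric(1))
  expect_true(all(diff(objs) > 0))
})

test_that("degenerate corpora are rejected", {
  expect_error(fit_atomic_polarizabilities(list()), "empty corpus")
  corpus <- make_synthetic_corpus(lengths = c(8L, 10L))
  corpus[[2L]]$spectrum <- cd_spectrum(seq(190, 240, 2),
                                       rep(1, 26))
  expect_error(fit_atomic_polarizabilities(corpus), "share one wavelength grid")
})
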