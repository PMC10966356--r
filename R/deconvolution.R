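# The training side of the model: recover the real (dispersive) part of
# the optical activity from an ellipticity spectrum by a discrete
# Kramers-Kronig transform, extract per-protein mean polarizabilities,
# and learn atomic polarizability curves from a corpus of
# (structure, spectrum) pairs by simulated-annealing Monte Carlo over
# non-negative combination coefficients.

#' Bundle a structure and its spectrum for training
#'
#' @param id protein identifier.
#' @param structure a [protein_structure()] with dipole directions and
#'   type labels assigned.
#' @param spectrum experimental molar ellipticity, a [cd_spectrum()].
#' @param o optional complex optical-activity curve on the same grid;
#'   when absent the real part is recovered by [kk_real_part()].
#' @return Object of class `training_record`.
#' @export
training_record <- function(id, structure, spectrum, o = NULL) {
  stopifnot(inherits(structure, "protein_structure"),
            inherits(spectrum, "cd_spectrum"))
  if (!is.null(o) && length(o) != length(spectrum$grid))
    stop("o must match the spectrum grid")
  structure(list(id = id, structure = structure, spectrum = spectrum, o = o),
            class = "training_record")
}

# ---- Kramers-Kronig ---------------------------------------------------------

# Maclaurin (alternating-point) principal-value sum on a uniform grid.
# dir = +1: real part from imaginary part; dir = -1: imaginary from real.
maclaurin_kk <- function(nu, f, dir = 1L) {
  n <- length(nu)
  h <- nu[2L] - nu[1L]
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- seq((i %% 2L) + 1L, n, by = 2L)       # opposite parity to i
    d <- nu[j]^2 - nu[i]^2
    if (dir > 0) out[i] <- (2 / pi) * 2 * h * sum(nu[j] * f[j] / d)
    else         out[i] <- -(2 / pi) * 2 * h * nu[i] * sum(f[j] / d)
  }
  out
}

kk_transform <- function(spec, dir, extension = list(mode = "zero"), n_fine = NULL) {
  lam <- spec$grid
  if (length(lam) < 5L) stop("grid too coarse for a Kramers-Kronig transform (< 5 points)")
  vals <- Re(spec$values)
  nu <- rev(1 / lam)                 # ascending frequency-like variable
  fv <- rev(vals)
  n_fine <- n_fine %||% max(4L * length(nu), 257L)
  nug <- seq(min(nu), max(nu), length.out = n_fine)
  fg <- stats::approx(nu, fv, xout = nug)$y
  mode <- extension$mode %||% "zero"
  if (!mode %in% c("zero", "lorentz"))
    stop("unknown tail-extension mode: ", mode)
  if (mode == "lorentz") {
    ext <- lorentz_tail_extension(nug, fg, extension)
    nug <- ext$nu; fg <- ext$f
  }
  g <- maclaurin_kk(nug, fg, dir = dir)
  out <- stats::approx(nug, g, xout = nu)$y
  cd_spectrum(lam, rev(out), per_residue = isTRUE(spec$meta$per_residue),
              source = paste0("kk(", spec$meta$source, ")"))
}

# Fit a single damped-oscillator absorptive profile to the in-band data
# and extend it over a widened frequency range; falls back to plain
# zero truncation if the fit fails.
lorentz_tail_extension <- function(nu, f, extension) {
  pad <- extension$pad %||% 1.0
  span <- max(nu) - min(nu)
  lo <- max(min(nu) - pad * span, 0.25 * min(nu))
  hi <- max(nu) + pad * span
  h <- nu[2L] - nu[1L]
  nug <- seq(lo, hi, by = h)
  fg <- rep(0, length(nug))
  inb <- nug >= min(nu) - h / 2 & nug <= max(nu) + h / 2
  fg[inb] <- stats::approx(nu, f, xout = nug[inb], rule = 2)$y
  fit <- tryCatch({
    i0 <- which.max(abs(f))
    st <- list(A = f[i0] * nu[i0]^2, nu0 = nu[i0], g = 0.2 * span)
    stats::nls(f ~ A * g * nu / ((nu0^2 - nu^2)^2 + g^2 * nu^2),
               data = data.frame(nu = nu, f = f), start = st,
               control = stats::nls.control(warnOnly = TRUE))
  }, error = function(e) NULL)
  if (!is.null(fit)) {
    p <- as.list(stats::coef(fit))
    tail_vals <- p$A * p$g * nug / ((p$nu0^2 - nug^2)^2 + p$g^2 * nug^2)
    fg[!inb] <- tail_vals[!inb]
  }
  list(nu = nug, f = fg)
}

#' Kramers-Kronig recovery of the dispersive part
#'
#' Discrete principal-value Kramers-Kronig transform (Maclaurin
#' alternating-point scheme on a uniform frequency grid) of an
#' absorptive curve, returning the dispersive (real) counterpart on the
#' same wavelength grid. The out-of-band contribution is handled by a
#' configurable tail model: `"zero"` (default; truncation, with a bias
#' documented in the vignette) or `"lorentz"` (damped-oscillator tail
#' extrapolation).
#'
#' @param theta a [cd_spectrum()] holding the imaginary (absorptive)
#'   part, e.g. a molar-ellipticity spectrum.
#' @param extension list with `mode` ("zero" or "lorentz") and, for
#'   "lorentz", `pad` (band widening as a fraction of the band).
#' @return A real-valued [cd_spectrum()] of the dispersive part.
#' @export
kk_real_part <- function(theta, extension = list(mode = "zero")) {
  kk_transform(theta, dir = 1L, extension = extension)
}

#' Inverse Kramers-Kronig: absorptive part from the dispersive part
#'
#' @param re_spec a real-valued [cd_spectrum()] of the dispersive part.
#' @inheritParams kk_real_part
#' @return A [cd_spectrum()] of the absorptive part.
#' @export
kk_imag_part <- function(re_spec, extension = list(mode = "zero")) {
  kk_transform(re_spec, dir = -1L, extension = extension)
}

# ---- mean polarizability ----------------------------------------------------

#' Mean polarizability of a protein
#'
#' Solves `alpha_p(lambda)^2 = -o_p(lambda) / sum_CG(lambda)` for the
#' complex mean polarizability, where the pair sum is the rotational
#' average of [rotational_average_CG()] (identical to the unrotated
#' scalar). The branch of the square root is chosen for continuity in
#' wavelength, anchored so the imaginary part is non-negative at the
#' dominant absorption band. Wavelengths with a vanishing denominator
#' are dropped with a message.
#'
#' @param record a [training_record()]; when `record$o` is absent the
#'   real part of the optical activity is recovered with
#'   [kk_real_part()].
#' @param extension tail-model configuration for [kk_real_part()].
#' @return List with `grid` and complex `values` (class `polar_curve`,
#'   type label `"mean"`).
#' @export
mean_polarizability <- function(record, extension = list(mode = "zero")) {
  grid <- record$spectrum$grid
  o <- record$o
  if (is.null(o)) {
    re <- kk_real_part(record$spectrum, extension = extension)
    o <- complex(real = Re(re$values), imaginary = Re(record$spectrum$values))
  }
  Tsum <- sum(pair_kernel(record$structure)$T)
  S <- Tsum / grid^2
  ok <- abs(S) > .Machine$double.eps * abs(Tsum)
  if (!all(ok)) message(sum(!ok), " wavelength(s) dropped: vanishing pair-sum denominator")
  grid <- grid[ok]; o <- o[ok]; S <- S[ok]
  a2 <- -o / S
  a <- sqrt(a2)
  # continuity of the square-root branch along the grid
  for (k in seq_along(a)[-1L]) {
    if (Mod(a[k] - a[k - 1L]) > Mod(-a[k] - a[k - 1L])) a[k] <- -a[k]
  }
  peak <- which.max(abs(Im(a)))
  if (length(peak) && Im(a[peak]) < 0) a <- -a
  polar_curve("mean", grid, a)
}

# ---- Monte Carlo fitting ----------------------------------------------------

# S^p_{tt'} = sum over atoms i of type t, j of type t' (i != j) of
# Chat_ij G_ij; theta_p(lambda) then contracts this with Im[a_t a_t'].
type_pair_sums <- function(s, labels) {
  Tm <- pair_kernel(s)$T
  X <- outer(s$atoms$type_label, labels, `==`) * 1
  t(X) %*% Tm %*% X
}

#' Monte Carlo settings for the polarizability fit
#'
#' @param n_iter chain length.
#' @param t0 initial temperature as a fraction of the starting
#'   objective (0 gives a pure greedy chain).
#' @param cooling geometric cooling factor per iteration.
#' @param proposal_sd standard deviation of the log-space Gaussian
#'   single-coordinate proposals (guarantees positivity).
#' @param objective `"nad"` (default) or `"nrmsd"`.
#' @param extension Kramers-Kronig tail model, see [kk_real_part()].
#' @return Named list of settings.
#' @export
mc_config <- function(n_iter = 8000L, t0 = 0.05, cooling = 0.9995,
                      proposal_sd = 0.35, objective = c("nad", "nrmsd"),
                      extension = list(mode = "zero")) {
  list(n_iter = as.integer(n_iter), t0 = t0, cooling = cooling,
       proposal_sd = proposal_sd, objective = match.arg(objective),
       extension = extension)
}

#' Fit atomic polarizability curves from a training corpus
#'
#' Learns non-negative coefficients k and k' that assemble each atomic
#' polarizability from the per-protein mean polarizabilities:
#' real part `sum_p k[t,p] Re(alpha_p)`, imaginary part
#' `sum_p k'[t,p] Im(alpha_p)`. A simulated-annealing Monte Carlo chain
#' (log-space Gaussian single-coordinate proposals, geometric cooling)
#' minimizes the mean NAD between the forward-model spectra and the
#' experimental ones over the corpus. Deterministic given `seed`.
#'
#' @param corpus list of [training_record()]s (>= 1) on one common
#'   wavelength grid; structures must be typed, with dipoles assigned.
#' @param config settings from [mc_config()].
#' @param seed integer seed.
#' @param init optional list with matrices `k` and `kprime`
#'   (`n_types x n_proteins`) to start from; default 1/P everywhere
#'   plus a deterministic global rescale.
#' @return List with `k`, `kprime` (matrices, types x proteins),
#'   `labels`, `ids`, `grid`, `alpha` (complex matrix, wavelengths x
#'   types), `objective` (final mean NAD), `per_protein` (named final
#'   per-protein deviations) and `trace` (data.frame iter, temperature,
#'   objective of accepted states).
#' @export
fit_atomic_polarizabilities <- function(corpus, config = mc_config(), seed = 1L,
                                        init = NULL) {
  if (length(corpus) < 1L) stop("empty corpus")
  grid <- corpus[[1L]]$spectrum$grid
  for (r in corpus) {
    if (!isTRUE(all.equal(r$spectrum$grid, grid)))
      stop("all corpus spectra must share one wavelength grid")
    if (any(r$structure$atoms$is_D))
      stop("D-residue structures are not supported in the fitter")
  }
  labels <- sort(unique(unlist(lapply(corpus, function(r) r$structure$atoms$type_label))))
  if (anyNA(labels)) stop("typing error: corpus structures lack type labels")
  P <- length(corpus); Tn <- length(labels); M <- length(grid)

  S <- lapply(corpus, function(r) type_pair_sums(r$structure, labels))
  theta_exp <- vapply(corpus, function(r) Re(r$spectrum$values), numeric(M))
  theta_exp <- matrix(theta_exp, M, P)
  alpha_p <- vapply(corpus, function(r) {
    mp <- mean_polarizability(r, extension = config$extension)
    if (length(mp$grid) != M) stop("mean polarizability lost wavelengths; cannot fit")
    mp$values
  }, complex(M))
  alpha_p <- matrix(alpha_p, M, P)
  Rp <- Re(alpha_p); Ip <- Im(alpha_p)

  forward <- function(alpha) {           # alpha: M x Tn complex
    re <- Re(alpha); im <- Im(alpha)
    out <- matrix(0, M, P)
    for (p in seq_len(P)) {
      Sre <- re %*% S[[p]]
      out[, p] <- -2 * rowSums(Sre * im) / grid^2
    }
    out
  }
  devfun <- if (config$objective == "nad") {
    function(e, m) sum(abs(e - m)) / sum(abs(e))
  } else {
    function(e, m) sqrt(sum((e - m)^2) / sum(e^2))
  }
  objective <- function(k, kp) {
    alpha <- complex(real = Rp %*% t(k), imaginary = Ip %*% t(kp))
    alpha <- matrix(alpha, M, Tn)
    th <- forward(alpha)
    mean(vapply(seq_len(P), function(p) devfun(theta_exp[, p], th[, p]), numeric(1)))
  }

  set.seed(as.integer(seed))
  if (is.null(init)) {
    k <- matrix(1 / P, Tn, P); kp <- matrix(1 / P, Tn, P)
    # deterministic global rescale: alpha scales by s, theta by s^2
    scales <- exp(seq(log(1e-4), log(1e4), length.out = 161L))
    vals <- vapply(scales, function(sc) objective(sc * k, sc * kp), numeric(1))
    sc <- scales[which.min(vals)]
    k <- sc * k; kp <- sc * kp
  } else {
    k <- init$k; kp <- init$kprime
    stopifnot(identical(dim(k), c(Tn, P)), identical(dim(kp), c(Tn, P)))
  }
  if (any(k < 0) || any(kp < 0)) stop("coefficients must be non-negative")

  obj <- objective(k, kp)
  if (!is.finite(obj)) stop("non-finite objective at initialization")
  temp <- config$t0 * obj
  n_par <- 2L * Tn * P
  trace <- data.frame(iter = 0L, temperature = temp, objective = obj)
  best <- list(k = k, kp = kp, obj = obj)

  for (it in seq_len(config$n_iter)) {
    idx <- sample.int(n_par, 1L)
    kc <- k; kpc <- kp
    fac <- exp(stats::rnorm(1L, 0, config$proposal_sd))
    if (idx <= Tn * P) kc[idx] <- kc[idx] * fac
    else kpc[idx - Tn * P] <- kpc[idx - Tn * P] * fac
    cand <- objective(kc, kpc)
    if (!is.finite(cand)) { temp <- temp * config$cooling; next }
    d <- cand - obj
    accept <- d < 0 || (temp > 0 && stats::runif(1L) < exp(-d / temp))
    if (accept) {
      k <- kc; kp <- kpc; obj <- cand
      trace <- rbind(trace, data.frame(iter = it, temperature = temp, objective = obj))
      if (obj < best$obj) best <- list(k = k, kp = kp, obj = obj)
    }
    temp <- temp * config$cooling
  }

  k <- best$k; kp <- best$kp
  alpha <- matrix(complex(real = Rp %*% t(k), imaginary = Ip %*% t(kp)), M, Tn)
  colnames(alpha) <- labels
  th <- forward(alpha)
  per <- vapply(seq_len(P), function(p) devfun(theta_exp[, p], th[, p]), numeric(1))
  names(per) <- vapply(corpus, `[[`, "", "id")
  dimnames(k) <- dimnames(kp) <- list(labels, names(per))
  list(k = k, kprime = kp, labels = labels, ids = names(per), grid = grid,
       alpha = alpha, objective = best$obj, per_protein = per, trace = trace)
}

#' Package a fitted polarizability set as a library
#'
#' Wraps the fitted curves as a single-base-entry [polar_library()]
#' whose content is the mean secondary-structure content of the corpus.
#'
#' @param fit result of [fit_atomic_polarizabilities()].
#' @param corpus the corpus the fit was run on.
#' @return A [polar_library()].
#' @export
fit_to_library <- function(fit, corpus) {
  contents <- vapply(corpus, function(r) ss_content(r$structure), numeric(4))
  content <- rowMeans(matrix(contents, 4L, dimnames = list(c("a", "b", "c", "o"), NULL)))
  content <- content / sum(content)
  polar_library(fit$grid,
                base = list(list(id = "fitted", content = content, curves = fit$alpha)))
}
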