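#' Two-component fingerprint model for focus-ISM
#'
#' Describes the micro-image classification model: a narrow centered 2D
#' Gaussian of standard deviation `sigma_sig` (pitch units) for the
#' in-focus light, and a broad Gaussian of standard deviation `sigma_bkg`
#' for the out-of-focus light. `sigma_bkg` is either fitted freely within
#' `[sigma_bkg_min, sigma_bkg_max]` (the lower bound prevents the
#' background term from absorbing in-focus light at low counts) or held
#' fixed at `sigma_bkg_value`. Micro-images with fewer than `min_counts`
#' photons are fitted on their 3x3-scan-neighborhood sum instead.
#'
#' @param sigma_sig In-focus standard deviation, element-pitch units.
#' @param sigma_bkg_policy `"free"` or `"fixed"`.
#' @param sigma_bkg_value Background sigma when the policy is `"fixed"`.
#' @param sigma_bkg_min,sigma_bkg_max Bounds for the free policy.
#' @param min_counts Photon threshold for direct per-pixel fitting.
#' @return An object of class `fingerprint_model`.
#' @export
fingerprint_model <- function(sigma_sig,
                              sigma_bkg_policy = c("free", "fixed"),
                              sigma_bkg_value = NULL,
                              sigma_bkg_min = 1.5 * sigma_sig,
                              sigma_bkg_max = 10 * sigma_sig,
                              min_counts = 10) {
  sigma_bkg_policy <- match.arg(sigma_bkg_policy)
  stopifnot(sigma_sig > 0, sigma_sig < sigma_bkg_min,
            sigma_bkg_min <= sigma_bkg_max, min_counts >= 0)
  if (sigma_bkg_policy == "fixed") {
    stopifnot(!is.null(sigma_bkg_value),
              sigma_bkg_value >= sigma_bkg_min,
              sigma_bkg_value <= sigma_bkg_max)
  }
  structure(list(sigma_sig = sigma_sig,
                 sigma_bkg_policy = sigma_bkg_policy,
                 sigma_bkg_value = sigma_bkg_value,
                 sigma_bkg_min = sigma_bkg_min,
                 sigma_bkg_max = sigma_bkg_max,
                 min_counts = min_counts),
            class = "fingerprint_model")
}

# Unit-sum isotropic 2D Gaussian evaluated at the element centers, pitch
# coordinates n, m in -2..2, in flat channel order.
detector_gauss <- function(sigma) {
  el <- element_table()
  g <- exp(-(el[, "n"]^2 + el[, "m"]^2) / (2 * sigma^2))
  g / sum(g)
}

#' Calibrate the in-focus fingerprint width
#'
#' Fits a single centered, unit-sum, isotropic 2D Gaussian to a
#' unit-normalized 5x5 fingerprint by least squares and returns its
#' standard deviation in element-pitch units. The fingerprint should come
#' from a region containing only in-focus emitters (or from a simulated
#' in-focus PSF stack).
#'
#' @param x A [fingerprint()], an [ism_dataset()] (its fingerprint is
#'   used), or a 5x5 matrix.
#' @param lower,upper Search bounds for sigma (pitch units).
#' @return `sigma_sig` in pitch units; warns when the fit hits a bound.
#' @export
calibrate_sigma_sig <- function(x, lower = 0.05, upper = 5) {
  fp <- if (inherits(x, "ism_dataset")) fingerprint(x) else x
  f <- as.numeric(fp)
  if (inherits(fp, "fingerprint")) {
    el <- element_table()
    f <- unclass(fp)[cbind(el[, "n"] + 3, el[, "m"] + 3)]
  }
  stopifnot(length(f) == 25)
  if (sum(f) <= 0) stop("fingerprint has no counts")
  f <- f / sum(f)
  obj <- function(s) sum((f - detector_gauss(s))^2)
  opt <- stats::optimize(obj, c(lower, upper))
  s <- opt$minimum
  tol <- 1e-3 * (upper - lower)
  if (s - lower < tol || upper - s < tol) {
    s <- if (s - lower < tol) lower else upper
    warning("sigma_sig fit hit the ", if (s == lower) "lower" else "upper",
            " bound (", signif(s, 3), " pitch); consider a different ",
            "calibration region")
  }
  s
}

outer_channels <- function() {
  el <- element_table()
  which(abs(el[, "n"]) == 2 | abs(el[, "m"]) == 2)
}

inner_channels <- function() setdiff(1:25, outer_channels())

#' Fast outer-frame background classification (f1-ISM)
#'
#' Estimates the out-of-focus background at each scan point as the mean
#' intensity of the 16 outer-frame detector elements,
#' \deqn{\beta(x_s) = \frac{1}{16} \sum_{|n|=2 \vee |m|=2} i_{n,m}(x_s),}
#' and the in-focus signal as
#' \deqn{A(x_s) = \left(\frac{1}{9}\sum_{|n|\le 1 \wedge |m|\le 1}
#'   i_{n,m}(x_s)\; -\; \beta(x_s)\right) \cdot 25,}
#' i.e. the inner 3x3 mean minus the background, rescaled to the full
#' array. Negative results are non-physical; they are counted and (when
#' `trim_negatives` is `TRUE`) set to zero. The alternative estimator
#' `"total_minus_25beta"` uses A = N - 25 beta (N the channel sum), which
#' conserves the photon flux exactly before trimming.
#'
#' @param dataset An [ism_dataset()] (2D or 3D).
#' @param trim_negatives Clip negative signal pixels to zero.
#' @param estimator `"literal"` (inner-3x3-mean form, default) or
#'   `"total_minus_25beta"`.
#' @return A `focus_result`; see [result_images()].
#' @export
f1_classify <- function(dataset, trim_negatives = TRUE,
                        estimator = c("literal", "total_minus_25beta")) {
  estimator <- match.arg(estimator)
  nz <- n_planes(dataset)
  out_sig <- out_bkg <- out_alpha <- out_beta <- vector("list", nz)
  bmaps <- vector("list", nz)
  negs <- 0L
  for (z in seq_len(nz)) {
    cts <- plane_counts(dataset, z)
    ntot <- apply(cts, c(1, 2), sum)
    beta <- apply(cts[, , outer_channels(), drop = FALSE], c(1, 2), mean)
    a <- if (estimator == "literal") {
      inner <- apply(cts[, , inner_channels(), drop = FALSE], c(1, 2), mean)
      (inner - beta) * 25
    } else {
      ntot - 25 * beta
    }
    negs <- negs + sum(a < 0)
    if (trim_negatives) a <- pmax(a, 0)
    out_sig[[z]] <- a
    out_bkg[[z]] <- 25 * beta
    out_alpha[[z]] <- ifelse(ntot > 0, a / ntot, 0)
    out_beta[[z]] <- ifelse(ntot > 0, 25 * beta / ntot, 0)
    b <- array(rep(beta, 25), c(dim(beta), 25))
    bmaps[[z]] <- b
  }
  focus_result("f1", dataset, out_sig, out_bkg, out_alpha, out_beta,
               sigma_bkg = NULL, bmaps = bmaps,
               negatives = negs, trimmed = trim_negatives)
}

#' Two-Gaussian micro-image classification (f2-ISM)
#'
#' Fits each (post-reassignment) micro-image, normalized to unit total, to
#' the two-component model
#' \deqn{i(x_d | x_s) = \alpha\, g(x_d | 0, \sigma_\mathrm{sig}) +
#'   \beta\, g(x_d | 0, \sigma_\mathrm{bkg}),\qquad \alpha + \beta = 1,}
#' by bounded least squares, with alpha in [0, 1] and sigma_bkg per the
#' model policy. Photon-flux conservation (alpha + beta = 1) makes the
#' split exact: signal = alpha N and background = beta N sum to the
#' channel-summed input at every pixel, and both are non-negative by
#' construction. Pixels with fewer than `min_counts` photons are fitted on
#' their 3x3 scan-neighborhood sum (the fractions are then applied to the
#' pixel's own photons). The fitted background also yields the expected
#' per-element background b_nm = beta N g(x_d | 0, sigma_bkg) consumed by
#' [rl_multi_background()].
#'
#' Apply after [reassign()]: post-APR micro-images carry a purely axial
#' meaning, which is what the model assumes.
#'
#' @param dataset An [ism_dataset()], typically the `registered` component
#'   of an [reassign()] result.
#' @param model A [fingerprint_model()].
#' @return A `focus_result`; see [result_images()].
#' @export
f2_classify <- function(dataset, model) {
  stopifnot(inherits(model, "fingerprint_model"))
  if (min(dataset$counts) < 0) {
    # Fourier-shift interpolation can leave small negative excursions in
    # registered datasets; they carry no photons
    dataset$counts <- pmax(dataset$counts, 0)
  }
  nz <- n_planes(dataset)
  gs <- detector_gauss(model$sigma_sig)
  out_sig <- out_bkg <- out_alpha <- out_beta <- out_sbk <- vector("list", nz)
  bmaps <- vector("list", nz)
  fallback <- 0L
  for (z in seq_len(nz)) {
    cts <- plane_counts(dataset, z)
    d <- dim(cts)
    P <- d[1] * d[2]
    M <- t(matrix(cts, P, 25))           # 25 x P micro-images
    ntot <- colSums(M)
    lowc <- ntot < model$min_counts
    fallback <- fallback + sum(lowc & ntot > 0)
    if (any(lowc)) {
      Mb <- apply(cts, 3, boxsum3)       # P x 25, 3x3 scan binning
      M[, lowc] <- t(Mb)[, lowc]
    }
    tot <- colSums(M)
    ok <- tot > 0
    Fn <- M
    Fn[, ok] <- sweep(M[, ok, drop = FALSE], 2, tot[ok], `/`)

    fit <- fit_two_gauss(Fn[, ok, drop = FALSE], gs, model)
    alpha <- numeric(P); sbk <- rep(NA_real_, P)
    alpha[ok] <- fit$alpha
    sbk[ok] <- fit$sigma_bkg

    sig <- alpha * ntot
    bkg <- (1 - alpha) * ntot
    bkg[!ok] <- 0
    # expected per-element background image
    b <- matrix(0, 25, P)
    gbk <- exp(-outer(rowSums(element_table()^2), 1 / (2 * sbk[ok]^2)))
    gbk <- sweep(gbk, 2, colSums(gbk), `/`)
    b[, ok] <- sweep(gbk, 2, bkg[ok], `*`)

    out_sig[[z]] <- matrix(sig, d[1], d[2])
    out_bkg[[z]] <- matrix(bkg, d[1], d[2])
    out_alpha[[z]] <- matrix(ifelse(ok, alpha, 0), d[1], d[2])
    out_beta[[z]] <- matrix(ifelse(ok, 1 - alpha, 0), d[1], d[2])
    out_sbk[[z]] <- matrix(sbk, d[1], d[2])
    bmaps[[z]] <- array(t(b), c(d[1], d[2], 25))
  }
  focus_result("f2", dataset, out_sig, out_bkg, out_alpha, out_beta,
               sigma_bkg = out_sbk, bmaps = bmaps,
               negatives = 0L, trimmed = FALSE, fallback = fallback,
               model = model)
}

# Bounded least-squares fit of unit-sum micro-images (columns of Fn) to
# alpha * g(sigma_sig) + (1 - alpha) * g(sigma_bkg). For fixed sigma_bkg
# the profile over alpha is a clamped linear solution; for the free policy
# the sigma grid is searched (log-spaced) and refined parabolically.
fit_two_gauss <- function(Fn, gs, model, n_grid = 41) {
  alpha_for <- function(gb) {
    u <- gs - gb
    a <- colSums((Fn - gb) * u) / sum(u^2)
    pmin(pmax(a, 0), 1)
  }
  ssr_for <- function(gb, a) {
    resid <- Fn - outer(gs, a) - gb %o% (1 - a)
    colSums(resid^2)
  }
  if (model$sigma_bkg_policy == "fixed") {
    gb <- detector_gauss(model$sigma_bkg_value)
    a <- alpha_for(gb)
    return(list(alpha = a,
                sigma_bkg = rep(model$sigma_bkg_value, ncol(Fn))))
  }
  sgrid <- exp(seq(log(model$sigma_bkg_min), log(model$sigma_bkg_max),
                   length.out = n_grid))
  P <- ncol(Fn)
  best_ssr <- rep(Inf, P)
  ssr_all <- matrix(NA_real_, n_grid, P)
  alpha_all <- matrix(NA_real_, n_grid, P)
  for (j in seq_len(n_grid)) {
    gb <- detector_gauss(sgrid[j])
    a <- alpha_for(gb)
    alpha_all[j, ] <- a
    ssr_all[j, ] <- ssr_for(gb, a)
  }
  jbest <- max.col(-t(ssr_all), ties.method = "first")
  # parabolic refinement in log sigma
  lstep <- diff(log(sgrid))[1]
  lsig <- log(sgrid)[jbest]
  interior <- jbest > 1 & jbest < n_grid
  if (any(interior)) {
    i <- which(interior)
    ym <- ssr_all[cbind(jbest[i] - 1, i)]
    y0 <- ssr_all[cbind(jbest[i], i)]
    yp <- ssr_all[cbind(jbest[i] + 1, i)]
    off <- 0.5 * (ym - yp) / pmax(ym - 2 * y0 + yp, .Machine$double.xmin)
    off <- pmin(pmax(off, -0.5), 0.5)
    off[!is.finite(off)] <- 0
    lsig[i] <- lsig[i] + off * lstep
  }
  sig <- pmin(pmax(exp(lsig), model$sigma_bkg_min), model$sigma_bkg_max)
  # recompute alpha at the refined sigma (vectorized over pixels)
  r2 <- rowSums(element_table()^2)
  gb <- exp(-outer(r2, 1 / (2 * sig^2)))
  gb <- sweep(gb, 2, colSums(gb), `/`)
  u <- gs - gb
  a <- colSums((Fn - gb) * u) / colSums(u^2)
  a <- pmin(pmax(a, 0), 1)
  # keep the refined solution only where it actually improves the fit
  resid <- Fn - outer(gs, a) - sweep(gb, 2, 1 - a, `*`)
  ssr_ref <- colSums(resid^2)
  ssr_grid <- ssr_all[cbind(jbest, seq_len(P))]
  worse <- ssr_ref > ssr_grid
  if (any(worse)) {
    a[worse] <- alpha_all[cbind(jbest[worse], which(worse))]
    sig[worse] <- sgrid[jbest[worse]]
  }
  list(alpha = a, sigma_bkg = sig)
}

# Shared constructor for f1/f2 results; per-plane lists are collapsed to
# matrices (2D) or arrays (3D).
focus_result <- function(method, dataset, sig, bkg, alpha, beta,
                         sigma_bkg, bmaps, negatives, trimmed,
                         fallback = 0L, model = NULL) {
  collapse <- function(lst) {
    if (is.null(lst)) return(NULL)
    if (length(lst) == 1) lst[[1]] else simplify2array(lst)
  }
  structure(list(
    signal_image = collapse(sig), background_image = collapse(bkg),
    alpha_map = collapse(alpha), beta_map = collapse(beta),
    sigma_bkg_map = collapse(sigma_bkg),
    background_per_element = collapse(bmaps),
    channel_sum = sum_channels(dataset),
    method = method, negatives = negatives,
    negatives_trimmed = if (trimmed) negatives else 0L,
    fallback_pixels = fallback, model = model),
    class = "focus_result")
}

#' @export
print.focus_result <- function(x, ...) {
  cat(sprintf(
    "focus_result (%s): signal %.4g, background %.4g (%d negative pixel%s%s)\n",
    x$method, sum(x$signal_image), sum(x$background_image), x$negatives,
    if (x$negatives == 1) "" else "s",
    if (x$negatives_trimmed > 0) ", trimmed" else ""))
  invisible(x)
}

#' Images and diagnostics of a focus-ISM classification
#'
#' @param result A `focus_result` from [f1_classify()] or [f2_classify()].
#' @return List with `signal`, `background`, `alpha`, `beta`, `sigma_bkg`
#'   maps, the input `channel_sum`, and the negative-pixel count.
#' @export
result_images <- function(result) {
  stopifnot(inherits(result, "focus_result"))
  list(signal = result$signal_image,
       background = result$background_image,
       alpha = result$alpha_map, beta = result$beta_map,
       sigma_bkg = result$sigma_bkg_map,
       channel_sum = result$channel_sum,
       negatives = result$negatives)
}
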