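# run expr with a temporary, seeded RNG state; the caller's stream is untouched
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Rician noise description
#'
#' @param sigma Rician noise standard deviation in signal units (scalar, or a
#'   vector with one value per b-value); >= 0.
#' @param floor_multiplier Points with corrected signal below
#'   `floor_multiplier * sigma` are additionally flagged as near the noise
#'   floor; >= 0.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sigma = 0, floor_multiplier = 0) {
  stopifnot(is.numeric(sigma), all(sigma >= 0),
            is.numeric(floor_multiplier), floor_multiplier >= 0)
  structure(list(sigma = sigma, floor_multiplier = floor_multiplier),
            class = "noise_model")
}

#' Rician bias correction of magnitude signals
#'
#' Removes the Rician noise floor from magnitude data using the second-moment
#' identity \eqn{E[S_{noisy}^2] = S^2 + 2\sigma^2}:
#' \eqn{S_{rn} = \sqrt{S^2 - 2\sigma^2}}. Points with
#' \eqn{S^2 \le 2\sigma^2} are set to 0 and flagged (they carry no usable
#' decay information); flagged points are excluded from fits by default.
#' A homogeneous noise field is assumed; `sigma` may be a per-b-value vector.
#'
#' @param signal Magnitude signal(s), >= 0.
#' @param noise A [noise_model()]; `sigma` is recycled along `signal`.
#' @return List with `signal` (corrected values) and `flagged` (logical,
#'   points at/below the noise floor).
#' @export
rician_correct <- function(signal, noise = noise_model()) {
  stopifnot(inherits(noise, "noise_model"), all(signal >= 0))
  sigma <- rep_len(noise$sigma, length(signal))
  s2 <- signal^2 - 2 * sigma^2
  flagged <- s2 <= 0
  out <- ifelse(flagged, 0, sqrt(pmax(s2, 0)))
  flagged <- flagged | out < noise$floor_multiplier * sigma
  list(signal = out, flagged = flagged)
}

#' Estimate the Rician sigma from a homogeneous ROI
#'
#' Helper for setting [noise_model()]'s `sigma` from user-selected voxels
#' (e.g. ventricle signal at one b-value). With `method = "sd"` (high-SNR
#' regime) the Rician distribution is near-Gaussian and sigma is the sample
#' standard deviation. With `method = "rayleigh"` (background/no-signal
#' regime) sigma is recovered from the Rayleigh mean,
#' \eqn{\sigma = \bar{S} / \sqrt{\pi/2}}.
#'
#' @param roi_signal Vector of magnitude samples from the ROI.
#' @param method `"sd"` or `"rayleigh"`.
#' @return Estimated sigma (signal units).
#' @export
estimate_sigma <- function(roi_signal, method = c("sd", "rayleigh")) {
  method <- match.arg(method)
  stopifnot(length(roi_signal) >= 2, all(roi_signal >= 0))
  switch(method,
         sd = stats::sd(roi_signal),
         rayleigh = mean(roi_signal) / sqrt(pi / 2))
}

#' Two-point apparent diffusion coefficient
#'
#' Classical ADC from the b = 0 and b = `b_ref` samples:
#' \eqn{ADC = \ln(S_0 / S(b_{ref})) / b_{ref}}. A negative value (signal
#' above S0 at the reference b) is returned with a warning.
#'
#' @param curve A [decay_curve()] containing b = 0 and b = `b_ref`.
#' @param b_ref Reference b-value (s/mm^2), default 1000.
#' @return ADC (mm^2/s).
#' @export
two_point_adc <- function(curve, b_ref = 1000) {
  stopifnot(inherits(curve, "decay_curve"), b_ref > 0)
  i0 <- match(0, curve$b)
  ir <- match(b_ref, curve$b)
  if (is.na(i0) || is.na(ir))
    stop("curve must contain b = 0 and b = ", b_ref)
  adc <- log(curve$signal[i0] / curve$signal[ir]) / b_ref
  if (adc < 0) warning("negative ADC: signal at b_ref exceeds S0")
  adc
}

# parameter table: bounds and defaults per model
.fit_param_spec <- function(model) {
  switch(model,
    mono = list(names = "D",
                lower = 1e-5, upper = 1e-1, start = NA),
    mlf2 = list(names = c("D", "alpha"),
                lower = c(1e-5, 0.01), upper = c(1e-1, 1),
                start = c(NA, 0.9)),
    mlf3 = list(names = c("D", "alpha", "beta"),
                lower = c(1e-5, 0.01, 1 + 1e-6), upper = c(1e-1, 1, 2),
                start = c(NA, 0.9, 1.9)),
    dki  = list(names = c("D", "K_app"),
                lower = c(1e-5, 0), upper = c(1e-1, 10),
                start = c(NA, 0.5)),
    stop("unknown model: ", model))
}

.model_predict <- function(model, b, p, config) {
  switch(model,
         mono = model_mono(b, p[["D"]]),
         mlf2 = model_mlf2(b, p[["D"]], p[["alpha"]], config),
         mlf3 = model_mlf3(b, p[["D"]], p[["alpha"]], p[["beta"]], config),
         dki  = model_dki(b, p[["D"]], p[["K_app"]]))
}

#' Fit a diffusion signal model to one decay curve
#'
#' Bounded Levenberg-Marquardt least squares (via \pkg{minpack.lm}) of one of
#' the four signal models to a measured decay curve. Signals are Rician
#' corrected, normalized by the measured S(b = 0), and flagged noise-floor
#' points are excluded. Bounds: D in (1e-5, 1e-1) mm^2/s, alpha in
#' [0.01, 1], beta in (1, 2], K_app in [0, 10]. The starting D is the
#' two-point ADC formed from the smallest nonzero b; on non-convergence up to
#' 5 seeded, jittered restarts are attempted, and a still-unconverged fit is
#' returned flagged rather than raising. For the Mittag-Leffler models the
#' result carries the derived kurtosis `K_mlf =` [kurtosis_from_alpha()]
#' of the fitted alpha.
#'
#' @param curve A [decay_curve()]; needs at least one more point than the
#'   model has parameters.
#' @param model One of `"mono"`, `"mlf2"`, `"mlf3"`, `"dki"`.
#' @param noise A [noise_model()].
#' @param seed Integer seed controlling restart jitter (optional; fits on
#'   clean data are deterministic regardless).
#' @param fit_s0 If `TRUE`, a multiplicative S0 scale (bounds 0.2-5) is fitted
#'   alongside the model parameters instead of pinning the curve at the
#'   measured S(b = 0).
#' @param config [mlf_config()] used for Mittag-Leffler evaluations.
#' @return An object of class `"mlf_fit"`: list with `model`, `params`
#'   (named numeric), `K_mlf` (or `NA`), `residual_norm`, `converged`,
#'   `warnings` (character), `n_used`.
#' @export
fit_curve <- function(curve, model = c("mlf2", "mlf3", "dki", "mono"),
                      noise = noise_model(), seed = NULL, fit_s0 = FALSE,
                      config = mlf_config()) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "decay_curve"))
  spec <- .fit_param_spec(model)
  npar <- length(spec$names) + as.integer(fit_s0)

  rc <- rician_correct(curve$signal, noise)
  warnings <- character()
  if (any(rc$flagged))
    warnings <- c(warnings, sprintf("%d point(s) at/below the noise floor excluded",
                                    sum(rc$flagged)))
  keep <- !rc$flagged
  b <- curve$b[keep]
  s <- rc$signal[keep]
  if (length(b) < npar + 1L)
    stop("too few usable points (", length(b), ") for a ", npar,
         "-parameter fit")
  i0 <- which(b == 0)
  s0 <- if (length(i0)) s[i0] else curve$s0
  if (s0 <= 0) stop("non-positive reference signal after Rician correction")
  y <- s / s0

  # starting D from the two smallest usable b-values
  bnz <- b[b > 0][1]
  ynz <- y[b > 0][1]
  y0 <- if (length(i0)) 1 else y[1]
  D0 <- log(y0 / ynz) / bnz
  D0 <- min(max(D0, spec$lower[1] * 2), spec$upper[1] / 2)
  start <- spec$start
  start[1] <- D0
  names(start) <- spec$names
  lower <- spec$lower; upper <- spec$upper
  if (fit_s0) {
    start <- c(start, s0scale = 1)
    lower <- c(lower, 0.2); upper <- c(upper, 5)
  }

  resid_fn <- function(p) {
    p <- stats::setNames(p, names(start))
    scale <- if (fit_s0) p[["s0scale"]] else 1
    scale * .model_predict(model, b, p, config) - y
  }

  do_fit <- function(p0) {
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  }

  fit <- with_local_seed(seed, {
    f <- try(do_fit(start), silent = TRUE)
    ok <- !inherits(f, "try-error") && f$info %in% 1:4
    tries <- 0L
    while (!ok && tries < 5L) {
      tries <- tries + 1L
      jit <- start * exp(stats::runif(length(start), -0.3, 0.3))
      jit <- pmin(pmax(jit, lower), upper)
      f2 <- try(do_fit(jit), silent = TRUE)
      if (!inherits(f2, "try-error") &&
          (inherits(f, "try-error") || f2$deviance < f$deviance)) f <- f2
      ok <- !inherits(f, "try-error") && f$info %in% 1:4
    }
    f
  })
  if (inherits(fit, "try-error"))
    stop("Levenberg-Marquardt failed: ", attr(fit, "condition")$message)

  par <- stats::setNames(fit$par, names(start))
  converged <- fit$info %in% 1:4
  if (!converged)
    warnings <- c(warnings, paste0("no convergence after restarts (info=",
                                   fit$info, ")"))
  K_mlf <- if ("alpha" %in% names(par)) kurtosis_from_alpha(par[["alpha"]]) else NA_real_
  if (model == "dki") {
    chk <- dki_validity_check(list(D = par[["D"]], K_app = par[["K_app"]]),
                              max(b))
    if (!isTRUE(chk)) warnings <- c(warnings, chk)
  }
  structure(list(model = model,
                 params = par[spec$names],
                 s0scale = if (fit_s0) par[["s0scale"]] else NA_real_,
                 K_mlf = K_mlf,
                 residual_norm = sqrt(fit$deviance),
                 converged = converged,
                 warnings = warnings,
                 n_used = length(b)),
            class = "mlf_fit")
}

#' @export
print.mlf_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s, %d points):\n", x$model,
              if (x$converged) "converged" else "NOT converged", x$n_used))
  print(signif(x$params, 6))
  if (!is.na(x$K_mlf)) cat(sprintf("derived K_mlf = %.4f\n", x$K_mlf))
  cat(sprintf("residual norm = %.3g\n", x$residual_norm))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Flag a DKI fit whose sampled b-range crosses the model apex
#'
#' The DKI exponent \eqn{-bD + \frac16 b^2 D^2 K} reaches its minimum at
#' \eqn{b^* = 3/(D K)}; beyond it the fitted model increases with b, which is
#' unphysical for a decay. Returns `TRUE` when the sampled range is safe,
#' otherwise a warning string.
#'
#' @param params List or named vector with `D` and `K_app`.
#' @param b_max_sampled Largest sampled b-value (s/mm^2).
#' @return `TRUE` or a character warning.
#' @export
dki_validity_check <- function(params, b_max_sampled) {
  D <- params[["D"]]; K <- params[["K_app"]]
  stopifnot(D > 0, K >= 0, b_max_sampled >= 0)
  if (K == 0) return(TRUE)
  b_star <- 3 / (D * K)
  if (b_max_sampled > b_star)
    return(sprintf("DKI apex b* = %.0f s/mm^2 lies inside the sampled range (b_max = %.0f)",
                   b_star, b_max_sampled))
  TRUE
}

#' Voxelwise parameter maps from a 4-D diffusion-weighted stack
#'
#' Runs [fit_curve()] in every voxel of `mask`, producing 3-D maps of the
#' fitted parameters plus the two-point ADC. The 4th axis of `stack` is the
#' b/volume axis and must match `bvals`. Maps not produced by the chosen
#' model (e.g. `K_app` for an `mlf2` fit) are all-`NA`, as are voxels outside
#' the mask.
#'
#' @param stack 4-D numeric array (or `RNifti` image) of direction-averaged
#'   magnitudes.
#' @param bvals Numeric b-values (s/mm^2), length = `dim(stack)[4]`.
#' @param mask 3-D 0/1 or logical array matching the spatial grid; `NULL`
#'   fits every voxel with positive b = 0 signal.
#' @param model Signal model passed to [fit_curve()].
#' @param noise A [noise_model()].
#' @param seed Integer seed; the voxel loop consumes one reproducible RNG
#'   stream, so results are identical for identical inputs and seed.
#' @param adc_b_ref Reference b for the ADC map (default 1000); the ADC map
#'   is `NA` if that b-value (or b = 0) is absent.
#' @param fit_s0,config Passed to [fit_curve()].
#' @return An object of class `"parameter_maps"`: list of 3-D arrays
#'   `alpha`, `D`, `K_mlf`, `K_app`, `adc`, `converged` plus `mask`, with the
#'   fit setup in `attr(, "meta")`.
#' @export
fit_maps <- function(stack, bvals, mask = NULL,
                     model = c("mlf2", "mlf3", "dki", "mono"),
                     noise = noise_model(), seed = 1L, adc_b_ref = 1000,
                     fit_s0 = FALSE, config = mlf_config()) {
  model <- match.arg(model)
  stack <- unclass(as.array(stack))
  if (length(dim(stack)) != 4L)
    stop("stack must be a 4-D array")
  dims <- dim(stack)
  if (dims[4] != length(bvals))
    stop("4th axis length (", dims[4], ") does not match bvals (",
         length(bvals), ")")
  sp <- dims[1:3]
  if (is.null(mask)) {
    i0 <- which(bvals == 0)[1]
    mask <- if (is.na(i0)) array(TRUE, sp) else stack[, , , i0, drop = TRUE] > 0
    dim(mask) <- sp
  }
  mask <- array(as.logical(mask), dim(as.array(mask)))
  if (!identical(dim(mask), as.integer(sp)) && !identical(dim(mask), sp))
    stop("mask shape does not match the spatial grid")

  empty <- array(NA_real_, sp)
  maps <- list(alpha = empty, D = empty, K_mlf = empty, K_app = empty,
               adc = empty, converged = empty)
  vox <- which(mask)
  has_adc <- (0 %in% bvals) && (adc_b_ref %in% bvals)
  n_fail <- 0L

  with_local_seed(seed, {
    for (v in vox) {
      idx <- arrayInd(v, sp)
      sig <- stack[idx[1], idx[2], idx[3], ]
      if (any(!is.finite(sig)) || all(sig <= 0)) next
      cur <- try(decay_curve(bvals, pmax(sig, .Machine$double.xmin)),
                 silent = TRUE)
      if (inherits(cur, "try-error")) { n_fail <- n_fail + 1L; next }
      ft <- try(fit_curve(cur, model = model, noise = noise, seed = NULL,
                          fit_s0 = fit_s0, config = config), silent = TRUE)
      if (inherits(ft, "try-error")) { n_fail <- n_fail + 1L; next }
      p <- ft$params
      maps$D[v] <- p[["D"]]
      if ("alpha" %in% names(p)) maps$alpha[v] <- p[["alpha"]]
      if ("K_app" %in% names(p)) maps$K_app[v] <- p[["K_app"]]
      maps$K_mlf[v] <- ft$K_mlf
      maps$converged[v] <- as.numeric(ft$converged)
      if (has_adc)
        maps$adc[v] <- suppressWarnings(two_point_adc(cur, adc_b_ref))
    }
  })

  structure(c(maps, list(mask = mask)),
            meta = list(model = model, sigma = noise$sigma, seed = seed,
                        bvals = bvals, n_voxels = length(vox),
                        n_failed = n_fail, fit_s0 = fit_s0,
                        bounds = .fit_param_spec(model)),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("parameter maps: model %s, grid %s, %d voxels fitted (%d failed)\n",
              meta$model, paste(dim(x$mask), collapse = "x"),
              meta$n_voxels, meta$n_failed))
  for (nm in c("alpha", "D", "K_mlf", "K_app", "adc")) {
    v <- x[[nm]][x$mask]
    if (all(is.na(v))) next
    cat(sprintf("  %-6s mean %.4g  sd %.3g\n", nm,
                mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE)))
  }
  invisible(x)
}
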