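#' Reference ROI parameters for human brain tissue classes
#'
#' Mean fitted parameters for white matter (WM), gray matter (GM), chronic
#' ischemic tissue (IT) and cerebrospinal fluid (CSF) regions of interest in
#' a chronic-stroke brain at 3 T (b = 0-4000 s/mm^2, effective diffusion
#' time 31 ms): the time-fractional order `alpha`, the Mittag-Leffler and
#' apparent excess kurtosis `K_mlf`/`K_app`, and diffusivities (mm^2/s)
#' from the Mittag-Leffler fit (`D_mlf`), the kurtosis fit (`D_K`) and the
#' two-point monoexponential fit (`adc`). These drive the default
#' [phantom_spec()] tissue classes.
#'
#' @format Data frame with one row per ROI and columns `roi`, `alpha`,
#'   `K_mlf`, `K_app`, `D_mlf`, `D_K`, `adc`.
#' @export
brain_roi_reference <- data.frame(
  roi   = c("WM", "GM", "IT", "CSF"),
  alpha = c(0.49, 0.77, 0.94, 0.97),
  K_mlf = c(1.75, 0.75, 0.18, 0.12),
  K_app = c(0.99, 0.58, 0.35, 0.29),
  D_mlf = c(0.72, 0.97, 3.12, 3.27) * 1e-3,
  D_K   = c(0.75, 1.02, 3.26, 3.46) * 1e-3,
  adc   = c(0.68, 0.93, 2.97, 3.12) * 1e-3,
  stringsAsFactors = FALSE
)

#' Synthetic brain-phantom specification
#'
#' Describes a multi-b-value phantom made of homogeneous tissue blocks. By
#' default the four [brain_roi_reference] classes fill equal slabs along the
#' first axis of a 16 x 16 x 4 grid, sampled at b = 0, 500, 1000, 3000,
#' 4000 s/mm^2 with the two-parameter Mittag-Leffler generator; a `dki`
#' generator mode instead uses each class's (`D_K`, `K_app`), and `mono`
#' uses the ADC alone.
#'
#' @param classes Data frame with columns `label`, `alpha`, `D`, and
#'   (for the dki generator) `K_app`; one row per tissue class. Default:
#'   the four reference ROIs, with `D` taken from the column matching the
#'   generator model.
#' @param b_values b-values (s/mm^2); must include 0.
#' @param shape 3-D grid dimensions.
#' @param s0 Baseline (b = 0) signal, > 0.
#' @param sigma Rician noise standard deviation in signal units, >= 0.
#' @param seed RNG seed for the noise.
#' @param model Generator model: `"mlf2"`, `"dki"` or `"mono"`.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(classes = NULL,
                         b_values = c(0, 500, 1000, 3000, 4000),
                         shape = c(16L, 16L, 4L), s0 = 1000, sigma = 0,
                         seed = 1L, model = c("mlf2", "dki", "mono")) {
  model <- match.arg(model)
  if (is.null(classes)) {
    r <- brain_roi_reference
    classes <- data.frame(
      label = r$roi,
      alpha = r$alpha,
      D = switch(model, mlf2 = r$D_mlf, dki = r$D_K, mono = r$adc),
      K_app = r$K_app,
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(classes),
            all(c("label", "alpha", "D") %in% names(classes)),
            nrow(classes) >= 1,
            all(classes$D > 0),
            all(classes$alpha > 0 & classes$alpha <= 1))
  if (model == "dki" && !"K_app" %in% names(classes))
    stop("dki generator needs a K_app column in classes")
  stopifnot(length(shape) == 3L, all(shape >= 1), s0 > 0, all(sigma >= 0),
            length(b_values) >= 2, all(b_values >= 0))
  if (!0 %in% b_values) stop("b_values must include 0")
  structure(list(classes = classes, b_values = sort(unique(b_values)),
                 shape = as.integer(shape), s0 = s0, sigma = sigma,
                 seed = as.integer(seed), model = model),
            class = "phantom_spec")
}

#' Generate a synthetic multi-b-value phantom
#'
#' Builds a 4-D signal stack: each voxel gets its class's noise-free decay
#' `s0 * model(b)` at every b-value, then Rician noise of standard deviation
#' `sigma` is applied (if positive). Classes occupy equal slabs along the
#' first grid axis, in the order given. The returned ground truth makes
#' round-trip recovery tests self-contained.
#'
#' @param spec A [phantom_spec()].
#' @return List with `stack` (4-D array, x-y-z-b), `truth` (list of 3-D
#'   arrays `label_map` (integer class index), `alpha_true`, `D_true`,
#'   `K_true` — `K_true` is the generator's `K_app` for the dki model and
#'   [kurtosis_from_alpha()] otherwise), and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$shape
  ncls <- nrow(spec$classes)
  slab <- ceiling(seq_len(sp[1]) / (sp[1] / ncls))
  slab <- pmin(slab, ncls)
  label_map <- array(rep(slab, times = sp[2] * sp[3]), sp)

  b <- spec$b_values
  curves <- matrix(NA_real_, ncls, length(b))
  for (k in seq_len(ncls)) {
    cl <- spec$classes[k, ]
    curves[k, ] <- spec$s0 * switch(spec$model,
      mlf2 = model_mlf2(b, cl$D, cl$alpha),
      dki  = model_dki(b, cl$D, cl$K_app),
      mono = model_mono(b, cl$D))
  }
  stack <- array(NA_real_, c(sp, length(b)))
  for (i in seq_along(b)) {
    vol <- curves[label_map, i]
    dim(vol) <- sp
    stack[, , , i] <- vol
  }
  if (any(spec$sigma > 0)) {
    sig_b <- rep_len(spec$sigma, length(b))
    with_local_seed(spec$seed, {
      for (i in seq_along(b))
        stack[, , , i] <- add_rician_noise(stack[, , , i], sig_b[i])
    })
  }
  K_true_cls <- if (spec$model == "dki") spec$classes$K_app
                else kurtosis_from_alpha(spec$classes$alpha)
  mk <- function(v) { m <- v[label_map]; dim(m) <- sp; m }
  truth <- list(label_map = label_map,
                alpha_true = mk(spec$classes$alpha),
                D_true = mk(spec$classes$D),
                K_true = mk(K_true_cls))
  list(stack = stack, truth = truth, spec = spec)
}

#' Apply Rician noise to magnitude signals
#'
#' \eqn{S_{noisy} = \sqrt{(S + n_1)^2 + n_2^2}} with independent
#' \eqn{n_1, n_2 \sim N(0, \sigma^2)} — the magnitude statistics of a
#' complex signal with Gaussian channel noise. Satisfies
#' \eqn{E[S_{noisy}^2] = S^2 + 2\sigma^2} (the identity inverted by
#' [rician_correct()]); at S = 0 the output is Rayleigh with mean
#' \eqn{\sigma\sqrt{\pi/2}}.
#'
#' @param signal Noise-free magnitudes, >= 0 (any shape; shape preserved).
#' @param sigma Noise standard deviation, >= 0 (0 returns `signal`
#'   unchanged).
#' @param seed Optional seed; the caller's RNG state is preserved when it is
#'   given.
#' @return Noisy magnitudes with the shape of `signal`.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  stopifnot(all(signal >= 0), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(signal)
  with_local_seed(seed, {
    n <- length(signal)
    noisy <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                    stats::rnorm(n, 0, sigma)^2)
    if (!is.null(dim(signal))) dim(noisy) <- dim(signal)
    noisy
  })
}

#' Class-wise summary of recovered parameter maps
#'
#' Convenience for phantom round trips: mean and standard deviation of each
#' map within each ground-truth class.
#'
#' @param maps A `"parameter_maps"` object from [fit_maps()].
#' @param truth The `truth` element returned by [make_phantom()].
#' @param labels Optional class labels (defaults to the class indices).
#' @return Data frame with one row per class: means and SDs of `alpha`, `D`,
#'   `K_mlf`, `K_app`, `adc` within the class (NA where a map was not
#'   produced).
#' @export
class_summary <- function(maps, truth, labels = NULL) {
  stopifnot(inherits(maps, "parameter_maps"))
  cls <- sort(unique(as.integer(truth$label_map)))
  if (is.null(labels)) labels <- as.character(cls)
  res <- lapply(seq_along(cls), function(i) {
    sel <- truth$label_map == cls[i] & maps$mask
    row <- list(class = labels[i], n = sum(sel))
    for (nm in c("alpha", "D", "K_mlf", "K_app", "adc")) {
      v <- maps[[nm]][sel]
      row[[paste0(nm, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(nm, "_sd")]] <- stats::sd(v, na.rm = TRUE)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
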