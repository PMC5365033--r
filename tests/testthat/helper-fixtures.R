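# closed form E_{1/2}(-x) = exp(x^2) * erfc(x), computed in log space so it
# survives x ~ 10 where erfc underflows
e_half_closed <- function(x) exp(x^2 + pnorm(-sqrt(2) * x, log.p = TRUE) + log(2))

# the acquisition used throughout: Delta = 41.2 ms, delta = 30.6 ms
paper_protocol <- function(G = 4e-5) {
  acquisition_protocol(G = G, delta = 30.6e-3, Delta = 41.2e-3)
}

paper_bvals <- c(0, 500, 1000, 3000, 4000)

# noise-free curve from a generator model, at unit s0
clean_curve <- function(model, D, alpha = NULL, beta = NULL, K_app = NULL,
                        b = paper_bvals, s0 = 1) {
  sig <- s0 * switch(model,
                     mono = model_mono(b, D),
                     mlf2 = model_mlf2(b, D, alpha),
                     mlf3 = model_mlf3(b, D, alpha, beta),
                     dki  = model_dki(b, D, K_app))
  decay_curve(b, sig, s0 = s0)
}

# Cramer-Rao standard deviations for fits of S/S(0)-normalized signals at
# relative noise sigma_rel. The covariance carries an independent term per
# point plus the rank-one term from dividing every point by the same noisy
# S(b = 0) measurement; the b = 0 point itself carries no information after
# normalization.
crlb_normalized <- function(model, D, alpha = NULL, K_app = NULL,
                            sigma_rel, b = c(500, 1000, 3000, 4000)) {
  pred <- function(p) switch(model,
                             mono = model_mono(b, p[1]),
                             mlf2 = model_mlf2(b, p[1], p[2]),
                             dki  = model_dki(b, p[1], p[2]))
  p0 <- switch(model, mono = D, mlf2 = c(D, alpha), dki = c(D, K_app))
  y <- pred(p0)
  J <- vapply(seq_along(p0), function(j) {
    h <- 1e-6 * abs(p0[j])
    pp <- pm <- p0
    pp[j] <- p0[j] + h; pm[j] <- p0[j] - h
    (pred(pp) - pred(pm)) / (2 * h)
  }, numeric(length(b)))
  C <- sigma_rel^2 * (diag(length(b)) + outer(y, y))
  V <- solve(t(as.matrix(J)) %*% solve(C) %*% as.matrix(J))
  sqrt(diag(V))   # sd of (D, second parameter if any)
}
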