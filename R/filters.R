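# Separable spatiotemporal filter of the perceptual front end:
# difference-of-Gaussians in space, biphasic gamma-difference in time.

#' Spatial difference-of-Gaussians filter profile
#'
#' `exp(-x^2 / (2 sigma_c^2)) - (sigma_c^2 / sigma_s^2) * exp(-x^2 / (2 sigma_s^2))`.
#' The surround amplitude ratio makes the filter integrate to a small
#' positive value; at x = 0 the weight is `1 - sigma_c^2 / sigma_s^2`.
#'
#' @param x position in pixels (vectorized; even function of x).
#' @param sigma_c,sigma_s center and surround SDs in pixels, `sigma_c < sigma_s`.
#' @return filter weights.
#' @export
spatial_filter_profile <- function(x, sigma_c, sigma_s) {
  if (sigma_c <= 0 || sigma_s <= 0) stop("filter SDs must be positive")
  exp(-x^2 / (2 * sigma_c^2)) - (sigma_c^2 / sigma_s^2) * exp(-x^2 / (2 * sigma_s^2))
}

#' Biphasic temporal filter profile
#'
#' `(1/n! - B (t/tau)^2 / (n+2)!) * (t/tau)^n * exp(-t/tau)` for t >= 0:
#' a cascade of `n_stages` leaky integrators minus a delayed copy scaled by
#' `B`, giving a positive lobe followed (for B > 0) by a negative lobe with
#' a single sign change at `t = tau * sqrt((n+2)! / (n! B))`.
#'
#' @param t time in frames (33.3 ms per frame; vectorized, must be >= 0).
#' @param B amplitude ratio of the negative to positive lobe.
#' @param tau transient factor in frames.
#' @param n_stages number of integrator stages (non-negative integer).
#' @return filter weights; 0 at t = 0 for n_stages >= 1.
#' @export
temporal_filter_profile <- function(t, B, tau, n_stages = 5L) {
  if (any(t < 0)) stop("t must be >= 0")
  if (tau <= 0) stop("tau must be positive")
  if (n_stages < 0 || n_stages != round(n_stages))
    stop("n_stages must be a non-negative integer")
  u <- t / tau
  (1 / factorial(n_stages) - B * u^2 / factorial(n_stages + 2)) *
    u^n_stages * exp(-u)
}

# bar-to-pixel spatial response operator: M[x, b] = sum over source pixels
# x' of bar b of F_s(x - x'). Columns are the filter's response to a unit
# contrast on one bar; the field edge is implicitly zero-padded.
spatial_bar_matrix <- function(mp, sp) {
  np <- sp$n_pixels
  bw <- sp$bar_width_px
  prof <- spatial_filter_profile(-(np - 1):(np - 1), mp$sigma_c, mp$sigma_s)
  M <- matrix(0, np, sp$n_bars_per_field)
  for (b in seq_len(sp$n_bars_per_field)) {
    src <- ((b - 1) * bw + 1):(b * bw)
    for (x0 in src) M[, b] <- M[, b] + prof[(1:np) - x0 + np]
  }
  M
}

# discrete temporal kernel on the frame grid, truncated where |F_t| stays
# below 0.1% of its peak (negligible tail mass)
temporal_kernel <- function(mp, max_len = 135L) {
  k <- temporal_filter_profile(0:(max_len - 1), mp$B, mp$tau, mp$n_stages)
  keep <- which(abs(k) >= 1e-3 * max(abs(k)))
  k[seq_len(max(keep))]
}

# causal convolution operator: (X %*% KT)[, t] = sum_s X[, s] k[t - s + 1]
temporal_kernel_matrix <- function(mp, n_frames) {
  k <- temporal_kernel(mp, n_frames)
  KT <- matrix(0, n_frames, n_frames)
  for (s in seq_len(n_frames)) {
    t_idx <- s:min(n_frames, s + length(k) - 1L)
    KT[s, t_idx] <- k[t_idx - s + 1L]
  }
  KT
}
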