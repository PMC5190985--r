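# shared fixtures and independent oracles, built in code

K_DEFAULT <- 0.5 / cos(57.5 * pi / 180)

# two-tone canopy image from the scene generator's reference palettes
# (no jitter): `sky` is a logical matrix, TRUE = sky pixel
two_tone_image <- function(sky) {
  hsv_px <- function(h, s, b) grDevices::col2rgb(grDevices::hsv(h / 360, s, b))
  sky_rgb <- hsv_px(210, 0.15, 0.95)
  leaf_rgb <- hsv_px(120, 0.75, 0.33)
  px <- array(0, c(nrow(sky), ncol(sky), 3))
  for (ch in 1:3)
    px[, , ch] <- ifelse(sky, sky_rgb[ch], leaf_rgb[ch])
  canopy_image(px)
}

# brute-force agreement metrics with explicit loops; independent of the
# vectorised implementation under test
brute_agreement <- function(obs, est) {
  n <- length(obs)
  s_obs <- 0; s_est <- 0
  for (i in 1:n) { s_obs <- s_obs + obs[i]; s_est <- s_est + est[i] }
  m_obs <- s_obs / n
  m_est <- s_est / n
  sse <- 0; sae <- 0; ss_o <- 0; ss_e <- 0; s_oe <- 0
  for (i in 1:n) {
    d <- est[i] - obs[i]
    sse <- sse + d^2
    sae <- sae + abs(d)
    ss_o <- ss_o + (obs[i] - m_obs)^2
    ss_e <- ss_e + (est[i] - m_est)^2
    s_oe <- s_oe + (obs[i] - m_obs) * (est[i] - m_est)
  }
  slope <- s_oe / ss_o
  list(
    rrmse = 100 * sqrt(sse / n) / m_obs,
    mae = sae / n,
    ef = 1 - sse / ss_o,
    crm = (s_obs - s_est) / s_obs,
    r2 = s_oe^2 / (ss_o * ss_e),
    slope = slope,
    intercept = m_est - slope * m_obs
  )
}

# binomial-style standard deviation of a measured gap fraction, using the
# number of independent disk-sized patches as the effective sample size
gap_fraction_sd <- function(p, h, w, r) {
  n_eff <- h * w / (pi * r^2)
  sqrt(p * (1 - p) / n_eff)
}
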