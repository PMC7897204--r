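# Independent brute-force oracles for the titration fits. These use only
# base R linear algebra: for a fixed pKa (pair) the plateau shifts enter the
# model linearly, so each grid point is an exact linear least-squares solve.

deprot_frac <- function(pH, pKa) 1 / (1 + 10^(pKa - pH))

grid_fit_1site <- function(pH, shift, pka_grid = seq(1, 10, by = 0.01)) {
  best <- list(rss = Inf)
  for (p in pka_grid) {
    th <- deprot_frac(pH, p)
    X <- cbind(1 - th, th)
    fit <- lm.fit(X, shift)
    rss <- sum(fit$residuals^2)
    if (rss < best$rss) {
      best <- list(pKa = p, delta_min = fit$coefficients[[1L]],
                   delta_max = fit$coefficients[[2L]], rss = rss)
    }
  }
  best
}

grid_fit_2site <- function(pH, shift, coarse = 0.05, fine = 0.01,
                           lo = 1, hi = 10) {
  solve_pair <- function(p1, p2) {
    th1 <- deprot_frac(pH, p1)
    th2 <- deprot_frac(pH, p2)
    X <- cbind(1, th1, th2)
    fit <- lm.fit(X, shift)
    sum(fit$residuals^2)
  }
  best <- list(rss = Inf)
  g <- seq(lo, hi, by = coarse)
  for (p1 in g) for (p2 in g) {
    if (p2 <= p1 + 0.5) next
    rss <- solve_pair(p1, p2)
    if (rss < best$rss) best <- list(pKa1 = p1, pKa2 = p2, rss = rss)
  }
  g1 <- seq(max(lo, best$pKa1 - 0.1), best$pKa1 + 0.1, by = fine)
  g2 <- seq(max(lo, best$pKa2 - 0.1), best$pKa2 + 0.1, by = fine)
  for (p1 in g1) for (p2 in g2) {
    if (p2 <= p1 + 0.3) next
    rss <- solve_pair(p1, p2)
    if (rss < best$rss) best <- list(pKa1 = p1, pKa2 = p2, rss = rss)
  }
  best
}

# shared tiny fixtures
write_sparky_fixture <- function(path, rows) {
  writeLines(c("      Assignment         w1         w2   Data Height", "",
               rows), path)
}
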