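# shared internal helpers

# micrometers -> m is 1e-6, nm^2 -> m^2 is 1e-18, S/m -> S/cm is 1/100;
# together: sigma[S/cm] = slope[A/V] * gap[um] / area[nm^2] * 1e10
.SIGMA_SCM_PER_SLOPE_UM_NM2 <- 1e10

# round half away from zero (base round() is round-half-even)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

stopIf <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}

# evaluate expr with a locally seeded RNG, restoring global state afterwards
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Tukey box statistics: quartiles (type 7), whiskers at the most extreme
# observations within 1.5 IQR of the box, outliers beyond
tukeyStats <- function(x) {
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  inlo <- x[x >= qs[1] - 1.5 * iqr]
  inhi <- x[x <= qs[3] + 1.5 * iqr]
  list(
    q1 = qs[1], median = qs[2], q3 = qs[3],
    whiskerLow = min(inlo), whiskerHigh = max(inhi),
    outliers = sort(x[x < qs[1] - 1.5 * iqr | x > qs[3] + 1.5 * iqr])
  )
}
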