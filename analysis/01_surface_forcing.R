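#!/usr/bin/env Rscript
# How the three field waveforms drive the obstacle surface.
#
# The field enters the medium only through the Neumann condition at the
# obstacle, so the instantaneous surface forcing n.E and its temporal
# extremum decide where waves can nucleate.  For the x-directed
# waveforms the extremum E0 sin(theta)|cos(az)| vanishes on the y-z
# great circle; the rotating field reaches E0 sin(theta) at every
# azimuth.  This table backs the claim that a circularly polarized
# field drives the whole equator as hard as a linear field drives its
# two best points.

library(scrollwave)

dir.create("results", showWarnings = FALSE)

E0 <- 2.0
theta <- seq(0, pi, length.out = 19)
az <- seq(0, 2 * pi, length.out = 25)[-25]
grid <- expand.grid(theta = theta, az = az)

specs <- list(PDCEF = field_spec("PDCEF", E0, 3.75, 0.1),
              ACEF = field_spec("ACEF", E0, 3.75),
              CPEF = field_spec("CPEF", E0, 3.75))

tab <- do.call(rbind, lapply(names(specs), function(k) {
  data.frame(kind = k, theta = grid$theta, az = grid$az,
             extremum = surface_forcing_extremum(specs[[k]], grid$theta,
                                                 grid$az))
}))
write.csv(tab, "results/surface_forcing_extrema.csv", row.names = FALSE)

eq <- subset(tab, abs(theta - pi / 2) < 1e-9)
cat("Surface-forcing extrema at the equator (E0 =", E0, "):\n")
for (k in names(specs)) {
  v <- eq$extremum[eq$kind == k]
  cat(sprintf("  %-5s min %.3f  mean %.3f  max %.3f\n",
              k, min(v), mean(v), max(v)))
}
cat("The rotating field holds the extremum at E0 everywhere on the\n")
cat("equator; the linear fields reach E0 only near az = 0 and pi.\n")
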