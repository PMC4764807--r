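#!/usr/bin/env Rscript
# Success region of scroll-wave removal in the (E0, omega_e) plane for
# the circularly polarized field.
#
# Long-running scan (the only driver in this set that takes hours at
# the full grid): one pinned reference state is reused across cells;
# each cell integrates until the filament leaves the success box or the
# 500-time-unit deadline passes.  The default here is a reduced 4 x 4
# grid; widen E0_list / omega_list for the full figure.

library(scrollwave)

dir.create("results", showWarnings = FALSE)

params <- model_params(grid = c(60, 60, 60))
domain <- build_phase_field(params, radius = 2.5)

E0_list <- c(1.0, 1.4, 1.8, 2.2, 2.6)
omega_list <- c(1.9, 2.0, 2.1, 2.2, 2.3)
t_limit <- 500

cat("Preparing the pinned scroll...\n")
pinned <- pinned_scroll_init(params, domain, relaxation_time = 30)

grid <- run_phase_diagram(E0_list, omega_list, params, domain, pinned,
                          t_limit = t_limit)
write.csv(grid, "results/phase_diagram.csv", row.names = FALSE)
print(attr(grid, "interval_width"))
cat("\nSuccess grid (rows E0, columns omega_e):\n")
print(with(grid, tapply(success, list(E0, omega_e), identity)))
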