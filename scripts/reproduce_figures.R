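#!/usr/bin/env Rscript

# Reproduces the reference phase portraits as data (CSV) and, if a plotting
# device is wanted, as PDFs: the classical closed orbit at a = 2, b = c = 1,
# d = 3 from (4, 1), and the hybrid orbits with the closed-form learning
# functional (eta = 1/4) from (4, 1) and from (0.1, 9). Starting with
# x0 << y0 reaches the asymptotic closed orbit much sooner than x0 > y0 —
# the hiding-learning phase delays effective predation. The comparison is
# qualitative: the reference figures print no trajectory coordinates.

suppressPackageStartupMessages(library(hybridlv))

out <- commandArgs(trailingOnly = TRUE)
out <- if (length(out) >= 1L) out[1L] else "figures_out"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (name in c("figure1", "figure2a", "figure2b")) {
  dest <- file.path(out, name)
  res <- run_from_config(example_config(name), out_dir = dest)
  ggplot2::ggsave(file.path(dest, "orbit.pdf"), ggplot2::autoplot(res),
                  width = 6, height = 5)
  gl <- hybridlv::glance(res)
  cat(sprintf("%s: final (x, y) = (%.4f, %.4f), H drift %.3g\n",
              name, gl$x_final, gl$y_final, gl$H_drift))
}

# quantify the delayed approach to the asymptotic orbit: H relative to its
# limiting level, late in each hybrid run
p <- lv_params(2, 1, 1, 3)
for (name in c("figure2a", "figure2b")) {
  orbit <- readr::read_csv(file.path(out, name, "macro.csv"),
                           show_col_types = FALSE)
  H <- lv_first_integral(orbit$x, orbit$y, p)
  late <- orbit$t >= 30
  cat(sprintf("%s: H span over t in [30, 40] = %.4g\n",
              name, diff(range(H[late]))))
}
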