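#!/usr/bin/env Rscript
# Stage 5 — microsphere-diameter statistics.
#
# Draws a synthetic diameter sample (truncated normal around 1600 nm, the
# published mean diameter scale), estimates its density with a
# Gaussian-kernel KDE at the Scott's-rule bandwidth, and computes box
# statistics with Tukey fences.  Also recomputes the published whisker
# endpoints directly from the published quartiles.

library(protospike)

dir.create("results", showWarnings = FALSE)

d <- sample_diameters(500L, mean = 1600, sd = 200, seed = 5L)
w <- scott_bandwidth(d)
est <- kde(d, bandwidth = w)
write.csv(data.frame(diameter_nm = est$grid, density = est$density),
          "results/diameter_kde.csv", row.names = FALSE)
cat(sprintf("diameter sample: n = %d, Scott bandwidth w = %.3f nm, KDE integral %.6f, mode %.0f nm\n",
            est$n, w, kde_integral(est), est$grid[which.max(est$density)]))

b <- box_stats(d)
print(b)
write.csv(data.frame(statistic = c("q1", "q2", "q3", "mean",
                                   "lower_fence", "upper_fence"),
                     value_nm = c(b$q1, b$q2, b$q3, b$mean,
                                  b$lower_fence, b$upper_fence)),
          "results/diameter_boxstats.csv", row.names = FALSE)

ref <- microsphere_boxstats_reference()
fences <- tukey_fences(ref[["q1"]], ref[["q3"]])
cat(sprintf("published quartiles %.2f / %.2f nm give fences %.2f / %.2f nm (published whiskers %.2f / %.2f)\n",
            ref[["q1"]], ref[["q3"]], fences[["lower"]], fences[["upper"]],
            ref[["lower_whisker"]], ref[["upper_whisker"]]))
cat(sprintf("published outlier %.4f nm lies %s the lower fence\n",
            ref[["outlier"]],
            if (ref[["outlier"]] < fences[["lower"]]) "below" else "above"))
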