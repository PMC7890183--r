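#!/usr/bin/env Rscript

# Step 4 — assemble the study report: pre/post group means with standard
# errors for every outcome, shaped like a pre/post outcome table, plus
# the test tables from steps 2 and 3 and a one-page summary figure.

suppressPackageStartupMessages(library(posturenet))

sem <- function(x) sd(x) / sqrt(length(x))

summarize <- function(df, cols, by) {
  agg <- stats::aggregate(df[cols], by = df[by], function(x)
    sprintf("%.3f ± %.3f", mean(x), sem(x)))
  agg[do.call(order, agg[by]), ]
}

beh <- read_metrics_tsv("results/behavioral_subject_metrics.tsv")
con <- read_metrics_tsv("results/connectome_subject_metrics.tsv")
beh_tests <- read_metrics_tsv("results/behavioral_tests.tsv")
con_tests <- read_metrics_tsv("results/connectome_tests.tsv")

out <- file("results/report.txt", "w")
w <- function(...) writeLines(c(...), out)

w("Synthetic balance-transfer cohort: pre/post outcomes",
  strrep("=", 52), "",
  "Sway metrics (group mean ± SE over subjects)")
beh_sum <- summarize(beh, c("rms_ap", "rms_ml", "cea", "mf_ap", "mf_ml",
                            "sampen_ap", "sampen_ml"),
                     c("group", "session"))
capture.output(print(beh_sum, row.names = FALSE), file = out, append = TRUE)

w("", "Behavioral statistics", strrep("-", 52))
w(format_study_table(beh_tests))

w("", "Spanning-tree integration metrics (group mean ± SE)")
con_sum <- summarize(con, c("diameter", "leaf_fraction", "avg_eccentricity",
                            "bc_max"),
                     c("group", "band", "session"))
capture.output(print(con_sum, row.names = FALSE), file = out, append = TRUE)

w("", "Connectome statistics", strrep("-", 52))
w(format_study_table(con_tests))
close(out)

# one summary figure: per-band session means of the four tree metrics
png("results/summary_figure.png", width = 1200, height = 800, res = 130)
op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
metrics <- c("diameter", "leaf_fraction", "avg_eccentricity", "bc_max")
for (m in metrics) {
  agg <- stats::aggregate(con[[m]],
                          by = con[c("group", "band", "session")], FUN = mean)
  agg$key <- paste(agg$group, agg$band, sep = ".")
  pre <- agg[agg$session == "pre", ]
  post <- agg[agg$session == "post", ][match(pre$key,
              agg[agg$session == "post", "key"]), ]
  rng <- range(c(pre$x, post$x))
  plot(seq_len(nrow(pre)), pre$x, pch = 1, ylim = rng, xaxt = "n",
       xlab = "", ylab = m, main = m)
  points(seq_len(nrow(pre)), post$x, pch = 16)
  axis(1, at = seq_len(nrow(pre)), labels = pre$key, las = 2, cex.axis = 0.7)
  legend("topright", pch = c(1, 16), legend = c("pre", "post"), bty = "n",
         cex = 0.8)
}
par(op)
invisible(dev.off())

cat("report written to results/report.txt, figure to results/summary_figure.png\n")
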