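#!/usr/bin/env Rscript
# Summaries and figures from the metric records of 03: grid summaries of
# SHD per (network, score), convergence calls, the structural-error
# decomposition for greedy vs exact, and an SHD-vs-N figure.

suppressPackageStartupMessages({
  library(bnrecover)
  library(ggplot2)
})

records <- utils::read.csv("results/metric_records.csv",
                           stringsAsFactors = FALSE)
records$error <- NA_character_  # read.csv turns the all-NA column to logical

# --- SHD summary across the size grid (min / mean / max / std) ---
summ <- summarize_shd(records)
utils::write.csv(summ, "results/shd_summary.csv", row.names = FALSE)
cat("SHD summaries (exact learner):\n")
print(summ[summ$learner == "exact", ], row.names = FALSE, digits = 3)

# --- convergence calls per (network, score, learner) ---
sizes <- sort(unique(records$size))
conv <- do.call(rbind, by(
  records, list(records$gold, records$score_label, records$learner),
  function(d) {
    series <- stats::aggregate(shd ~ size, d, mean)
    series <- series[order(series$size), ]
    r <- detect_convergence(series$shd, series$size)
    data.frame(gold = d$gold[1], score_label = d$score_label[1],
               learner = d$learner[1], converged = r$converged,
               at = if (is.na(r$at)) NA else r$at)
  }))
rownames(conv) <- NULL
utils::write.csv(conv, "results/convergence.csv", row.names = FALSE)
cat(sprintf("\n%d of %d (network, score, learner) series converged\n",
            sum(conv$converged), nrow(conv)))

# --- structural-error decomposition, greedy vs exact (MDL) ---
dec <- records[records$score_label == "MDL" &
                 records$size %in% c(200, 1000, 10000), ]
dec_agg <- stats::aggregate(
  cbind(add, delete, rev, mis, shd) ~ gold + learner + size, dec, mean)
utils::write.csv(dec_agg, "results/error_decomposition.csv",
                 row.names = FALSE)
cat("\nMDL structural-error decomposition (mean over replicates):\n")
print(dec_agg[order(dec_agg$gold, dec_agg$size, dec_agg$learner), ],
      row.names = FALSE, digits = 3)

# --- SHD vs N, one panel per network, exact learner ---
plot_scores <- c("MDL", "AIC", "fNML", "BDeu(alpha=1)",
                 "BDeu(alpha=100)")
pd <- records[records$learner == "exact" &
                records$score_label %in% plot_scores, ]
pd <- stats::aggregate(shd ~ gold + score_label + size, pd, mean)
p <- ggplot(pd, aes(size, shd, colour = score_label)) +
  geom_line() + geom_point(size = 0.8) +
  scale_x_log10() +
  facet_wrap(~gold, scales = "free_y") +
  labs(x = "sample size", y = "mean SHD to gold network",
       colour = "score") +
  theme_bw(base_size = 9)
ggsave("results/shd_vs_n.pdf", p, width = 8, height = 5)
cat("\nwrote results/shd_vs_n.pdf\n")
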