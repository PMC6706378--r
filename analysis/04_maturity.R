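#!/usr/bin/env Rscript
# Stage 4: age and length at independence and first reproduction.
#
# Binomial-logit fits of each status on minimum age (A50) and estimated
# total length (L50), per region, with 1,000-iteration bootstrap
# percentile intervals over individuals. First reproduction uses females
# only. Writes results/maturity.csv.

library(lasergrowth)

SEED <- 20193
rows <- list()

for (region in c("SW", "SB")) {
  records <- read.csv(file.path("results/data", region, "individuals.csv"))
  est <- read.csv(sprintf("results/estimates_%s.csv", region))
  for (outcome in c("independence", "first_reproduction")) {
    for (predictor in c("age", "length")) {
      res <- tryCatch(
        estimate_maturity(records, est, outcome, predictor,
                          n_iter = 1000, seed = SEED),
        error = function(e) {
          message(sprintf("%s %s/%s: refused (%s)", region, outcome,
                          predictor, conditionMessage(e)))
          NULL
        }
      )
      if (is.null(res)) next
      print(res)
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, outcome = outcome, predictor = predictor,
        x50 = res$x50, ci_lo = res$ci[1L], ci_hi = res$ci[2L],
        n_success = res$n_success, n_failure = res$n_failure,
        n_dropped = res$n_dropped)
    }
  }
}

write.csv(do.call(rbind, rows), "results/maturity.csv", row.names = FALSE)
message("wrote results/maturity.csv")
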