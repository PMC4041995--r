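#!/usr/bin/env Rscript
# In vivo efficacy arithmetic on a synthetic caliper series: weights
# from L x W^2 / 2, per-day %T/C from group medians, the optimal
# (minimum) %T/C, the 40% activity boundary, and per-day Student t
# comparisons. The series is labelled synthetic: raw animal data of the
# source experiments are not published.

source("analysis/00_config.R")

set.seed(XM_SEED)
days <- c(11, 14, 18, 22, 26)
# vehicle tumors grow ~exponentially; treatment bites hardest at day 22
vehicle <- do.call(rbind, lapply(days, function(d) {
  data.frame(animal_id = sprintf("v%02d", 1:10), group = "vehicle",
             day = d,
             length_mm = rlnorm(10, log(6) + 0.07 * (d - 11), 0.08),
             width_mm = rlnorm(10, log(5) + 0.06 * (d - 11), 0.08))
}))
inhibition <- c(0.75, 0.55, 0.35, 0.19, 0.30)  # treated/control ratio
treated <- do.call(rbind, lapply(seq_along(days), function(i) {
  d <- days[i]
  s <- inhibition[i]^(1 / 3)  # apply on the linear scale per axis
  data.frame(animal_id = sprintf("t%02d", 1:10), group = "treated",
             day = d,
             length_mm = s * rlnorm(10, log(6) + 0.07 * (d - 11), 0.08),
             width_mm = s * rlnorm(10, log(5) + 0.06 * (d - 11), 0.08))
}))
meas <- rbind(vehicle, treated)
meas$weight_mg <- caliper_to_weight(meas$length_mm, meas$width_mm)

res <- percent_tc(meas)
print(res)
message(sprintf("optimal %%T/C %.1f on day %d -> %s",
                res$optimal_percent_tc,
                res$per_day$day[which.min(res$per_day$percent_tc)],
                activity_call(res$optimal_percent_tc)))
write_tsv(res$per_day, "efficacy_per_day.tsv")
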