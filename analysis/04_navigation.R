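#!/usr/bin/env Rscript
# Score the example triangle-completion trials: turn (angle) error at the
# final vertex and path-length (distance) error against the ideal homing
# segment, averaged over the four-trial protocol.

library(posturenav)

trials <- read_triangle_csv("results/example_triangles.csv")
scores <- lapply(trials, score_trial)
tab <- do.call(rbind, lapply(seq_along(trials), function(i) {
  s <- scores[[i]]
  data.frame(trial = i, triangle = trials[[i]]$triangle_id,
             direction = trials[[i]]$direction,
             angle_error_deg = s$angle_error,
             distance_error_cm = s$distance_error,
             endpoint_miss_cm = s$endpoint_miss)
}))
print(tab, digits = 3)
m <- summarize_trials(scores)
cat(sprintf("Mean angle error %.1f deg, mean distance error %.1f cm\n",
            m[["mean_angle_error"]], m[["mean_distance_error"]]))
write.csv(tab, "results/triangle_scores.csv", row.names = FALSE)
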