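#!/usr/bin/env Rscript
# Stage 2: behavioral measures. From the illustrative trajectories, compute
# body-length-normalized speed, tank-mean activity and thigmotaxis; from
# the full activity design, fit the Weibull freeze-recovery curve per
# aquarium-day and extract freezing intensity and time to freeze.

suppressPackageStartupMessages(library(stressphen))

data_dir <- "results/data"
out_dir <- "results/behavior"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

## kinematics on the stored trajectories
frames <- utils::read.csv(file.path(data_dir, "trajectories.csv"))
lengths <- utils::read.csv(file.path(data_dir, "body_lengths.csv"))
units <- unique(frames[c("trial", "aquarium", "zone", "day")])
trajs <- lapply(seq_len(nrow(units)), function(i) {
  u <- units[i, ]
  d <- merge(frames, u)
  trajectory(d[c("fish_id", "time_s", "x_cm", "y_cm")],
             lengths[lengths$fish_id %in% d$fish_id, ],
             tank_width_cm = 40, tank_height_cm = 25,
             aquarium = u$aquarium, zone = u$zone, trial = u$trial,
             day = u$day)
})
thig <- do.call(rbind, lapply(trajs, function(tr) {
  th <- thigmotaxis(tr, window = c(0, 60))
  data.frame(trial = tr$trial, aquarium = tr$aquarium, zone = tr$zone,
             day = tr$day, mean_dist_cm = th$mean_dist_cm)
}))
message("thigmotaxis (pre-stress window), by zone:")
print(tapply(thig$mean_dist_cm, thig$zone, mean))
utils::write.csv(thig, file.path(out_dir, "thigmotaxis.csv"),
                 row.names = FALSE)

## freeze-curve fits on the full activity design
act <- utils::read.csv(file.path(data_dir, "activity.csv"))
units <- unique(act[c("trial", "aquarium", "zone", "day")])
fits <- lapply(seq_len(nrow(units)), function(i) {
  u <- units[i, ]
  d <- merge(act, u)
  d <- d[order(d$time_s), ]
  s <- activity_series(d$time_s, d$speed_blps, aquarium = u$aquarium,
                       day = u$day, zone = u$zone, trial = u$trial)
  nls_fit(s, skip_s = 10)
})
feat <- fits_to_table(fits)
utils::write.csv(feat, file.path(out_dir, "freeze_fits.csv"),
                 row.names = FALSE)
message(sprintf("fitted %d aquarium-days (%d converged); mean freezing intensity CZ %.1f vs TZ %.1f %%BL/s",
                nrow(feat), sum(feat$converged),
                mean(feat$freezing_intensity[feat$zone == "CZ"]),
                mean(feat$freezing_intensity[feat$zone == "TZ"])))
message("wrote ", out_dir, "/{thigmotaxis,freeze_fits}.csv")
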