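#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study. Two trials (June: 4 aquaria/zone,
# August: 6 aquaria/zone), 17 fish per aquarium, five experimental days of
# filming, cortisol sampled at baseline and 0.5/1.5/2.5/3.5 h post-stress,
# and a three-trial qPCR panel (5 fish per zone and trial).
#
# Full-length trajectories are heavy, so this driver simulates positions
# for a single illustrative aquarium-day per zone and uses the
# distribution-identical activity-level simulator for the full behavioral
# design (see the methods vignette).

suppressPackageStartupMessages(library(stressphen))

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

## illustrative trajectories: one aquarium-day per zone, 2 min of video
traj_cfg <- sim_config(seed = 101, n_aquaria_per_zone = 1, n_days = 1,
                       duration_s = 120, stress_time_s = 60)
trajs <- simulate_trajectories(traj_cfg, trial = "June")
message("simulated ", length(trajs), " illustrative trajectories (",
        format(sum(vapply(trajs, function(t) nrow(t$frames), numeric(1))),
               big.mark = ","), " position rows)")

## full behavioral design at the activity level, both trials
acts_june <- simulate_activity(
  sim_config(seed = 102, n_aquaria_per_zone = 4), trial = "June")
acts_aug <- simulate_activity(
  sim_config(seed = 103, n_aquaria_per_zone = 6), trial = "August")
acts <- c(acts_june, acts_aug)
act_tab <- do.call(rbind, lapply(acts, function(a) {
  u <- attr(a, "unit")
  data.frame(trial = u$trial, aquarium = paste(u$trial, u$aquarium, sep = "_"),
             zone = u$zone, day = u$day, time_s = a$time_s,
             speed_blps = a$speed_blps)
}))
message("activity series: ", length(acts), " aquarium-days, ",
        nrow(act_tab), " rows")

## cortisol (one sampling day per trial) and qPCR (three trials)
cort <- rbind(simulate_cortisol(cortisol_truth(), 4, 1, seed = 104),
              transform(simulate_cortisol(cortisol_truth(), 6, 1,
                                          seed = 105), trial = "August"))
qpcr <- simulate_expression(expression_truth(), 5, 3, seed = 106)

write_simulation(out_dir, trajs = trajs, cortisol = cort, qpcr = qpcr,
                 config = list(seed = c(101:106),
                               design = "June 4 + August 6 aquaria/zone, 17 fish, 5 days"))
utils::write.csv(act_tab, file.path(out_dir, "activity.csv"),
                 row.names = FALSE)
message("wrote ", out_dir, "/{trajectories,body_lengths,activity,cortisol,qpcr}.csv")
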