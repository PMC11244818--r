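#!/usr/bin/env Rscript
# Full-scale reference protocol on the standard 1000-neuron network:
# 10 simulated minutes of training (Q = 10 stimuli, one presentation every
# 2 s, 500 ms each), then 10 simulated minutes of ongoing activity with
# plasticity on. Writes the weight-class trajectories, the state-duration
# statistics of the ongoing epoch, and the spike tables. Expect tens of
# minutes of compute on one CPU.
#
# Usage: Rscript scripts/reproduce_basic.R [--seed INT] [--out-dir DIR]

suppressPackageStartupMessages({
  library(plastnet)
  library(optparse)
  library(readr)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out-dir", type = "character", default = "results/basic",
              dest = "out_dir")
)))
dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- network_config(seed = opts$seed)  # 800 E / 200 I, Q = 10, f = 0.1
net <- build_network(cfg)
message("training (10 simulated minutes) ...")
sched <- training_schedule(net$clusters, amplitude = cfg$h_st,
                           seed = substream_seed(cfg$seed, "schedule"))
tr <- run_session(net, sched, class_interval_ms = 1000,
                  snapshot_times = seq(60000, 600000, by = 60000))
write_spike_table(tr, file.path(opts$out_dir, "spikes_training.tsv"))
write_csv(tr$class_series, file.path(opts$out_dir, "class_series_training.csv"))

message("ongoing activity (10 simulated minutes) ...")
og <- run_session(tr$network, empty_schedule(600000), resume = tr,
                  class_interval_ms = 1000,
                  snapshot_times = seq(660000, 1200000, by = 60000))
write_spike_table(og, file.path(opts$out_dir, "spikes_ongoing.tsv"))
write_csv(og$class_series, file.path(opts$out_dir, "class_series_ongoing.csv"))
write_weights(og$network, file.path(opts$out_dir, "weights_final.tsv"),
              time_ms = og$t_end)

message("analysis ...")
ov <- overlap_series(og$spikes, net$clusters, og$t0, og$t_end)
states <- detect_states(ov)
write_csv(states, file.path(opts$out_dir, "state_segments.csv"))
ds <- duration_stats(states)
wc <- mean_weights_by_class(og$network)
wm <- weight_moments(og)
write_csv(wm, file.path(opts$out_dir, "intracluster_weight_moments.csv"))

report <- list(
  seed = opts$seed,
  post_training = as.list(mean_weights_by_class(tr$network)),
  final = as.list(wc),
  duration_stats = as.list(ds))
jsonlite::write_json(report, file.path(opts$out_dir, "report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf(paste0(
  "post-training:  w1 = %.3f mV, w0 = %.4f mV\n",
  "after ongoing:  w1 = %.3f mV, w0 = %.4f mV\n",
  "states: %d segments, mean %.0f ms, sd/mean %.2f\n"),
  report$post_training$w1, report$post_training$w0, wc$w1, wc$w0,
  ds$n_segments, ds$mean_ms, ds$cv))
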