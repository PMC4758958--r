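# Small hand-built dataset used by the fast unit tests: 2 blocks x 3 trials,
# alternating cue, 2 standards + 1 target per trial, 4 units (2 per
# hemisphere). Counts are drawn once with a fixed seed.
tiny_dataset <- function(seed = 1) {
  set.seed(seed)
  n_trials <- 6
  cue <- rep(c("L", "R"), each = 3)
  pres <- do.call(rbind, lapply(seq_len(n_trials), function(i) {
    data.frame(trial_id = i, block_id = (i - 1) %/% 3 + 1, cue_side = cue[i],
               within_trial_index = 0:2,
               is_standard = c(TRUE, TRUE, FALSE))
  }))
  pres$presentation_id <- seq_len(nrow(pres))
  pres$timestamp_s <- seq_len(nrow(pres)) * 0.5
  units <- data.frame(unit_id = c("a", "b", "c", "d"),
                      hemisphere = c("L", "L", "R", "R"))
  counts <- matrix(rpois(nrow(pres) * 4, 5), nrow(pres), 4)
  trials <- data.frame(trial_id = seq_len(n_trials),
                       outcome = rep(c("hit", "miss"), 3),
                       target_side = rep(c("cued", "opposite"), 3),
                       delta_theta_deg = rep(c(4, 12), 3),
                       rewarded = rep(c(TRUE, FALSE), 3))
  popgain_dataset(counts, pres, units, trials)
}
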