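# In-code fixtures: published peak-table values used as inputs, plus
# noiseless constructions with known closed-form answers.

# five replicate injections of the validated assay (suitability table)
suitability_injections <- function() {
  data.frame(
    injection_id = 1:5,
    rt_min = c(2.423, 2.430, 2.429, 2.428, 2.423),
    area = c(56048, 56025, 55648, 55929, 55887),
    tailing = rep(1, 5),
    plates = c(13002, 12925, 12866, 12824, 12973)
  )
}

# triplicate responses at the extreme calibration levels
extreme_level_responses <- function() {
  list(low = c(643, 620, 633), high = c(177307, 173466, 184125))
}

# replicated points exactly on a known line
exact_line_data <- function(slope = 2, intercept = 0,
                            levels = c(1, 2, 3), reps = 3) {
  conc <- rep(levels, each = reps)
  calibration_data(conc, intercept + slope * conc,
                   replicate = rep(seq_len(reps), times = length(levels)))
}

# closed-form solution of the 2x2 weighted normal equations; independent
# of the lm-based fitting path
wls_oracle <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  list(intercept = (sxx * sy - sx * sxy) / det,
       slope = (sw * sxy - sx * sy) / det)
}
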