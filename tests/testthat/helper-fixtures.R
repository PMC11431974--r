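# Shared fixture builders; everything is generated in code.

# small 3-lead recording with known values
tiny_recording <- function(fs = 1000, n = 4) {
  samples <- rbind(
    I = seq_len(n) / 100,
    II = -seq_len(n) / 200,
    V1 = rep(0.05, n)
  )
  ecg_recording(samples, fs, adc_bits = 16L, adc_range_mv = 10,
                source_id = "tiny")
}

# a single triangular wave on a flat baseline; returns list(x, onset, apex,
# offset) with 0-based indices
triangle_signal <- function(n = 1200, onset = 500, duration = 120,
                            amp = 0.2, fs = 1000) {
  x <- numeric(n)
  m <- duration
  tri <- amp * (1 - abs(2 * (0:m) / m - 1))
  x[(onset + 1):(onset + m + 1)] <- tri
  list(x = x, onset = onset, apex = onset + m %/% 2, offset = onset + m)
}

# default synthetic spec scaled for test runtime
test_spec <- function(seed = 1, duration_s = 25, ...) {
  synthetic_spec(duration_s = duration_s, seed = seed, ...)
}

# mean absolute onset/offset recovery error (ms at fs 1000) of a delineation
# run against generator truth
recovery_errors <- function(gen, del) {
  u <- del$beats[del$beats$used, ]
  tr <- as.data.frame(gen$truth$annotations)
  on <- tr[tr$kind == "P_ONSET", c("lead", "beat", "sample")]
  names(on)[3] <- "true_on"
  of <- tr[tr$kind == "P_OFFSET", c("lead", "beat", "sample")]
  names(of)[3] <- "true_off"
  m <- merge(merge(u, on, by = c("lead", "beat")), of, by = c("lead", "beat"))
  fs <- 1000
  c(onset = mean(abs(m$p_onset - m$true_on)) / fs * 1000,
    offset = mean(abs(m$p_offset - m$true_off)) / fs * 1000,
    n = nrow(m))
}
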