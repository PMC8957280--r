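# Shared fixtures, all built in code.

make_sine <- function(freq_hz, rate_hz, duration_s, amplitude = 1, phase = 0) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  raw_signal(amplitude * sin(2 * pi * freq_hz * t + phase), rate_hz)
}

# Raised 1 Hz sine: one crest per second, full 0-100 swing after scaling.
make_raised_sine <- function(duration_s = 10, rate_hz = 100) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  50 + 50 * sin(2 * pi * t - pi / 2)
}

rms <- function(x) sqrt(mean(x^2))

# Signed magnitude response implied by comparing output to input RMS.
relative_rms <- function(out_sig, in_sig) rms(out_sig$samples) / rms(in_sig$samples)
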