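# Independent oracles and small fixture builders shared across tests.

# Exhaustive pairwise Mann-Whitney concordance of marker vs. binary status,
# ties counted 1/2.  Deliberately a plain double comparison, independent of
# the nearest-neighbour code path.
concordance_oracle <- function(marker, y) {
  m1 <- marker[y == 1]
  m0 <- marker[y == 0]
  cmp <- outer(m1, m0, ">") + 0.5 * outer(m1, m0, "==")
  mean(cmp)
}

# Riemann integral of an analytic function f (of time in ms) at 10x the
# native sampling rate; oracle for the trapezoidal integrators.
riemann_oracle <- function(f, t0_ms, t1_ms, fs) {
  dt <- 1000 / fs / 10
  tt <- seq(t0_ms, t1_ms, by = dt)
  mid <- (f(tt[-1]) + f(tt[-length(tt)])) / 2
  sum(mid) * dt
}

# Hand-built median beat from analytic component functions (of time in ms).
make_beat <- function(fx, fy, fz, fs = 500, dur_ms = 600,
                      qrs_onset_ms = 100, qrs_offset_ms = 200,
                      t_offset_ms = 450) {
  t_ms <- seq(0, dur_ms, by = 1000 / fs)
  structure(list(x = fx(t_ms), y = fy(t_ms), z = fz(t_ms), fs = fs,
                 r_peak = round((qrs_onset_ms + qrs_offset_ms) / 2 * fs / 1000) + 1L,
                 qrs_onset = round(qrs_onset_ms * fs / 1000) + 1L,
                 qrs_offset = round(qrs_offset_ms * fs / 1000) + 1L,
                 t_offset = round(t_offset_ms * fs / 1000) + 1L,
                 origin = c(0, 0, 0), n_beats_used = 1L, rr_median = 1000),
            class = "median_beat_xyz")
}

# Small clean synthetic record used by several tests.
quick_record <- function(...) {
  gehroc::generate_ecg12(gehroc::ecg_gen_params(...))
}
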