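# Small builders shared across test files. All fixtures are generated in
# code; no data files.

# quiet multichannel traces with gravity along a pitched sensor axis
quiet_traces <- function(n = 500, fs = 220, pitch_deg = 0) {
  ax <- c(0, sin(pitch_deg * pi / 180), cos(pitch_deg * pi / 180))
  trace_set(gyro = matrix(0, n, 3),
            linacc = matrix(rep(9.81 * ax, each = n), ncol = 3),
            eye_h = numeric(n), eye_v = numeric(n),
            photodiode = numeric(n), fs = fs)
}

# a minimal valid session with no trials
quiet_session <- function(n = 500, fs = 220) {
  session_recording(quiet_traces(n, fs))
}

# raised-cosine velocity bump embedded in a longer trace; returns the
# series plus the analytic landmarks
rc_bump <- function(V = 200, A = 4000, fs = 220, lead = 220, direction = 1) {
  T_dur <- pi * V / A
  m <- floor(T_dur * fs)
  tt <- (0:m) / fs
  v <- direction * (V / 2) * (1 - cos(2 * pi * tt / T_dur))
  series <- c(numeric(lead), v, numeric(lead))
  list(v = series, T = T_dur, V = V, A = A, fs = fs,
       t_start = lead / fs, t_peak_acc = lead / fs + T_dur / 4,
       t_peak_vel = lead / fs + T_dur / 2)
}

# random 3x3 rotation matrix (via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
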