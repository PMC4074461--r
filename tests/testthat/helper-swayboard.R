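# shared fixtures and independent oracles

# sinusoid trajectory on the x axis
sinusoid_traj <- function(freq, fs = 50, duration = 10, amplitude = 1) {
  t <- seq(0, duration, by = 1 / fs)
  cop_trajectory(amplitude * sin(2 * pi * freq * t), rep(0, length(t)),
                 fs = fs, t = t)
}

# steady-state amplitude over the middle third of a series (RMS * sqrt(2))
amp_mid <- function(v) {
  n <- length(v)
  m <- v[floor(n / 3):ceiling(2 * n / 3)]
  sqrt(2 * mean((m - mean(m))^2))
}

# independent ANOVA mean squares via aov(), for the ICC oracle
aov_ms <- function(m) {
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                  meas = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subj + meas, data = d))[[1]]
  list(msr = tab["subj", "Mean Sq"], msc = tab["meas", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"], n = nrow(m), k = ncol(m))
}

# brute-force ICC from aov mean squares (McGraw-Wong definitions)
oracle_icc <- function(m, definition) {
  ms <- aov_ms(m)
  n <- ms$n; k <- ms$k
  if (definition == "consistency")
    (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
  else
    (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
}

# lean two-session board-only design for Monte-Carlo work
two_session_design <- function(n, sigma_subject = 7, sigma_session = 1,
                               sigma_error = sqrt(7.64706), seed = NULL) {
  study_design(n_subjects = n,
               tasks = data.frame(task = "STOE", duration_s = 30,
                                  mean_pl_cm = 36, stringsAsFactors = FALSE),
               n_trials = 1, sessions = c("A1", "B"),
               platform_sessions = character(0),
               sigma_subject = sigma_subject, sigma_session = sigma_session,
               sigma_error = sigma_error, seed = seed)
}

# ratings matrix of one simulated two-session study
two_session_matrix <- function(design) {
  trials <- simulate_study(design)
  ratings_matrix(summarize_trials(trials), "STOE", "pl_cm", c("A1", "B"))
}
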