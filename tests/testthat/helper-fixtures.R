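# Shared fixtures: everything is generated in code, no stored data.

tiny_rois <- function() default_roi_set()

# Small two-condition ROI study; warnings about single-subject groups are
# expected for some configurations and silenced here.
quiet_sim <- function(...) {
  suppressWarnings(simulate_roi_timeseries(...))
}

# Minimal hand-built state_model for frequency/transition unit tests.
fake_model <- function(labels, subject, k) {
  m <- structure(list(k = k, labels = labels, subject = subject,
                      group = rep(NA_character_, length(labels))),
                 class = "state_model")
  m$frequencies <- state_frequencies(m)
  m$transition <- transition_matrices(m)
  m
}

# Brute-force Benjamini-Hochberg step-up, written from the definition:
# largest k with p_(k) <= k/m * alpha is the rejection cutoff.
bh_brute_force <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= (seq_len(m) / m) * alpha)
  reject <- logical(m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}

# From-definition Kendall's W (independent of the package implementation):
# explicit rank sums, explicit tie terms.
kendalls_w_definition <- function(scores, tie_correction = TRUE) {
  m <- nrow(scores); n <- ncol(scores)
  R <- matrix(0, m, n)
  Tsum <- 0
  for (i in seq_len(m)) {
    R[i, ] <- rank(scores[i, ])
    tt <- table(R[i, ])
    if (tie_correction) Tsum <- Tsum + sum(tt^3 - tt)
  }
  Rj <- colSums(R)
  S <- sum((Rj - mean(Rj))^2)
  12 * S / (m^2 * (n^3 - n) - m * Tsum)
}

# Random connected-or-not binary graph on n nodes.
random_adjacency <- function(n, p = NULL) {
  if (is.null(p)) p <- stats::runif(1, 0.05, 0.6)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}
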