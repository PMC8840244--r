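# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# O(n^2) local-maximum finder straight from the definition: a strict local
# maximum, with a plateau contributing its first sample; prominence by
# explicit scan to the nearest strictly higher sample on each side.
brute_peaks <- function(x) {
  n <- length(x)
  idx <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] <= x[i - 1]) next # rises strictly (plateau: first sample only)
    k <- i + 1
    while (k <= n && x[k] == x[i]) k <- k + 1 # skip the plateau
    if (k <= n && x[k] < x[i]) idx <- c(idx, i)
  }
  prom <- vapply(idx, function(p) {
    lo <- p
    while (lo > 1 && x[lo - 1] <= x[p]) lo <- lo - 1
    hi <- p
    while (hi < n && x[hi + 1] <= x[p]) hi <- hi + 1
    x[p] - max(min(x[lo:p]), min(x[p:hi]))
  }, 1.0)
  list(index = idx, prominence = prom)
}

# brute-force BHS grading by explicit counting against the threshold table
brute_bhs <- function(err) {
  p5 <- 100 * sum(abs(err) <= 5) / length(err)
  p10 <- 100 * sum(abs(err) <= 10) / length(err)
  p15 <- 100 * sum(abs(err) <= 15) / length(err)
  grade <- if (p5 >= 60 && p10 >= 85 && p15 >= 95) "A"
           else if (p5 >= 50 && p10 >= 75 && p15 >= 90) "B"
           else if (p5 >= 40 && p10 >= 65 && p15 >= 85) "C"
           else "D"
  list(pct = c(p5, p10, p15), grade = grade)
}

# hand-rolled sample Pearson correlation (sum formula)
brute_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# small clean synthetic cohort shared by several files (cached per session)
.fixture_env <- new.env()
clean_cohort <- function(n = 40, seed = 404) {
  key <- sprintf("clean_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_segments(
      synth_config(n_records = n, seed = seed))
  }
  .fixture_env[[key]]
}

# a beat-periodic pulse train with known clean reference
pulse_train <- function(n = 1024, beat = 90, fs = 125) {
  ph <- ((seq_len(n) - 1) %% beat) / beat
  exp(-(ph - 0.3)^2 / (2 * 0.08^2))
}
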