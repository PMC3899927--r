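# Fixture builders and independent brute-force oracles used across tests.

random_es <- function(n = 50, m1 = 4, m2 = 4, seed = 1, sd = 1, mean = 8) {
  set.seed(seed)
  vals <- matrix(rnorm(n * (m1 + m2), mean = mean, sd = sd), nrow = n,
                 dimnames = list(paste0("g", seq_len(n)),
                                 paste0("s", seq_len(m1 + m2))))
  expression_set(vals, control = seq_len(m1), test = m1 + seq_len(m2))
}

# midrank oracle: count-based definition, independent of base::rank
brute_midranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# trimmed mean oracle: sort, slice, mean
brute_trimmed_mean <- function(x, trim) {
  g <- floor(length(x) * trim)
  s <- sort(x)
  mean(s[(g + 1):(length(x) - g)])
}

# trapezoidal ROC integration oracle for AUC
trapezoid_auc <- function(score, truth) {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  npos <- sum(truth); nneg <- sum(!truth)
  tpr <- vapply(thr, function(t) sum(score[truth] >= t) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(score[!truth] >= t) / nneg, numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
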