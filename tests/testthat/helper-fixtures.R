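# Builders for small trial tables used across the tests.

# one participant's worth of trials with controllable correctness/RTs
make_trials <- function(n = 80, participant = "P1", rt = NULL,
                        correct = NULL, set_size = NULL, target = NULL) {
  if (is.null(rt)) rt <- rep(1, n)
  if (is.null(correct)) correct <- rep(1L, n)
  if (is.null(set_size)) set_size <- rep(c(4L, 16L, 24L), length.out = n)
  if (is.null(target)) target <- rep(c("ab", "p"), length.out = n)
  data.frame(participant_id = participant, group = "c", gender = "f",
             age = 10, nystagmus = 0L, acuity_logmar = 0,
             set_size = set_size, target = target, rt_s = rt,
             correct = correct, order = seq_len(n),
             stringsAsFactors = FALSE)
}

# O(n^2) pair-counting Kendall tau-b, coded independently of the package
kendall_bruteforce <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
    if (sx * sy > 0) C <- C + 1
    if (sx * sy < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) sum(sapply(table(v), function(t) t * (t - 1) / 2))
  (C - D) / sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
}

# closed-form Gaussian ML log-likelihood of a sample
norm_ml_loglik <- function(v) {
  n <- length(v)
  s2 <- mean((v - mean(v))^2)
  -n / 2 * (log(2 * pi * s2) + 1)
}
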