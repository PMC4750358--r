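# Independent brute-force oracles: element-wise loops and algebraically
# different formula arrangements than the package internals.

brute_fixed <- function(y, se) {
  sw <- 0; swy <- 0
  for (i in seq_along(y)) {
    w <- 1 / (se[i] * se[i])
    sw <- sw + w
    swy <- swy + w * y[i]
  }
  list(y = swy / sw, se = sqrt(1 / sw))
}

# Q via the computational formula sum(w y^2) - (sum(w y))^2 / sum(w)
brute_q <- function(y, se) {
  sw <- 0; swy <- 0; swy2 <- 0
  for (i in seq_along(y)) {
    w <- 1 / (se[i] * se[i])
    sw <- sw + w
    swy <- swy + w * y[i]
    swy2 <- swy2 + w * y[i] * y[i]
  }
  swy2 - swy * swy / sw
}

brute_tau2 <- function(y, se) {
  sw <- 0; sw2 <- 0
  for (i in seq_along(y)) {
    w <- 1 / (se[i] * se[i])
    sw <- sw + w
    sw2 <- sw2 + w * w
  }
  max(0, (brute_q(y, se) - (length(y) - 1)) / (sw - sw2 / sw))
}

brute_random <- function(y, se) {
  t2 <- brute_tau2(y, se)
  sw <- 0; swy <- 0
  for (i in seq_along(y)) {
    w <- 1 / (se[i] * se[i] + t2)
    sw <- sw + w
    swy <- swy + w * y[i]
  }
  list(y = swy / sw, se = sqrt(1 / sw), tau2 = t2)
}

# Kendall S by explicit pair enumeration
brute_kendall_s <- function(a, b) {
  s <- 0
  n <- length(a)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(a[j] - a[i]) * sign(b[j] - b[i])
    }
  }
  s
}

random_estimates <- function(k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(y = stats::rnorm(k, 0, 0.6),
       se = stats::runif(k, 0.05, 0.8))
}

fixture_effects <- function(snp = NULL, aggregate = TRUE) {
  studies <- read_study_table(snpmeta_fixture())
  if (!is.null(snp)) studies <- studies[studies$snp_id == snp, ]
  ef <- study_effects(studies)
  if (aggregate) ef <- suppressMessages(aggregate_shared_controls(ef))
  ef
}
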