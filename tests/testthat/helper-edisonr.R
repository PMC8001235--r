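# fixtures and independent oracles used across test files

# small cohort used by several files
tiny_config <- function(seed = 1, ...) {
  args <- modifyList(list(n_samples = 80, n_probes = 120,
                          n_informative_probes = 20, seed = seed), list(...))
  do.call(sim_config, args)
}

# exhaustive pair-counting AUC oracle (ties count one half)
auc_pair_oracle <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# planted-signal design: one feature tracking the labels plus pure noise
make_planted <- function(n = 200, n_noise = 50, noise_sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * (n_noise + 1)), n, n_noise + 1)
    x[, 1] <- y + rnorm(n, 0, noise_sd)
    colnames(x) <- c("signal", paste0("noise", seq_len(n_noise)))
    list(x = x, y = y)
  })
}

# survival frame with a binary group and exponential hazards
make_survival <- function(n, hr_group1 = 1, baseline = 0.01,
                          censor_rate = 0.003, seed = 1) {
  withr::with_seed(seed, {
    group <- rep(c(0L, 1L), length.out = n)
    rate <- baseline * ifelse(group == 1, hr_group1, 1)
    t_event <- rexp(n, rate)
    t_cens <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
    tibble::tibble(time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens),
                   group = group)
  })
}
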