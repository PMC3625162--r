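# Independent oracles and fixture builders shared across the suite.

# Exact Mann-Whitney p by full enumeration of the C(m+n, m) ways of
# assigning the pooled values to group a (valid when there are no ties).
enumerate_mw_p <- function(a, b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  pooled <- c(a, b)
  m <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  idx <- utils::combn(length(pooled), m)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  switch(alternative,
         less = p_le, greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Two-sided Fisher p by hypergeometric enumeration: sum of probabilities
# of all tables with the observed margins no more probable than observed.
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(xs, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# geNorm M by direct evaluation of its definition.
direct_genorm_m <- function(expr) {
  n <- nrow(expr)
  vapply(seq_len(n), function(j) {
    mean(vapply(setdiff(seq_len(n), j),
                function(k) sd(expr[j, ] - expr[k, ]), numeric(1)))
  }, numeric(1))
}

# Random Ct matrix with a given card structure and non-detect load.
random_ct <- function(n_assays = 20, n_cards = 4, samples_per_card = 3,
                      nondetect_frac = 0.05, seed = 1) {
  set.seed(seed)
  n_samples <- n_cards * samples_per_card
  values <- matrix(runif(n_assays * n_samples, 18, 34), n_assays,
                   dimnames = list(sprintf("a%02d", seq_len(n_assays)),
                                   sprintf("s%02d", seq_len(n_samples))))
  colnames(values) <- sprintf("s%02d", seq_len(n_samples))
  if (nondetect_frac > 0) {
    drop <- sample(length(values), ceiling(nondetect_frac * length(values)))
    values[drop] <- NA_real_
  }
  # guarantee every card keeps at least one present value
  card <- setNames(rep(sprintf("c%02d", seq_len(n_cards)),
                       each = samples_per_card), colnames(values))
  for (cd in unique(card)) {
    block <- values[, card == cd, drop = FALSE]
    if (all(is.na(block))) values[1, which(card == cd)[1]] <- 25
  }
  ct_matrix(values, card = card)
}

geo_mean <- function(x) exp(mean(log(x)))
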