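# Independent brute-force oracles used to pin down expected values.

# Hypergeometric enumeration for a 2x2 table with fixed margins, built from
# choose() only. Returns two-sided (minimum-likelihood) and one-sided tails.
fisher_oracle <- function(tab, sided = "two") {
  tab <- as.matrix(tab)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_obs <- tab[1, 1]
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- vapply(a_range, function(a)
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1), numeric(1))
  p_obs <- prob[a_range == a_obs]
  switch(sided,
         two = sum(prob[prob <= p_obs * (1 + 1e-7)]),
         one_greater = sum(prob[a_range >= a_obs]),
         one_less = sum(prob[a_range <= a_obs]))
}

# Exhaustive single-origin parsimony scoring over a ladder where every
# outgroup forms its own split. Pattern: character vector of calls ordered
# root to tip (split indices 0..S-1). For each candidate origin branch, the
# expected staircase is "absent before the origin, present from it on"; an
# observed present where the staircase expects absent would need a second
# gain and is disallowed; an observed absent where it expects present is one
# loss; missing matches anything. Minimum total cost wins, ties to the
# older branch.
parsimony_oracle <- function(pattern) {
  S <- length(pattern)
  cost <- vapply(0:S, function(b) {
    expected <- c(rep("absent", b), rep("present", S - b))
    cst <- 0
    for (i in seq_len(S)) {
      if (pattern[i] == "missing") next
      if (pattern[i] == "present" && expected[i] == "absent") return(Inf)
      if (pattern[i] == "absent" && expected[i] == "present") cst <- cst + 1
    }
    cst
  }, numeric(1))
  which.min(cost) - 1L   # which.min takes the first (oldest) minimum
}

# All-subsets enumeration of the rank-sum distribution (no ties), for the
# one-sided alternative that x is stochastically larger.
wilcoxon_oracle_greater <- function(x, y) {
  n <- length(x); pooled <- c(x, y)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(n)])
  splits <- utils::combn(length(pooled), n)
  sums <- apply(splits, 2, function(idx) sum(ranks[idx]))
  mean(sums >= obs)
}

# Tiny ladder used across dating tests: five single-species outgroup splits.
toy_ladder <- function(S = 5) {
  branch_ladder(as.list(paste0("sp", seq_len(S))),
                split_ages = seq(500 - 50, by = -70, length.out = S),
                focal = "focal")
}

# Evidence row named by ladder species.
make_calls <- function(ladder, pattern) {
  stats::setNames(pattern, ladder$species)
}
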