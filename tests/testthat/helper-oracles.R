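# Independent oracles, kept free of the package's cohort recursion.

# Expected cost/QALY by explicit enumeration of every state path over k
# cycles (3^k paths), crediting the start-of-cycle state each cycle.
path_enumeration_oracle <- function(P, utilities, state_costs, k,
                                    initial = "W", cycles_per_year = 52) {
  st <- c("W", "S", "A")
  u <- utilities[st]; cs <- state_costs[st]
  paths <- as.matrix(expand.grid(rep(list(1:3), k + 1)))
  start <- match(initial, st)
  total_q <- 0; total_c <- 0
  for (i in seq_len(nrow(paths))) {
    pth <- paths[i, ]
    if (pth[1] != start) next
    pr <- 1
    for (t in seq_len(k)) pr <- pr * P[pth[t], pth[t + 1]]
    if (pr == 0) next
    occupied <- pth[seq_len(k)]  # state during cycle t
    total_q <- total_q + pr * sum(u[occupied]) / cycles_per_year
    total_c <- total_c + pr * sum(cs[occupied])
  }
  list(qaly = total_q, cost = total_c)
}

# Stationary distribution via the left eigenvector.
stationary_oracle <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# Random row-stochastic 3x3 matrix.
random_stochastic_matrix <- function() {
  P <- matrix(stats::rgamma(9, shape = 1), 3, 3,
              dimnames = list(c("W", "S", "A"), c("W", "S", "A")))
  P / rowSums(P)
}

replication_cfg <- function() replication_params()
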