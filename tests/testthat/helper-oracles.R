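# Independent oracles used across the suite.  Everything here is brute-force
# enumeration or direct formula evaluation, deliberately sharing no code with
# the package internals it checks.

# all set partitions of 1..n, each a list of integer blocks
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1)) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# log probability that a Chinese-restaurant process with concentration conc
# produces a given set partition (block sizes)
crp_log_prob <- function(sizes, conc) {
  n <- sum(sizes)
  length(sizes) * log(conc) + sum(lgamma(sizes)) -
    (lgamma(conc + n) - lgamma(conc))
}

# exact abundance-partition probabilities of the two-stage neutral sampling
# process at small J: individuals -> immigrant ancestors (CRP with
# I = m(J-1)/(1-m)), ancestors -> species (CRP with theta).  Returns a named
# vector keyed by the sorted abundance partition, e.g. "3 1 1".
exact_snm_probs <- function(theta, m, J) {
  acc <- new.env(parent = emptyenv())
  add <- function(key, p) {
    assign(key, p + (if (exists(key, envir = acc)) get(key, envir = acc) else 0),
           envir = acc)
  }
  part_key <- function(sizes) paste(sort(sizes, decreasing = TRUE), collapse = " ")
  if (m == 1) {
    for (P in set_partitions(J)) {
      sizes <- lengths(P)
      add(part_key(sizes), exp(crp_log_prob(sizes, theta)))
    }
  } else {
    I <- m * (J - 1) / (1 - m)
    anc_parts <- lapply(seq_len(J), set_partitions)
    for (P in set_partitions(J)) {
      sizes <- lengths(P)
      lpA <- crp_log_prob(sizes, I)
      for (Q in anc_parts[[length(sizes)]]) {
        ab <- vapply(Q, function(b) sum(sizes[b]), numeric(1))
        add(part_key(ab), exp(lpA + crp_log_prob(lengths(Q), theta)))
      }
    }
  }
  keys <- ls(acc)
  stats::setNames(vapply(keys, get, numeric(1), envir = acc), keys)
}

# canonical key of an abundance sample for frequency tables
sample_key <- function(d) paste(sort(d$count, decreasing = TRUE), collapse = " ")

# exact single-elemental-step transition matrix of the HL model at J = 3
# with an even two-species pool, over states n1 = 0..3.  Death first
# (weights ((1-g) + g n/J) n/J over present species), then recruitment:
# immigrant with probability m (species 1 w.p. 1/2), else a uniform copy of
# one of the two survivors.
hl3_transition_matrix <- function(gamma, m) {
  J <- 3
  P <- matrix(0, 4, 4, dimnames = list(0:3, 0:3))
  for (n1 in 0:3) {
    n2 <- J - n1
    wf <- function(n) if (n == 0) 0 else ((1 - gamma) + gamma * n / J) * (n / J)
    w1 <- wf(n1); w2 <- wf(n2)
    for (dead in 1:2) {
      pdeath <- if (dead == 1) w1 / (w1 + w2) else w2 / (w1 + w2)
      if (pdeath == 0) next
      n1p <- n1 - (dead == 1)
      r1 <- m * 0.5 + (1 - m) * n1p / (J - 1)
      P[n1 + 1, n1p + 1 + 1] <- P[n1 + 1, n1p + 1 + 1] + pdeath * r1
      P[n1 + 1, n1p + 1] <- P[n1 + 1, n1p + 1] + pdeath * (1 - r1)
    }
  }
  P
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# frequencies of abundance partitions over ndraw urn samples
urn_partition_freqs <- function(theta, m, J, ndraw, levels) {
  ks <- vapply(seq_len(ndraw),
               function(i) sample_key(urn_sample(theta, m, J)), character(1))
  table(factor(ks, levels = levels))
}
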