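# Independent oracles used across tests. Deliberately naive, loop-based
# reimplementations so they share no code path with the package.

# Curve-number runoff, evaluated literally from the closed form.
oracle_scs <- function(p, cn, lambda = 0.2) {
  s <- 25400 / cn - 254
  ia <- lambda * s
  if (p <= ia) return(0)
  (p - ia)^2 / (p - ia + s)
}

# Clark routing at the internal step: explicit per-step reservoir recursion
# over the incremental time-area histogram, then daily aggregation.
oracle_clark_daily <- function(tc_h, r_h, dt_h) {
  ta <- function(tf) {
    if (tf <= 0.5) 1.414 * tf^1.5 else 1 - 1.414 * (1 - tf)^1.5
  }
  n_in <- ceiling(tc_h / dt_h)
  cum <- vapply(seq_len(n_in) * dt_h, function(t) ta(min(t, tc_h) / tc_h),
                numeric(1))
  inflow <- diff(c(0, cum))
  cc <- min(1, dt_h / (r_h + 0.5 * dt_h))
  o <- 0; out <- numeric(0); csum <- 0; i <- 1
  while (csum < 1 - 1e-6) {
    inp <- if (i <= n_in) inflow[i] else 0
    o <- cc * inp + (1 - cc) * o
    out <- c(out, o); csum <- csum + o; i <- i + 1
  }
  out <- out / sum(out)
  per <- 24 / dt_h
  grp <- rep(seq_len(ceiling(length(out) / per)), each = per)[seq_along(out)]
  as.numeric(tapply(out, grp, sum))
}

# Quadratic entropy by explicit double loop.
oracle_rao <- function(p, d) {
  out <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) {
    out <- out + d[i, j] * p[i] * p[j]
  }
  out
}

# Pairwise-sum functional attribute diversity by explicit double loop.
oracle_fad1 <- function(present, d) {
  idx <- which(present)
  out <- 0
  if (length(idx) < 2) return(0)
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (a < b) out <- out + d[idx[a], idx[b]]
  }
  out
}

# Gower-type trait distance by explicit elementwise recomputation.
oracle_trait_distance <- function(profiles, missing, schema) {
  traits <- unique(as.character(schema$trait))
  n <- nrow(profiles)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; cnt <- 0
    for (k in seq_along(traits)) {
      if (missing[i, k] || missing[j, k]) next
      cols <- which(as.character(schema$trait) == traits[k])
      num <- num + 0.5 * sum(abs(profiles[i, cols] - profiles[j, cols]))
      cnt <- cnt + 1
    }
    d[i, j] <- num / cnt
  }
  d
}

# Spearman's rho as rank-then-Pearson with average ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# A small synthetic discharge window generator for property tests.
random_window <- function(w, seed) {
  set.seed(seed)
  stats::rgamma(w, shape = 1.2, scale = 0.01)
}
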