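# Fixtures are built in code at test time; nothing binary is stored.

# Two-domain toy matrix: blocks 1..p and (p+1)..b, short within-block
# distances, long cross-block distances.
two_block_matrix <- function(b = 8, p = 4, within = 0.1, cross = 0.9) {
  grp <- as.integer(seq_len(b) > p)
  m <- matrix(ifelse(outer(grp, grp, `==`), within, cross), b, b)
  diag(m) <- 0
  m
}

# Memoised small synthetic dataset shared across tests (cheap to refit).
.fixture_env <- new.env(parent = emptyenv())

small_synthetic <- function(noise_sd = 0.02, seed = 5) {
  key <- sprintf("ds_%g_%d", noise_sd, seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- synthetic_config(b = 16, k_true = 3, n = 150, noise_sd = noise_sd,
                            label_components = 2, label_effect = 2, seed = seed)
    .fixture_env[[key]] <- simulate_dataset(cfg)
  }
  .fixture_env[[key]]
}

# Ensemble of 10 cells x 10 loci whose missing fractions are exactly
# 0.0, 0.1, ..., 0.9 (cell i misses its first i-1 loci).
missingness_ladder <- function() {
  n <- 10L; b <- 10L
  coords <- array(rnorm(n * b * 3), c(n, b, 3))
  for (i in seq_len(n)) {
    if (i > 1) for (ax in 1:3) coords[i, seq_len(i - 1L), ax] <- NA_real_
  }
  cell_ensemble(coords)
}

# Write a coordinate table TSV for an ensemble and return the path.
write_fixture_table <- function(ensemble) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  write_coordinate_table(ensemble, path)
  path
}

# Independent brute-force oracles -------------------------------------------

# Exhaustive-enumeration two-sided Mann-Whitney p for tie-free data: count
# rank assignments whose |U - n1 n2 / 2| is at least as extreme.
enumerate_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  m <- n1 * n2 / 2
  subsets <- utils::combn(N, n1)
  u_all <- apply(subsets, 2, function(s) sum(s) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - m) >= abs(u_obs - m))
}

# Literal step-up Benjamini-Hochberg: q_(i) = min_{j >= i} p_(j) * m / j.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[o][i:m] * m / (i:m))
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Planted-vs-recovered template correlations after optimal matching.
matched_template_cors <- function(fit, W_true) {
  b <- dim(W_true)[1]; k <- dim(W_true)[3]
  planted <- matrix(aperm(W_true, c(2, 1, 3)), b * b, k)
  chromafactor:::match_components(
    chromafactor:::flat_templates(fit), planted)$correlations
}
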