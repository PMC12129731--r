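# Shared in-code fixtures. Everything is generated at test time;
# nothing binary is stored.

# A small three-group cohort for fast ML and differential tests.
small_cohort <- function(seed = 1L,
                         sizes = c(G2019S_L2PD = 12L, G2019S_L2NMC = 10L,
                                   CTRL = 14L)) {
  generate_cohort(sizes, seed = seed)
}

# A named matrix of iid normal noise, features x samples.
noise_matrix <- function(n_feat, n_samp, seed = 1L, sd = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_feat * n_samp, sd = sd), n_feat, n_samp,
                dimnames = list(sprintf("F%04d", seq_len(n_feat)),
                                sprintf("s%03d", seq_len(n_samp))))
    m
  })
}

# Sample-level matrix (rows = samples) with k informative columns
# separating the given classes by a mean shift.
informative_data <- function(n_per_class = 15L, n_informative = 5L,
                             n_noise = 20L, delta = 2, seed = 1L,
                             classes = c("A", "B", "C")) {
  withr::with_seed(seed, {
    n <- n_per_class * length(classes)
    y <- rep(classes, each = n_per_class)
    p <- n_informative + n_noise
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("V%03d", seq_len(p))))
    for (j in seq_len(n_informative)) {
      # each informative feature separates a rotating pair of classes
      target <- classes[1L + (j - 1L) %% length(classes)]
      X[y == target, j] <- X[y == target, j] + delta
    }
    list(X = X, y = y,
         informative = colnames(X)[seq_len(n_informative)],
         noise = colnames(X)[-seq_len(n_informative)])
  })
}

# Independent brute-force BH step-up oracle (kept deliberately naive).
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[ord[i]] <- min(1, min(m * p[ord[js]] / js))
  }
  adj
}

# Independent tie-corrected Spearman oracle: Pearson on average ranks.
spearman_bruteforce <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

expect_identical_manifest <- function(m1, m2) {
  strip <- function(m) {
    m$total_wall_clock <- NULL
    m$stages <- lapply(m$stages, function(s) { s$wall_clock <- NULL; s })
    m
  }
  expect_identical(strip(m1), strip(m2))
}
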