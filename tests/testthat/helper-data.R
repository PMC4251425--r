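# Programmatic fixtures shared across test files.

# k Gaussian blobs at corners of the unit square (2-D), well separated.
blob_corners <- list(
  c(0, 0), c(1, 1), c(0, 1), c(1, 0)
)

make_blobs <- function(k, n_per = 30, sd = 0.03, seed = 1) {
  stopifnot(k >= 1, k <= 4)
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(
      rnorm(n_per, blob_corners[[i]][1], sd),
      rnorm(n_per, blob_corners[[i]][2], sd)
    )
  }))
  list(X = X, means = do.call(rbind, blob_corners[seq_len(k)]))
}

# A tiny table in the UCI Parkinsons dialect (name + 22 features + status).
pd_feature_names <- c(
  "MDVP:Fo(Hz)", "MDVP:Fhi(Hz)", "MDVP:Flo(Hz)", "MDVP:Jitter(%)",
  "MDVP:Jitter(Abs)", "MDVP:RAP", "MDVP:PPQ", "Jitter:DDP",
  "MDVP:Shimmer", "MDVP:Shimmer(dB)", "Shimmer:APQ3", "Shimmer:APQ5",
  "MDVP:APQ", "Shimmer:DDA", "NHR", "HNR", "RPDE", "DFA",
  "spread1", "spread2", "D2", "PPE"
)

write_pd_toy <- function(path, n = 6, seed = 42) {
  set.seed(seed)
  d <- as.data.frame(matrix(round(runif(n * 22, 0.01, 200), 5), n, 22))
  names(d) <- pd_feature_names
  d <- cbind(
    name = paste0("phon_R01_S", seq_len(n)),
    d,
    status = rep(c(1L, 0L), length.out = n)
  )
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE)
  invisible(d)
}

# A cleanly separable two-class table (no ring, tight shifted Gaussians).
make_separable <- function(n_per_class = c(20, 40), seed = 1) {
  synth_two_class(
    n_per_class = n_per_class, n_informative = 3, n_noise = 1, n_ring = 0,
    shift_means = c(0, 10), shift_sd = 0.5, nonseparable = FALSE,
    feature_scales = c(1, 0.1, 10, 1), seed = seed
  )
}

# Small random labelled table for oracle comparisons.
random_table <- function(n = 20, m = 4, seed = 1) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * m), n, m))
  names(d) <- paste0("f", seq_len(m))
  d$class <- factor(sample(c("0", "1"), n, replace = TRUE, prob = c(0.4, 0.6)))
  if (length(unique(d$class)) < 2) d$class[1:2] <- c("0", "1")
  tibble::as_tibble(d)
}

# Reproduce the min-max scaling find_centers applies internally.
unit_scaled <- function(X) {
  apply(X, 2, function(v) {
    if (max(v) == min(v)) rep(0, length(v)) else (v - min(v)) / (max(v) - min(v))
  })
}
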