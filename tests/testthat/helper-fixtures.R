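# Shared fixtures and independent oracles.

# Brute-force double-loop oracles for the contact descriptors: the naive O(L^2)
# reference the vectorized implementations are checked against.
bf_lrcn <- function(m, L, sep = 12, cc = 1) {
  s <- 0
  for (i in seq_len(L - 1)) for (j in (i + 1):L)
    if (j - i >= sep) s <- s + m[i, j]
  s / L^cc
}

bf_lrco <- function(m, L, sep = 12, cc = 2) {
  s <- 0
  for (i in seq_len(L - 1)) for (j in (i + 1):L)
    if (j - i >= sep) s <- s + m[i, j] * (j - i)
  s / L^cc
}

bf_co <- function(m, L) {
  s <- 0; tot <- 0
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    s <- s + m[i, j] * (j - i)
    tot <- tot + m[i, j]
  }
  if (tot == 0) 0 else s / (L * tot)
}

# Random symmetric probability matrix with given pair density.
random_map_matrix <- function(L, density) {
  m <- matrix(0, L, L)
  up <- which(upper.tri(m))
  hit <- runif(length(up)) < density
  m[up[hit]] <- runif(sum(hit))
  m + t(m)
}

# The spec's running example: 20 residues, one long-range contact
# p(1,13) = 1, half helix / half sheet, poly-alanine.
tiny_record <- function() {
  protein_record("tiny", strrep("A", 20),
                 ss_string = paste0(strrep("H", 10), strrep("E", 10)),
                 map = contact_map(cbind(1, 13, 1), n = 20))
}

# Memoized synthetic benchmarks shared across test files (generation is the
# expensive part; the records are read-only).
.bench_cache <- new.env(parent = emptyenv())
bench_records <- function(noise_sd = 0.3, seed = 42, n = 80) {
  key <- sprintf("n%d_s%d_sd%g", n, seed, noise_sd)
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- synth_records(
      synth_config(n_proteins = n, noise_sd = noise_sd, seed = seed))
  .bench_cache[[key]]
}

# Small well-separated 2-D two-class clouds for classifier tests.
gaussian_clouds <- function(n = 40, sep = 4, seed = 1) {
  set.seed(seed)
  half <- n / 2
  x <- rbind(matrix(rnorm(half * 2), ncol = 2),
             matrix(rnorm(half * 2, mean = sep), ncol = 2))
  list(x = x, y = rep(c("two_state", "multi_state"), each = half))
}

xor_data <- function(n_per = 10, seed = 5) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0)) * 4
  x <- do.call(rbind, lapply(1:4, function(k) {
    sweep(matrix(rnorm(n_per * 2, sd = 0.4), ncol = 2), 2, centers[k, ], "+")
  }))
  list(x = x, y = rep(c("two_state", "two_state",
                        "multi_state", "multi_state"), each = n_per))
}
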