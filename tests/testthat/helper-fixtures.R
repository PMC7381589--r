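# Fixtures and independent oracles shared across tests.

# quick genotype_matrix from a dosage matrix and labels
toy_G <- function(dosage, deme, range = NULL, sample_time = 0) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  if (is.null(range)) range <- rep("native", n)
  info <- data.frame(id = sprintf("ind%02d", seq_len(n)), deme = deme,
                     range = range, sample_time = sample_time,
                     stringsAsFactors = FALSE)
  genotype_matrix(dosage, info)
}

# symmetric k-deme island model as a demographic_model; deme 1 is the
# primordial deme, the rest are founded (and everything merges) at a time
# deep enough that equilibrium dominates
toy_island_model <- function(k = 2, ne = 1000, m = 1e-3,
                             colonization_time = 1e7, refugium_ne = NULL,
                             mu = 2.5e-8, locus_length = 85) {
  if (is.null(refugium_ne)) refugium_ne <- ne
  demes <- data.frame(
    id = seq_len(k), label = paste0("d", seq_len(k)),
    range = "native", habitat = "mainland", ne = ne,
    founding_time = c(0, rep(colonization_time, k - 1)),
    source_deme = c(NA_integer_, rep(1L, k - 1)),
    founder_size = NA_real_, stringsAsFactors = FALSE)
  mat <- matrix(m, k, k)
  diag(mat) <- 0
  demographic_model(
    demes = demes,
    epochs = list(list(start_gen = 0, end_gen = Inf, matrix = mat)),
    mutation = mutation_model(mu, locus_length, 1000L),
    colonization_time = colonization_time, refugium_ne = refugium_ne)
}

# brute-force quartet Delta: explicit four-index loops, independent of the
# vectorized implementation
brute_delta <- function(D) {
  T <- nrow(D)
  vals <- c()
  for (w in 1:(T - 3)) for (x in (w + 1):(T - 2))
    for (y in (x + 1):(T - 1)) for (z in (y + 1):T) {
      s <- sort(c(D[w, x] + D[y, z], D[w, y] + D[x, z], D[w, z] + D[x, y]),
                decreasing = TRUE)
      vals <- c(vals, if (s[1] == s[3]) 0 else (s[1] - s[2]) / (s[1] - s[3]))
    }
  mean(vals)
}

# random symmetric distance matrix with zero diagonal
rand_sym_dist <- function(T) {
  D <- matrix(0, T, T)
  D[upper.tri(D)] <- runif(T * (T - 1) / 2, 0.1, 2)
  D + t(D)
}

# all permutations of 1..n (independent of the package's enumerator)
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L)) for (i in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}
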