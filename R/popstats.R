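# ---------------------------------------------------------------------------
# Diversity and differentiation statistics on genotype matrices.
# Missing data policy: pairwise/groupwise deletion per SNP, no imputation.
# ---------------------------------------------------------------------------

.grouping_vector <- function(G, grouping = c("deme", "range")) {
  grouping <- match.arg(grouping)
  as.character(G$info[[grouping]])
}

# run a block with a locally seeded RNG, restoring global state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

#' Per-group diversity summary
#'
#' For each group (deme or range): observed heterozygosity `Ho` (mean over
#' SNPs of the heterozygote fraction among non-missing calls), expected
#' heterozygosity `He` (mean over SNPs of the plug-in `2 p (1-p)`), the
#' number of private SNPs (polymorphic within the group, monomorphic in
#' every other group), and private SNPs per individual.
#'
#' @param G a [genotype_matrix()]
#' @param grouping `"deme"` or `"range"`
#' @return data frame with one row per group; groups with fewer than two
#'   individuals are flagged in the `flag` column
#' @export
diversity_summary <- function(G, grouping = c("deme", "range")) {
  g <- .grouping_vector(G, grouping)
  X <- G$dosage
  groups <- sort(unique(g))
  poly <- matrix(FALSE, length(groups), ncol(X),
                 dimnames = list(groups, NULL))
  res <- lapply(groups, function(gr) {
    Xg <- X[g == gr, , drop = FALSE]
    n_called <- colSums(!is.na(Xg))
    het <- colSums(Xg == 1, na.rm = TRUE)
    p <- colSums(Xg, na.rm = TRUE) / (2 * n_called)
    ok <- n_called > 0
    poly[gr, ] <<- ok & p > 0 & p < 1
    data.frame(group = gr, n = nrow(Xg),
               Ho = mean((het / n_called)[ok]),
               He = mean((2 * p * (1 - p))[ok]),
               flag = if (nrow(Xg) < 2) "n<2" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  priv <- vapply(seq_along(groups), function(i) {
    others <- poly[-i, , drop = FALSE]
    sum(poly[i, ] & colSums(others) == 0)
  }, 0L)
  out$private_snps <- priv
  out$private_per_ind <- priv / out$n
  out
}

# per-SNP allele counts (derived count a, allele number n) for one group
.allele_counts <- function(X) {
  n <- 2 * colSums(!is.na(X))
  a <- colSums(X, na.rm = TRUE)
  list(a = a, n = n)
}

#' Reich's small-sample F_ST
#'
#' Pairwise ratio-of-sums estimator designed to stay unbiased at very small
#' sample sizes. Per SNP, with derived counts `a1` of `n1` alleles and `a2`
#' of `n2`: `h_k = a_k (n_k - a_k) / (n_k (n_k - 1))`,
#' `N = (a1/n1 - a2/n2)^2 - h1/n1 - h2/n2`, `D = N + h1 + h2`, and
#' `F = sum(N) / sum(D)` over SNPs. SNPs monomorphic for the same allele in
#' both groups (`D = 0`) or with fewer than two called alleles in either
#' group are excluded.
#'
#' @param G a [genotype_matrix()]
#' @param grouping `"deme"` or `"range"`
#' @return list of class `pairwise_fst`: `fst` (symmetric matrix, zero
#'   diagonal), `num`/`den` (per-pair sums of N and D)
#' @export
reich_fst <- function(G, grouping = c("deme", "range")) {
  g <- .grouping_vector(G, grouping)
  groups <- sort(unique(g))
  k <- length(groups)
  counts <- lapply(groups, function(gr)
    .allele_counts(G$dosage[g == gr, , drop = FALSE]))
  fst <- num <- den <- matrix(0, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    c1 <- counts[[i]]; c2 <- counts[[j]]
    use <- c1$n >= 2 & c2$n >= 2
    a1 <- c1$a[use]; n1 <- c1$n[use]
    a2 <- c2$a[use]; n2 <- c2$n[use]
    h1 <- a1 * (n1 - a1) / (n1 * (n1 - 1))
    h2 <- a2 * (n2 - a2) / (n2 * (n2 - 1))
    N <- (a1 / n1 - a2 / n2)^2 - h1 / n1 - h2 / n2
    D <- N + h1 + h2
    inc <- D != 0
    if (!any(inc)) stop("all SNPs excluded for pair ", groups[i], "/", groups[j])
    num[i, j] <- num[j, i] <- sum(N[inc])
    den[i, j] <- den[j, i] <- sum(D[inc])
    fst[i, j] <- fst[j, i] <- num[i, j] / den[i, j]
  }
  structure(list(fst = fst, num = num, den = den, grouping = match.arg(grouping)),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat("Pairwise Reich F_ST (", x$grouping, " level)\n", sep = "")
  print(round(x$fst, 4))
  invisible(x)
}

#' Permutation comparison of within-range F_ST
#'
#' Tests whether mean within-range pairwise F_ST differs between the two
#' ranges. The statistic is the absolute difference of the two within-range
#' means; the null distribution permutes the deme-to-range assignment
#' (preserving range sizes). With `n_perm = "exhaustive"` every distinct
#' assignment is enumerated and the p-value is the exact proportion of
#' assignments at least as extreme (identity included).
#'
#' @param G a [genotype_matrix()] with at least two demes per range
#' @param n_perm number of random permutations, or `"exhaustive"`
#' @param seed integer seed (ignored for exhaustive enumeration)
#' @return list: `statistic`, `p`, `within_means` (named per range),
#'   `n_perm`; a `warning` element is attached when fewer than 20 distinct
#'   assignments exist
#' @export
compare_fst_between_ranges <- function(G, n_perm = 999, seed = NULL) {
  pf <- reich_fst(G, "deme")
  demes <- rownames(pf$fst)
  rng_of <- G$info$range[match(demes, as.character(G$info$deme))]
  ranges <- sort(unique(rng_of))
  if (length(ranges) != 2) stop("exactly two ranges required")
  if (min(table(rng_of)) < 2) stop("need >= 2 demes per range")

  within_mean <- function(assign) {
    vapply(ranges, function(r) {
      idx <- which(assign == r)
      mean(pf$fst[idx, idx][upper.tri(diag(length(idx)))])
    }, 0)
  }
  obs_means <- within_mean(rng_of)
  obs <- abs(diff(obs_means))

  n_a <- sum(rng_of == ranges[1])
  n_distinct <- choose(length(demes), n_a)
  warn <- if (n_distinct < 20)
    sprintf("only %d distinct deme-to-range assignments", n_distinct) else NULL

  if (identical(n_perm, "exhaustive")) {
    sets <- combn(length(demes), n_a)
    null <- apply(sets, 2, function(s) {
      lab <- rep(ranges[2], length(demes)); lab[s] <- ranges[1]
      abs(diff(within_mean(lab)))
    })
    p <- mean(null >= obs - 1e-12)
    n_used <- ncol(sets)
  } else {
    null <- .with_seed(seed, vapply(seq_len(n_perm), function(i)
      abs(diff(within_mean(sample(rng_of)))), 0))
    p <- (1 + sum(null >= obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  out <- list(statistic = obs, p = p,
              within_means = setNames(obs_means, ranges), n_perm = n_used)
  if (!is.null(warn)) out$warning <- warn
  out
}

#' Hierarchical AMOVA on dosage vectors
#'
#' Partitions the variance of individual dosage vectors into three nested
#' levels — among ranges, among demes within ranges, within demes — using
#' moment estimators with the standard nested-ANOVA coefficients for
#' unbalanced designs. Sums of squares are squared Euclidean distances to
#' level means, summed over SNPs (missing calls omitted per SNP). Negative
#' components are reported raw; percentages use the raw total.
#'
#' @param G a [genotype_matrix()] with >= 2 ranges and >= 2 demes in at
#'   least one range
#' @return list of class `amova_result`: `components` (sigma_a, sigma_b,
#'   sigma_c), `percent`, `ss`, `df`
#' @export
amova <- function(G) {
  deme <- as.character(G$info$deme)
  rng <- as.character(G$info$range)
  if (length(unique(rng)) < 2) stop("AMOVA needs >= 2 ranges")
  if (length(unique(deme)) < 2) stop("AMOVA needs >= 2 demes")
  X <- G$dosage
  N <- nrow(X)
  demes <- unique(deme)
  P <- length(demes)
  Gn <- length(unique(rng))
  rng_of_deme <- rng[match(demes, deme)]

  col_mean <- function(M) colMeans(M, na.rm = TRUE)
  grand <- col_mean(X)
  grand[is.nan(grand)] <- 0

  ss_wd <- 0; ss_ad <- 0; ss_ar <- 0
  for (r in unique(rng)) {
    Xr <- X[rng == r, , drop = FALSE]
    mr <- col_mean(Xr); mr[is.nan(mr)] <- grand[is.nan(mr)]
    ss_ar <- ss_ar + nrow(Xr) * sum((mr - grand)^2, na.rm = TRUE)
    for (d in demes[rng_of_deme == r]) {
      Xd <- X[deme == d, , drop = FALSE]
      md <- col_mean(Xd); md[is.nan(md)] <- mr[is.nan(md)]
      ss_ad <- ss_ad + nrow(Xd) * sum((md - mr)^2, na.rm = TRUE)
      ss_wd <- ss_wd + sum(sweep(Xd, 2, md)^2, na.rm = TRUE)
    }
  }
  df <- c(ranges = Gn - 1, demes = P - Gn, within = N - P)
  if (any(df[c("ranges", "within")] <= 0) || df["demes"] < 0)
    stop("degenerate nesting for AMOVA")
  ms <- c(ss_ar, ss_ad, ss_wd) / pmax(df, 1)

  n_d <- as.numeric(table(deme)[demes])
  n_r <- as.numeric(tapply(n_d, rng_of_deme, sum))
  sum_nd2_by_r <- tapply(n_d^2, rng_of_deme, sum)
  # unbalanced nested-ANOVA coefficients
  n_b <- (N - sum(sum_nd2_by_r / n_r)) / max(P - Gn, 1)
  n_b2 <- (sum(sum_nd2_by_r / n_r) - sum(n_d^2) / N) / (Gn - 1)
  n_a <- (N - sum(n_r^2) / N) / (Gn - 1)

  sigma_c <- ms[3]
  sigma_b <- if (P > Gn) (ms[2] - sigma_c) / n_b else 0
  sigma_a <- (ms[1] - sigma_c - n_b2 * sigma_b) / n_a
  comps <- c(among_ranges = sigma_a, among_demes_within = sigma_b,
             within_demes = sigma_c)
  tot <- sum(comps)
  pct <- if (tot > 0) 100 * comps / tot else rep(NA_real_, 3)
  structure(list(components = comps, percent = pct,
                 ss = c(among_ranges = ss_ar, among_demes_within = ss_ad,
                        within_demes = ss_wd),
                 df = df),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  df <- data.frame(df = x$df, SS = x$ss, sigma2 = x$components,
                   percent = x$percent)
  rownames(df) <- names(x$components)
  print(df)
  invisible(x)
}

#' Rousset's inter-individual genetic distance (a-hat)
#'
#' Identity-probability construction: `Q_ij` is the mean over co-called SNPs
#' of the probability that one random allele from individual i and one from
#' j are identical in state (`(x_i x_j + (2-x_i)(2-x_j)) / 4` on dosages);
#' `Q_w` is the panel-wide mean within-individual identity (1 for a
#' homozygote, 0.5 for a heterozygote). Then
#' `a_ij = (Q_w - Q_ij) / (1 - Q_w)`.
#'
#' @param G a [genotype_matrix()] with >= 2 individuals
#' @return symmetric matrix of a-hat values with zero diagonal convention
#'   left to the caller (diagonal holds self-comparisons); a `degenerate`
#'   attribute flags an all-homozygous identical panel (`Q_w = 1`)
#' @export
rousset_a <- function(G) {
  X <- G$dosage
  n <- nrow(X)
  stopifnot(n >= 2)
  qw_i <- rowMeans((X^2 + (2 - X)^2) / 4, na.rm = TRUE)
  Qw <- mean(qw_i)
  has_na <- anyNA(X)
  if (!has_na) {
    S <- ncol(X)
    Q <- (X %*% t(X) + (2 - X) %*% t(2 - X)) / (4 * S)
  } else {
    Q <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in i:n) {
      ok <- !is.na(X[i, ]) & !is.na(X[j, ])
      if (!any(ok)) stop("individuals ", i, " and ", j, " share no called SNP")
      Q[i, j] <- Q[j, i] <-
        mean((X[i, ok] * X[j, ok] + (2 - X[i, ok]) * (2 - X[j, ok])) / 4)
    }
  }
  if (Qw >= 1) {
    a <- matrix(NA_real_, n, n)
    a[Q >= 1] <- 0
    attr(a, "degenerate") <- TRUE
    if (anyNA(a)) attr(a, "flag") <- "Q_w = 1 with non-identical pairs"
  } else {
    a <- (Qw - Q) / (1 - Qw)
    attr(a, "degenerate") <- FALSE
  }
  dimnames(a) <- list(G$info$id, G$info$id)
  a
}

#' Isolation-by-distance regression with a Mantel permutation test
#'
#' Ordinary least squares of pairwise a-hat on pairwise geographic distance
#' over unordered pairs, with significance from Mantel permutation of
#' individual labels: the rows/columns of the genetic matrix are permuted
#' jointly and the slope recomputed; the one-sided p-value is
#' `(1 + #\{null slope >= observed\}) / (n_perm + 1)`, or the exact
#' proportion over all label permutations (identity included) when
#' `n_perm = "exhaustive"`.
#'
#' @param a_matrix symmetric matrix of Rousset a-hat values
#' @param geo_km symmetric nonnegative matrix of distances in km,
#'   conformable with `a_matrix`
#' @param n_perm number of permutations, or `"exhaustive"` (feasible for
#'   <= 8 individuals)
#' @param seed integer seed
#' @return list of class `ibd_result`: `slope` (a-hat per km), `intercept`,
#'   `r2`, `adj_r2`, `p`, `n_pairs`
#' @export
ibd_regression <- function(a_matrix, geo_km, n_perm = 999, seed = NULL) {
  stopifnot(nrow(a_matrix) == nrow(geo_km), ncol(geo_km) == nrow(geo_km))
  if (any(geo_km < 0)) stop("geographic distances must be >= 0")
  n <- nrow(a_matrix)
  up <- upper.tri(a_matrix)
  x <- geo_km[up]
  if (length(unique(x)) < 2) stop("constant geographic distances: slope undefined")
  y <- a_matrix[up]

  fit_slope <- function(yv) {
    xc <- x - mean(x)
    sum(xc * yv) / sum(xc^2)
  }
  slope <- fit_slope(y)
  intercept <- mean(y) - slope * mean(x)
  ssr <- sum((y - intercept - slope * x)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 0
  k <- length(y)
  adj_r2 <- if (sst > 0) 1 - (1 - r2) * (k - 1) / (k - 2) else 0

  perm_slope <- function(ord) {
    ap <- a_matrix[ord, ord]
    fit_slope(ap[up])
  }
  if (identical(n_perm, "exhaustive")) {
    perms <- .all_permutations(n)
    null <- vapply(perms, perm_slope, 0)
    p <- mean(null >= slope - 1e-12)
    n_used <- length(perms)
  } else {
    null <- .with_seed(seed, vapply(seq_len(n_perm), function(i)
      perm_slope(sample(n)), 0))
    p <- (1 + sum(null >= slope - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 adj_r2 = adj_r2, p = p, n_pairs = k, n_perm = n_used),
            class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat(sprintf("IBD regression over %d pairs: slope %.4g a-hat/km, r2 %.3f (adj %.3f), Mantel p %.4g\n",
              x$n_pairs, x$slope, x$r2, x$adj_r2, x$p))
  invisible(x)
}

.all_permutations <- function(n) {
  if (n > 8) stop("exhaustive permutations limited to n <= 8")
  if (n == 1) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos - 1L)
  }
  out
}

#' Write a Table-1-style diversity TSV and a pairwise F_ST TSV
#'
#' @param div output of [diversity_summary()]
#' @param fst output of [reich_fst()]
#' @param div_path,fst_path file paths
#' @export
write_popstats_tsv <- function(div, fst, div_path, fst_path) {
  write.table(div[c("group", "n", "Ho", "He", "private_snps", "private_per_ind")],
              div_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(group = rownames(fst$fst),
                         round(fst$fst, 6), check.names = FALSE),
              fst_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
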