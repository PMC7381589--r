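# ---------------------------------------------------------------------------
# p-distances, quartet Delta reticulation scores, NEXUS distance export.
# ---------------------------------------------------------------------------

#' Uncorrected p-distance matrix
#'
#' Individual level: `d(i, j)` is the mean over co-called SNPs of
#' `|x_i - x_j| / 2` on the dosage scale — the expected allele mismatch
#' between one random allele from each individual under random pairing.
#' Population level: the mean of the individual distances over all
#' cross-population pairs.
#'
#' @param G a [genotype_matrix()]
#' @param level `"individual"` or `"population"`
#' @return symmetric labeled matrix with zero diagonal, entries in `[0, 1]`,
#'   with attribute `level`
#' @export
p_distance <- function(G, level = c("individual", "population")) {
  level <- match.arg(level)
  X <- G$dosage
  n <- nrow(X)
  if (anyNA(X)) {
    D <- matrix(0, n, n)
    called <- !is.na(X)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ok <- called[i, ] & called[j, ]
      if (!any(ok))
        stop("individuals ", G$info$id[i], " and ", G$info$id[j],
             " share no called SNP")
      D[i, j] <- D[j, i] <- mean(abs(X[i, ok] - X[j, ok])) / 2
    }
  } else {
    D <- as.matrix(stats::dist(X, method = "manhattan")) / (2 * ncol(X))
  }
  dimnames(D) <- list(G$info$id, G$info$id)
  if (level == "population") {
    deme <- as.character(G$info$deme)
    demes <- sort(unique(deme))
    P <- matrix(0, length(demes), length(demes),
                dimnames = list(demes, demes))
    for (i in seq_along(demes)) for (j in seq_along(demes)) {
      if (j <= i) next
      P[i, j] <- P[j, i] <- mean(D[deme == demes[i], deme == demes[j]])
    }
    D <- P
  }
  attr(D, "level") <- level
  D
}

#' Quartet Delta reticulation score
#'
#' For each quartet of taxa \{w, x, y, z\} the three pairwise distance sums
#' `d(w,x)+d(y,z)`, `d(w,y)+d(x,z)`, `d(w,z)+d(x,y)` are ordered
#' `m1 >= m2 >= m3` and the quartet's score is
#' `delta = (m1 - m2) / (m1 - m3)`, taken as 0 in the degenerate case
#' `m1 = m3`. Tree metrics satisfy the four-point condition (`m1 = m2`), so
#' Delta is 0 on a perfectly tree-like distance matrix and grows with
#' phylogenetic conflict. The summary reports the mean over all `C(T, 4)`
#' quartets and the mean over quartets containing each taxon.
#'
#' @param D symmetric nonnegative distance matrix over >= 4 taxa
#' @return list of class `delta_summary`: `mean`, `per_taxon` (named),
#'   `n_quartets`
#' @export
delta_score <- function(D) {
  D <- as.matrix(D)
  T <- nrow(D)
  if (T < 4) stop("delta_score needs >= 4 taxa")
  if (any(D < 0)) stop("negative distances")
  q <- combn(T, 4)
  w <- q[1, ]; x <- q[2, ]; y <- q[3, ]; z <- q[4, ]
  s1 <- D[cbind(w, x)] + D[cbind(y, z)]
  s2 <- D[cbind(w, y)] + D[cbind(x, z)]
  s3 <- D[cbind(w, z)] + D[cbind(x, y)]
  m1 <- pmax(s1, s2, s3)
  m3 <- pmin(s1, s2, s3)
  m2 <- s1 + s2 + s3 - m1 - m3
  span <- m1 - m3
  delta <- ifelse(span <= 0, 0, (m1 - m2) / span)
  per_taxon <- vapply(seq_len(T), function(i)
    mean(delta[w == i | x == i | y == i | z == i]), 0)
  labs <- rownames(D)
  if (is.null(labs)) labs <- as.character(seq_len(T))
  structure(list(mean = mean(delta), per_taxon = setNames(per_taxon, labs),
                 n_quartets = ncol(q)),
            class = "delta_summary")
}

#' @export
print.delta_summary <- function(x, ...) {
  cat(sprintf("Mean quartet Delta %.4f over %d quartets\n",
              x$mean, x$n_quartets))
  invisible(x)
}

#' Write a distance matrix as a NEXUS DISTANCES block
#'
#' Emits TAXA and DISTANCES blocks (lower-triangular with diagonal, labels
#' quoted) readable by split-network software such as SplitsTree for
#' neighbor-net visualization, and by [read_nexus_distances()].
#'
#' @param D symmetric labeled distance matrix
#' @param path file path
#' @export
write_nexus_distances <- function(D, path) {
  D <- as.matrix(D)
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("taxon", seq_len(nrow(D)))
  qlabs <- paste0("'", gsub("'", "''", labs), "'")
  n <- nrow(D)
  lines <- c(
    "#NEXUS", "",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", n),
    paste0("  TAXLABELS ", paste(qlabs, collapse = " "), ";"),
    "END;", "",
    "BEGIN DISTANCES;",
    sprintf("  DIMENSIONS NTAX=%d;", n),
    "  FORMAT TRIANGLE=LOWER DIAGONAL LABELS=LEFT;",
    "  MATRIX")
  for (i in seq_len(n))
    lines <- c(lines, paste0("    ", qlabs[i], " ",
                             paste(format(D[i, seq_len(i)], digits = 15,
                                          trim = TRUE, scientific = FALSE),
                                   collapse = " ")))
  lines <- c(lines, "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_nexus_distances
#' @export
read_nexus_distances <- function(path) {
  txt <- readLines(path)
  tax_line <- grep("TAXLABELS", txt, value = TRUE)
  labs <- regmatches(tax_line, gregexpr("'(?:[^']|'')*'", tax_line))[[1]]
  labs <- gsub("''", "'", substr(labs, 2, nchar(labs) - 1))
  n <- length(labs)
  start <- grep("MATRIX", txt)[1] + 1
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    row <- txt[start + i - 1]
    row <- sub("^\\s*'(?:[^']|'')*'\\s*", "", row, perl = TRUE)
    vals <- as.numeric(strsplit(trimws(row), "\\s+")[[1]])
    D[i, seq_len(i)] <- vals
    D[seq_len(i), i] <- vals
  }
  D
}

#' Write a distance matrix or Delta report as TSV
#'
#' @param D distance matrix (for `write_distance_tsv`)
#' @param delta a `delta_summary` (for `write_delta_tsv`)
#' @param path file path
#' @export
write_distance_tsv <- function(D, path) {
  write.table(data.frame(taxon = rownames(D), as.matrix(D),
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
write_delta_tsv <- function(delta, path) {
  df <- data.frame(taxon = c("(mean)", names(delta$per_taxon)),
                   delta = c(delta$mean, unname(delta$per_taxon)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
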