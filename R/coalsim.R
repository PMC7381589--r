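# ---------------------------------------------------------------------------
# Coalescent simulation wrappers around the C++ engine.
# ---------------------------------------------------------------------------

# flatten a demographic_model for the C++ core (0-based demes, founding_time
# 0 mapped to Inf = primordial)
.model_to_cpp <- function(model) {
  d <- model$demes
  ft <- ifelse(d$founding_time == 0, Inf, d$founding_time)
  refugium <- which(!is.finite(ft))[1]
  if (is.na(refugium)) stop("model has no primordial (refugial) deme")
  list(
    n_demes = nrow(d),
    ne = as.numeric(d$ne),
    founding_time = as.numeric(ft),
    source = as.integer(ifelse(is.na(d$source_deme), -1L,
                               match(d$source_deme, d$id) - 1L)),
    founder_size = as.numeric(ifelse(is.na(d$founder_size), -1, d$founder_size)),
    colonization_time = as.numeric(model$colonization_time),
    refugium_ne = as.numeric(model$refugium_ne),
    refugium = as.integer(refugium - 1L),
    epoch_start = vapply(model$epochs, function(e) e$start_gen, 0),
    epoch_mats = lapply(model$epochs, function(e) e$matrix))
}

# expand a sampling plan into per-allele-copy tips and per-individual labels;
# allele copies 2k-1, 2k form individual k
.plan_tips <- function(model, plan) {
  .validate_plan(model, plan)
  rows <- lapply(seq_len(nrow(plan)), function(r) {
    n <- plan$n_diploids[r]
    deme <- plan$deme_id[r]
    tt <- plan$sample_time[r]
    list(ind = data.frame(
           id = sprintf("d%02d_t%05d_i%d", deme, as.integer(tt), seq_len(n)),
           deme = deme,
           range = model$demes$range[match(deme, model$demes$id)],
           sample_time = tt, stringsAsFactors = FALSE),
         tip_deme = rep(match(deme, model$demes$id) - 1L, 2L * n),
         tip_time = rep(tt, 2L * n))
  })
  list(info = do.call(rbind, lapply(rows, `[[`, "ind")),
       tip_deme = unlist(lapply(rows, `[[`, "tip_deme")),
       tip_time = unlist(lapply(rows, `[[`, "tip_time")))
}

#' Simulate genealogies under the structured coalescent
#'
#' Generates independent per-locus genealogies. Within a deme of diploid
#' size `Ne` any pair of lineages coalesces at rate `1/(2 Ne)` per
#' generation; each lineage in deme i migrates (backward in time) to deme j
#' at the rate of the epoch in force; at a deme's founding time its lineages
#' pass through the founder bottleneck and move to the source deme; at the
#' colonization time all lineages merge into the refugial deme. Serial
#' samples enter the process at their sampling times.
#'
#' @param model a [demographic_model()]
#' @param plan a [sampling_plan()]
#' @param n_loci number of independent loci
#' @param seed integer seed; each locus gets its own derived stream, so
#'   locus k is reproducible independently of how many loci are run
#' @return list of `genealogy` objects: `ntip`, `parent` (1-based, `NA` at
#'   the root), `age` (generations BP), and a `tips` attribute with
#'   individual / deme / sampling-time annotation per allele copy
#' @export
simulate_genealogies <- function(model, plan, n_loci, seed) {
  stopifnot(n_loci >= 1)
  tp <- .plan_tips(model, plan)
  res <- .cpp_simulate(.model_to_cpp(model), tp$tip_deme, tp$tip_time,
                       as.integer(n_loci), as.numeric(seed),
                       0, model$mutation$locus_length, TRUE, FALSE)
  tipdf <- data.frame(
    individual = rep(tp$info$id, each = 2L),
    deme = rep(tp$info$deme, each = 2L),
    sample_time = rep(tp$info$sample_time, each = 2L))
  lapply(res$trees, function(tr) {
    attr(tr, "tips") <- tipdf
    class(tr) <- "genealogy"
    tr
  })
}

#' Drop mutations on a genealogy
#'
#' Mutations fall as a Poisson process at rate `mu` per site per generation
#' along branches; each gets a uniform site in `1..locus_length`; sites hit
#' more than once are discarded entirely (strict infinite-sites surrogate).
#'
#' @param gen a `genealogy` from [simulate_genealogies()]
#' @param mutation a [mutation_model()]
#' @param seed integer seed
#' @return list with `pos` (sorted site positions) and `derived` (list of
#'   1-based tip-index vectors carrying the derived allele)
#' @export
mutate <- function(gen, mutation, seed) {
  stopifnot(inherits(gen, "genealogy"))
  .cpp_mutate(unclass(gen), mutation$mu, mutation$locus_length,
              as.numeric(seed))
}

#' Ascertain a SNP matrix from per-locus variants
#'
#' Applies the RADseq-style ascertainment used throughout: only the variant
#' at the smallest site position of each locus is kept, allele copies
#' `2k-1, 2k` are paired into diploid dosages, and SNPs whose overall minor
#' allele frequency (across all individuals in the matrix) falls below
#' `maf_threshold` are dropped. Monomorphic loci contribute no SNP.
#'
#' @param variants list of per-locus variant sets (`pos`, `derived`) as
#'   produced by [mutate()]
#' @param model,plan the model and [sampling_plan()] that produced the tips
#' @param maf_threshold minimum minor allele frequency retained
#' @param meta optional provenance list
#' @return a [genotype_matrix()]
#' @export
extract_snp_matrix <- function(variants, model, plan, maf_threshold = 0.01,
                               meta = list()) {
  tp <- .plan_tips(model, plan)
  if (length(tp$tip_deme) %% 2L != 0L)
    stop("odd number of allele copies cannot pair into diploids")
  n_ind <- nrow(tp$info)
  cols <- list(); ids <- list()
  for (l in seq_along(variants)) {
    v <- variants[[l]]
    if (length(v$pos) == 0) next
    k <- which.min(v$pos)             # first SNP per locus
    dt <- v$derived[[k]]
    dos <- tabulate(ceiling(dt / 2), nbins = n_ind)
    cols[[length(cols) + 1L]] <- dos
    ids[[length(ids) + 1L]] <- sprintf("L%d_%d", l, v$pos[k])
  }
  if (length(cols) == 0) {
    dosage <- matrix(numeric(0), nrow = n_ind, ncol = 0)
  } else {
    dosage <- do.call(cbind, cols)
    colnames(dosage) <- unlist(ids)
    f <- colSums(dosage) / (2 * n_ind)
    keep <- f > 0 & f < 1 & pmin(f, 1 - f) >= maf_threshold
    dosage <- dosage[, keep, drop = FALSE]
  }
  genotype_matrix(dosage, tp$info,
                  meta = c(meta, list(maf_threshold = maf_threshold,
                                      n_loci = length(variants))))
}

#' Simulate a SNP dataset end to end
#'
#' Composes [simulate_genealogies()], [mutate()] and [extract_snp_matrix()]
#' in one pass (genealogies are not materialized). Identical
#' `(model, plan, n_loci, seed)` give identical matrices.
#'
#' @inheritParams simulate_genealogies
#' @param n_loci number of loci; defaults to the model's mutation setting
#' @param maf_threshold minor-allele-frequency cutoff (default 0.01)
#' @return a [genotype_matrix()] with seed and scenario metadata
#' @export
simulate_dataset <- function(model, plan = present_day_plan(model), seed,
                             n_loci = model$mutation$n_loci,
                             maf_threshold = 0.01) {
  v <- simulate_variants(model, plan, n_loci, seed)
  extract_snp_matrix(v, model, plan, maf_threshold,
                     meta = list(seed = seed,
                                 M_N = model$params$M_N,
                                 M_H = model$params$M_H))
}

#' Simulate per-locus variant sets without storing genealogies
#'
#' Lower-level building block of [simulate_dataset()]; useful when the same
#' simulated variants feed several ascertainment schemes (e.g. serial
#' time-point subsets).
#'
#' @inheritParams simulate_genealogies
#' @return list of per-locus variant sets (`pos`, `derived`)
#' @export
simulate_variants <- function(model, plan, n_loci, seed) {
  stopifnot(n_loci >= 1)
  tp <- .plan_tips(model, plan)
  res <- .cpp_simulate(.model_to_cpp(model), tp$tip_deme, tp$tip_time,
                       as.integer(n_loci), as.numeric(seed),
                       model$mutation$mu, model$mutation$locus_length,
                       FALSE, TRUE)
  res$variants
}

#' Convert a genealogy to an ape "phylo" tree
#'
#' Multifurcations from founder bottlenecks are preserved. Branch lengths
#' are in generations; tip labels are `individual.copy`.
#'
#' @param gen a `genealogy`
#' @return an [ape::as.phylo] compatible `phylo` object
#' @export
genealogy_to_phylo <- function(gen) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("genealogy_to_phylo requires the ape package")
  ntip <- gen$ntip
  n <- length(gen$parent)
  root <- which(is.na(gen$parent))
  # ape ordering: tips 1..ntip, root ntip+1, internals onward
  internal <- c(root, setdiff((ntip + 1L):n, root))
  newid <- integer(n)
  newid[seq_len(ntip)] <- seq_len(ntip)
  newid[internal] <- ntip + seq_along(internal)
  child <- setdiff(seq_len(n), root)
  edge <- cbind(newid[gen$parent[child]], newid[child])
  len <- gen$age[gen$parent[child]] - gen$age[child]
  tips <- attr(gen, "tips")
  labs <- if (is.null(tips)) paste0("t", seq_len(ntip))
          else paste0(tips$individual, ".", rep(1:2, length.out = ntip))
  structure(list(edge = edge, edge.length = len, tip.label = labs,
                 Nnode = n - ntip),
            class = "phylo", order = "cladewise")
}

#' Total coalescence time of a two-tip genealogy, or time to the most recent
#' common ancestor of all tips
#'
#' @param gen a `genealogy`
#' @return age of the root in generations before present
#' @export
tmrca <- function(gen) gen$age[which(is.na(gen$parent))]
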