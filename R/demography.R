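#' @useDynLib phylodrift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm sd quantile setNames lm coef pf
#' @importFrom utils combn write.table read.table
NULL

# ---------------------------------------------------------------------------
# Demographic model: demes, migration epochs, mutation model
# ---------------------------------------------------------------------------

#' Construct a mutation model
#'
#' Finite loci of fixed length evolving under an infinite-sites surrogate
#' (recurrently hit sites are discarded). Defaults follow the study
#' configuration: 10,000 unlinked 85-bp loci at 2.5e-8 per site per
#' generation.
#'
#' @param mu mutation rate per site per generation (>= 0)
#' @param locus_length locus length in base pairs
#' @param n_loci number of unlinked loci
#' @return a list of class `mutation_model`
#' @export
mutation_model <- function(mu = 2.5e-8, locus_length = 85L, n_loci = 10000L) {
  stopifnot(mu >= 0, locus_length >= 1, n_loci >= 1)
  structure(list(mu = mu, locus_length = as.integer(locus_length),
                 n_loci = as.integer(n_loci)),
            class = "mutation_model")
}

#' Construct a demographic model
#'
#' A set of demes with per-deme diploid effective sizes and founding events,
#' an ordered list of migration epochs tiling backward time, a mutation
#' model, and the terminal postglacial-colonization event that merges all
#' lineages into the refugial deme.
#'
#' Migration matrices use the backward (lineage-movement) convention:
#' `m[i, j]` is the per-generation probability that a lineage currently in
#' deme `i` traces back to deme `j`.
#'
#' @param demes data frame with columns `id`, `label`, `range`, `habitat`,
#'   `ne`, `founding_time`, `source_deme`, `founder_size`
#' @param epochs list of epochs, each `list(start_gen, end_gen, matrix)`,
#'   ordered, tiling `[0, Inf)`
#' @param mutation a [mutation_model()]
#' @param colonization_time generations before present of the postglacial
#'   expansion out of the refugium
#' @param refugium_ne diploid size of the ancestral refugial population
#' @param generations_per_year generations per calendar year
#' @param chains list of integer vectors giving the stepping-stone chains
#'   (used to rebuild matrices on deserialization)
#' @param params named list of scalar parameters (`M_N`, `M_H`, ...)
#' @return object of class `demographic_model`
#' @export
demographic_model <- function(demes, epochs, mutation,
                              colonization_time, refugium_ne,
                              generations_per_year = 2,
                              chains = list(), params = list()) {
  model <- structure(
    list(demes = demes, epochs = epochs, mutation = mutation,
         colonization_time = colonization_time, refugium_ne = refugium_ne,
         generations_per_year = generations_per_year,
         chains = chains, params = params),
    class = "demographic_model")
  bad <- validate_model(model)
  if (length(bad)) stop("invalid demographic model:\n  ",
                        paste(bad, collapse = "\n  "))
  model
}

.paper_defaults <- function() {
  list(
    human_start = 200, human_end = 2000,   # generations BP, [start, end)
    introduction_time = 800,
    colonization_time = 20000,
    expansion_step = 1000,                  # generations between successive foundings
    refugium_ne = 10000,
    founder_size = 25,
    source_deme = 5L,
    ne = c(2000, 2000, 2000, 2000, 2000, 2000, 1000, 2000, 2000,
           2000, 2000, 2000, 2000, 2000, 1000, 200),
    mu = 2.5e-8, locus_length = 85L, n_loci = 10000L
  )
}

# stepping-stone chains of the 16-deme layout: mainland 1..9 (deme 1 the
# persisting refugial deme), island pair 10-11 (no natural exchange with the
# mainland), introduced chain 12..16
.paper_chains <- function() list(1:9, 10:11, 12:16)

.range_of <- function() rep(c("native", "introduced"), c(11L, 5L))

.natural_matrix <- function(M_N, n_demes = 16L, chains = .paper_chains()) {
  m <- matrix(0, n_demes, n_demes)
  for (ch in chains) {
    if (length(ch) < 2) next
    for (k in seq_len(length(ch) - 1L)) {
      i <- ch[k]; j <- ch[k + 1L]
      m[i, j] <- m[i, j] + M_N
      m[j, i] <- m[j, i] + M_N
    }
  }
  m
}

.human_matrix <- function(M_N, M_H, ranges, chains = .paper_chains()) {
  m <- .natural_matrix(M_N, length(ranges), chains)
  for (rg in unique(ranges)) {
    idx <- which(ranges == rg)
    for (i in idx) for (j in idx) if (i != j) m[i, j] <- m[i, j] + M_H
  }
  m
}

#' Build the 16-deme study model
#'
#' Constructs the full demographic scenario: postglacial colonization from a
#' refugium at `colonization_time`; a persisting refugial mainland deme
#' (deme 1) plus mainland stepping-stone demes 2-9; an island pair 10-11
#' exchanging migrants only with each other; five introduced demes 12-16
#' founded 800 generations before present from mainland deme 5 through a
#' 25-diploid founder bottleneck; and three migration epochs — natural-only
#' for the most recent 200 generations, natural plus all-to-all within-range
#' human-mediated migration for the preceding 1,800 generations, and
#' natural-only before that.
#'
#' Effective sizes are 2,000 diploids everywhere except demes 7 and 15
#' (1,000) and deme 16 (200).
#'
#' @param M_N per-generation natural (stepping-stone) migration rate
#' @param M_H per-generation human-mediated migration rate, added all-to-all
#'   within each range during the human-mediated epoch
#' @param overrides optional named list; recognized names:
#'   `human_start`, `human_end`, `introduction_time`, `colonization_time`,
#'   `refugium_ne`, `founder_size`, `source_deme`, `ne` (length 16),
#'   `mu`, `locus_length`, `n_loci`
#' @return a [demographic_model()]
#' @examples
#' m <- build_paper_model(5e-4, 5e-4)
#' m$demes$ne
#' @export
build_paper_model <- function(M_N, M_H, overrides = list()) {
  if (M_N < 0 || M_H < 0) stop("migration rates must be nonnegative")
  p <- .paper_defaults()
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown))
    stop("unknown override parameter(s): ", paste(unknown, collapse = ", "))
  p[names(overrides)] <- overrides
  if (length(p$ne) != 16L) stop("`ne` override must have length 16")

  ranges <- .range_of()
  habitat <- c("refugium-mainland", rep("mainland", 8L), rep("island", 2L),
               rep("introduced", 5L))
  # postglacial expansion: serial stepping-stone colonization out of the
  # refugial deme, one founding per expansion_step generations along the
  # mainland chain (1 -> 2 -> ... -> 9) and onto the islands (1 -> 10 -> 11)
  step <- p$expansion_step
  ft_mainland <- p$colonization_time - step * (1:8)
  ft_islands <- p$colonization_time - step * (1:2)
  if (any(c(ft_mainland, ft_islands) <= p$human_end))
    stop("expansion_step too large: colonization overlaps the human-mediated window")
  demes <- data.frame(
    id = 1:16,
    label = c(paste0("M", 1:9), paste0("I", 10:11), paste0("X", 12:16)),
    range = ranges, habitat = habitat, ne = p$ne,
    founding_time = c(0, ft_mainland, ft_islands,
                      rep(p$introduction_time, 5L)),
    source_deme = c(NA_integer_, 1:8, 1L, 10L,
                    rep(as.integer(p$source_deme), 5L)),
    founder_size = c(rep(NA_real_, 11L), rep(p$founder_size, 5L)),
    stringsAsFactors = FALSE)

  chains <- .paper_chains()
  nat <- .natural_matrix(M_N, 16L, chains)
  hum <- .human_matrix(M_N, M_H, ranges, chains)
  # in the pre-human epoch the introduced demes never exist: zero their block
  nat_old <- nat
  nat_old[12:16, ] <- 0
  nat_old[, 12:16] <- 0
  epochs <- list(
    list(start_gen = 0,            end_gen = p$human_start, matrix = nat),
    list(start_gen = p$human_start, end_gen = p$human_end,  matrix = hum),
    list(start_gen = p$human_end,  end_gen = Inf,           matrix = nat_old))

  demographic_model(
    demes = demes, epochs = epochs,
    mutation = mutation_model(p$mu, p$locus_length, p$n_loci),
    colonization_time = p$colonization_time, refugium_ne = p$refugium_ne,
    chains = chains,
    params = list(M_N = M_N, M_H = M_H, human_start = p$human_start,
                  human_end = p$human_end,
                  introduction_time = p$introduction_time))
}

#' Migration matrix in force at a given time
#'
#' @param model a [demographic_model()]
#' @param t generations before present (>= 0)
#' @return the matrix of the unique epoch whose `[start_gen, end_gen)`
#'   interval contains `t`
#' @export
migration_matrix_at <- function(model, t) {
  if (!is.numeric(t) || length(t) != 1 || t < 0)
    stop("`t` must be a single nonnegative number of generations")
  for (e in model$epochs)
    if (t >= e$start_gen && t < e$end_gen) return(e$matrix)
  stop("no epoch contains t = ", t)  # unreachable for a valid model
}

# existence interval of a deme, backward time: [0, end)
.deme_exists_until <- function(model) {
  ft <- model$demes$founding_time
  ifelse(ft == 0, Inf, ft)
}

#' Validate a demographic model
#'
#' Checks every structural invariant (deme fields, epoch tiling, matrix
#' nonnegativity and row sums, entries into demes that never exist during an
#' epoch) and reports violations rather than erroring.
#'
#' @param model a `demographic_model` (possibly malformed)
#' @return character vector of human-readable violations; empty when valid
#' @export
validate_model <- function(model) {
  v <- character()
  d <- model$demes
  if (any(d$ne < 1)) v <- c(v, sprintf("deme %d: Ne < 1", d$id[d$ne < 1]))
  if (any(d$founding_time < 0))
    v <- c(v, sprintf("deme %d: negative founding_time",
                      d$id[d$founding_time < 0]))
  bad_src <- xor(d$founding_time > 0, !is.na(d$source_deme))
  if (any(bad_src))
    v <- c(v, sprintf("deme %d: source_deme must be given iff founding_time > 0",
                      d$id[bad_src]))
  if (any(d$founding_time > model$colonization_time))
    v <- c(v, sprintf("deme %d: founded before colonization_time",
                      d$id[d$founding_time > model$colonization_time]))

  ep <- model$epochs
  if (length(ep) == 0) return(c(v, "no epochs"))
  if (ep[[1]]$start_gen != 0) v <- c(v, "first epoch must start at 0")
  if (is.finite(ep[[length(ep)]]$end_gen))
    v <- c(v, "last epoch must extend to Inf")
  if (length(ep) > 1)
    for (k in seq_len(length(ep) - 1L))
      if (ep[[k]]$end_gen != ep[[k + 1L]]$start_gen)
        v <- c(v, sprintf("epoch gap/overlap between [%g,%g) and [%g,%g)",
                          ep[[k]]$start_gen, ep[[k]]$end_gen,
                          ep[[k + 1L]]$start_gen, ep[[k + 1L]]$end_gen))

  exist_until <- .deme_exists_until(model)
  for (k in seq_along(ep)) {
    m <- ep[[k]]$matrix
    if (nrow(m) != nrow(d) || ncol(m) != nrow(d)) {
      v <- c(v, sprintf("epoch %d: matrix is not %d x %d", k, nrow(d), nrow(d)))
      next
    }
    if (any(m < 0)) v <- c(v, sprintf("epoch %d: negative migration entry", k))
    off <- m; diag(off) <- 0
    rs <- rowSums(off)
    if (any(rs > 1))
      v <- c(v, sprintf("epoch %d: off-diagonal row sum %.3g > 1 in row %d",
                        k, max(rs), which.max(rs)))
    # a deme absent for the whole epoch must have zero entries
    absent <- which(exist_until <= ep[[k]]$start_gen)
    if (length(absent)) {
      bad <- union(absent[rowSums(off[absent, , drop = FALSE]) > 0],
                   absent[colSums(off[, absent, drop = FALSE]) > 0])
      if (length(bad))
        v <- c(v, sprintf("epoch %d: migration to/from deme(s) %s which do not exist during it",
                          k, paste(d$id[sort(bad)], collapse = ",")))
    }
  }
  v
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("Demographic model: %d demes, %d epochs\n",
              nrow(x$demes), length(x$epochs)))
  if (!is.null(x$params$M_N))
    cat(sprintf("  M_N = %g, M_H = %g\n", x$params$M_N, x$params$M_H))
  cat(sprintf("  colonization %g gen BP (refugium Ne %g), %g gen/yr\n",
              x$colonization_time, x$refugium_ne, x$generations_per_year))
  cat(sprintf("  mutation: mu = %g, %d loci x %d bp\n",
              x$mutation$mu, x$mutation$n_loci, x$mutation$locus_length))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Sampling plans
# ---------------------------------------------------------------------------

#' Construct a sampling plan
#'
#' Each entry samples `n_diploids` diploid individuals from one deme at one
#' time point (generations before present). A deme may not be sampled before
#' it exists; sampling exactly at a deme's founding time is allowed and
#' yields founders drawn immediately after the founding event.
#'
#' @param deme_id,n_diploids,sample_time parallel vectors (recycled)
#' @return a data frame of class `sampling_plan`
#' @export
sampling_plan <- function(deme_id, n_diploids = 6L, sample_time = 0) {
  p <- data.frame(deme_id = as.integer(deme_id),
                  n_diploids = as.integer(n_diploids),
                  sample_time = as.numeric(sample_time))
  if (any(p$n_diploids < 1)) stop("n_diploids must be >= 1")
  if (any(p$sample_time < 0)) stop("sample_time must be >= 0")
  class(p) <- c("sampling_plan", "data.frame")
  p
}

#' Sampling plans for the study designs
#'
#' `present_day_plan()` samples every deme at the present;
#' `serial_plan()` samples every deme extant at each requested past time
#' point (introduced demes enter the plan from their founding time onward).
#'
#' @param model a [demographic_model()]
#' @param n_diploids diploids per deme per time point
#' @param times generations before present
#' @return a [sampling_plan()]
#' @export
present_day_plan <- function(model, n_diploids = 6L)
  sampling_plan(model$demes$id, n_diploids, 0)

#' @rdname present_day_plan
#' @export
serial_plan <- function(model, times, n_diploids = 6L) {
  exist_until <- .deme_exists_until(model)
  rows <- do.call(rbind, lapply(times, function(tt) {
    ok <- exist_until >= tt & tt <= model$colonization_time
    data.frame(deme_id = model$demes$id[ok], n_diploids = n_diploids,
               sample_time = tt)
  }))
  sampling_plan(rows$deme_id, rows$n_diploids, rows$sample_time)
}

.validate_plan <- function(model, plan) {
  stopifnot(is.data.frame(plan), nrow(plan) >= 1)
  exist_until <- .deme_exists_until(model)
  bad <- !(plan$deme_id %in% model$demes$id)
  if (any(bad)) stop("plan references unknown deme id(s): ",
                     paste(unique(plan$deme_id[bad]), collapse = ", "))
  eu <- exist_until[match(plan$deme_id, model$demes$id)]
  late <- plan$sample_time > eu
  if (any(late))
    stop("cannot sample deme(s) before they exist: ",
         paste(sprintf("deme %d at t=%g", plan$deme_id[late],
                       plan$sample_time[late]), collapse = "; "))
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Plain-text model configuration (YAML)
# ---------------------------------------------------------------------------

#' Read / write a model configuration file
#'
#' Serializes a [demographic_model()] to a nested key-value (YAML) file and
#' reconstructs it exactly. Migration matrices are not stored verbatim: they
#' are rebuilt from the stepping-stone chains, ranges and the `M_N`/`M_H`
#' rates, so the file stays human-editable. A bundled configuration
#' reproducing the study model is at
#' `system.file("extdata", "paper_model.yaml", package = "phylodrift")`.
#'
#' @param model a [demographic_model()]
#' @param path file path
#' @return `read_model_config()` returns a [demographic_model()];
#'   `write_model_config()` returns `path` invisibly
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    params = model$params,
    mutation = unclass(model$mutation),
    colonization_time = model$colonization_time,
    refugium_ne = model$refugium_ne,
    generations_per_year = model$generations_per_year,
    chains = lapply(model$chains, as.integer),
    demes = lapply(seq_len(nrow(model$demes)), function(i) {
      r <- as.list(model$demes[i, ])
      r$source_deme <- if (is.na(r$source_deme)) NULL else r$source_deme
      r$founder_size <- if (is.na(r$founder_size)) NULL else r$founder_size
      r
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  demes <- do.call(rbind, lapply(cfg$demes, function(r) {
    data.frame(id = as.integer(r$id), label = r$label, range = r$range,
               habitat = r$habitat, ne = r$ne,
               founding_time = r$founding_time,
               source_deme = if (is.null(r$source_deme)) NA_integer_
                             else as.integer(r$source_deme),
               founder_size = if (is.null(r$founder_size)) NA_real_
                              else r$founder_size,
               stringsAsFactors = FALSE)
  }))
  chains <- lapply(cfg$chains, as.integer)
  p <- cfg$params
  nat <- .natural_matrix(p$M_N, nrow(demes), chains)
  hum <- .human_matrix(p$M_N, p$M_H, demes$range, chains)
  never <- .deme_exists_until_df(demes) <= p$human_end
  nat_old <- nat
  nat_old[never, ] <- 0
  nat_old[, never] <- 0
  epochs <- list(
    list(start_gen = 0, end_gen = p$human_start, matrix = nat),
    list(start_gen = p$human_start, end_gen = p$human_end, matrix = hum),
    list(start_gen = p$human_end, end_gen = Inf, matrix = nat_old))
  demographic_model(
    demes = demes, epochs = epochs,
    mutation = do.call(mutation_model, cfg$mutation),
    colonization_time = cfg$colonization_time,
    refugium_ne = cfg$refugium_ne,
    generations_per_year = cfg$generations_per_year,
    chains = chains, params = p)
}

.deme_exists_until_df <- function(demes)
  ifelse(demes$founding_time == 0, Inf, demes$founding_time)
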