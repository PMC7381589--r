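# ---------------------------------------------------------------------------
# Orchestration: the nine-scenario migration grid and the serial-sampling
# time series, with deterministic seed derivation and TSV reporting.
# ---------------------------------------------------------------------------

#' The nine grid scenarios
#'
#' Scenarios A-I cross natural migration `M_N` in \{5e-6, 5e-5, 5e-4\} with
#' human-mediated migration an order of magnitude below, equal to, and an
#' order of magnitude above `M_N`.
#'
#' @return data frame with columns `scenario`, `M_N`, `M_H`
#' @export
grid_scenarios <- function() {
  M_N <- rep(c(5e-6, 5e-5, 5e-4), each = 3)
  data.frame(scenario = LETTERS[1:9], M_N = M_N,
             M_H = M_N * rep(c(0.1, 1, 10), 3))
}

#' Configuration for grid and time-series runs
#'
#' @param n_loci unlinked loci per simulated dataset
#' @param replicates independent replicate simulations per scenario
#' @param seed base seed; every per-run seed is derived from it
#' @param n_diploids diploids sampled per deme per time point
#' @param maf_threshold minor-allele-frequency cutoff
#' @param fast convenience switch: 2,000 loci and 10 replicates
#' @param scenarios subset of `LETTERS[1:9]` (grid runs only)
#' @return named list
#' @export
run_config <- function(n_loci = 10000, replicates = 5, seed = 1,
                       n_diploids = 6, maf_threshold = 0.01,
                       fast = FALSE, scenarios = LETTERS[1:9]) {
  if (fast) { n_loci <- 2000; replicates <- 10 }
  list(n_loci = as.integer(n_loci), replicates = as.integer(replicates),
       seed = as.integer(seed), n_diploids = as.integer(n_diploids),
       maf_threshold = maf_threshold, scenarios = scenarios)
}

# distinct sub-2^31 seed per (stream, replicate)
.derive_seed <- function(base, stream, replicate)
  as.integer((as.numeric(base) + 7919 * stream + 104729 * replicate) %% 2147483647)

#' Run the migration grid
#'
#' Simulates each requested scenario `replicates` times (6 diploids per deme
#' sampled at present by default), ascertains SNPs (first SNP per locus,
#' maf filter), computes the population-level p-distance matrix and the mean
#' quartet Delta per replicate. Fully deterministic given `config$seed`.
#'
#' @param config a [run_config()]
#' @return data frame of class `scenario_result`, one row per
#'   scenario x replicate, with a `pooled` attribute of per-scenario means
#' @export
run_grid <- function(config = run_config()) {
  sc <- grid_scenarios()
  unknown <- setdiff(config$scenarios, sc$scenario)
  if (length(unknown))
    stop("unknown scenario label(s): ", paste(unknown, collapse = ", "))
  sc <- sc[sc$scenario %in% config$scenarios, ]
  rows <- list()
  for (si in seq_len(nrow(sc))) {
    model <- build_paper_model(sc$M_N[si], sc$M_H[si])
    plan <- present_day_plan(model, config$n_diploids)
    for (r in seq_len(config$replicates)) {
      seed_r <- .derive_seed(config$seed, match(sc$scenario[si], LETTERS), r)
      G <- simulate_dataset(model, plan, seed = seed_r,
                            n_loci = config$n_loci,
                            maf_threshold = config$maf_threshold)
      dl <- delta_score(p_distance(G, "population"))
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$scenario[si], M_N = sc$M_N[si], M_H = sc$M_H[si],
        time_gen = 0, years_bp = 0, replicate = r, seed = seed_r,
        n_snps = ncol(G$dosage), delta = dl$mean)
    }
  }
  .as_scenario_result(do.call(rbind, rows))
}

#' Run the serial-sampling time series
#'
#' A single demographic scenario (`M_N = M_H = 5e-4` by default) is
#' simulated with serial samples at 2,000, 1,800, 1,600, 800, 200 and 0
#' generations before present (1,000 ... 0 years at two generations per
#' year). A deme is sampled at a time point only once founded, so the five
#' introduced demes enter at 800 generations BP. Each time point is treated
#' as its own dataset: SNPs are ascertained (first segregating site per
#' locus, maf filter) within the individuals sampled at that time, and the
#' population-level mean Delta is computed over the demes sampled then.
#'
#' @param config a [run_config()]
#' @param M_N,M_H migration rates of the single simulated scenario
#' @param times_gen sampling times in generations before present
#' @return data frame of class `scenario_result`, one row per
#'   time point x replicate
#' @export
run_time_series <- function(config = run_config(), M_N = 5e-4, M_H = 5e-4,
                            times_gen = c(2000, 1800, 1600, 800, 200, 0)) {
  model <- build_paper_model(M_N, M_H)
  plan <- serial_plan(model, times_gen, config$n_diploids)
  tp <- .plan_tips(model, plan)
  rows <- list()
  for (r in seq_len(config$replicates)) {
    seed_r <- .derive_seed(config$seed, 600, r)
    v <- simulate_variants(model, plan, config$n_loci, seed_r)
    for (tt in times_gen) {
      sub_plan <- plan[plan$sample_time == tt, ]
      tip_idx <- which(tp$tip_time == tt)
      sv <- .subset_variants(v, tip_idx)
      G <- extract_snp_matrix(sv, model, sub_plan, config$maf_threshold,
                              meta = list(seed = seed_r, time_gen = tt))
      dl <- delta_score(p_distance(G, "population"))
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = "timeseries", M_N = M_N, M_H = M_H,
        time_gen = tt, years_bp = tt / model$generations_per_year,
        replicate = r, seed = seed_r, n_snps = ncol(G$dosage),
        delta = dl$mean)
    }
  }
  .as_scenario_result(do.call(rbind, rows))
}

# restrict per-locus variant sets to a subset of tips (old 1-based indices),
# dropping sites monomorphic within the subset
.subset_variants <- function(variants, tip_idx) {
  n_sub <- length(tip_idx)
  lapply(variants, function(v) {
    if (length(v$pos) == 0) return(list(pos = integer(0), derived = list()))
    keep_pos <- integer(0); keep_der <- list()
    for (k in seq_along(v$pos)) {
      dt <- match(v$derived[[k]], tip_idx)
      dt <- dt[!is.na(dt)]
      if (length(dt) == 0 || length(dt) == n_sub) next
      keep_pos <- c(keep_pos, v$pos[k])
      keep_der[[length(keep_der) + 1L]] <- dt
    }
    list(pos = keep_pos, derived = keep_der)
  })
}

.as_scenario_result <- function(df) {
  pooled <- aggregate(delta ~ scenario + M_N + M_H + time_gen + years_bp,
                      data = df, FUN = mean)
  pooled <- pooled[order(pooled$scenario, -pooled$time_gen), ]
  sds <- aggregate(delta ~ scenario + time_gen, data = df, FUN = sd)
  pooled$delta_sd <- sds$delta[match(paste(pooled$scenario, pooled$time_gen),
                                     paste(sds$scenario, sds$time_gen))]
  attr(df, "pooled") <- pooled
  class(df) <- c("scenario_result", "data.frame")
  df
}

#' Per-scenario pooled means of a `scenario_result`
#'
#' @param x a `scenario_result` from [run_grid()] or [run_time_series()]
#' @return data frame of replicate means (and SDs) per scenario/time point
#' @export
pooled_delta <- function(x) attr(x, "pooled")

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario results (", length(unique(x$replicate)), " replicate(s))\n",
      sep = "")
  print(pooled_delta(x), row.names = FALSE)
  invisible(x)
}

#' Write run reports
#'
#' Writes a Table-2-style TSV of pooled Delta values (`table_delta.tsv`),
#' the per-replicate table (`replicates.tsv`), a configuration echo
#' (`config.yaml`), a seed manifest (`seeds.tsv`) and a short log.
#'
#' @param results a `scenario_result`
#' @param out_dir output directory (created if needed)
#' @param config the [run_config()] used (echoed verbatim)
#' @return invisibly, the paths written
#' @export
report <- function(results, out_dir, config = NULL) {
  if (is.null(results) || nrow(results) == 0) stop("no results to report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("table_delta.tsv", "replicates.tsv",
                                "config.yaml", "seeds.tsv", "run.log"))
  pooled <- pooled_delta(results)
  write.table(format(pooled, digits = 8), paths[1], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(format(as.data.frame(results), digits = 8), paths[2],
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config)) yaml::write_yaml(config, paths[3])
  write.table(unique(results[c("scenario", "time_gen", "replicate", "seed")]),
              paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("phylodrift run, %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("rows: %d; scenarios: %s", nrow(results),
                       paste(unique(results$scenario), collapse = " "))),
             paths[5])
  invisible(paths)
}

#' @importFrom stats aggregate
NULL
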