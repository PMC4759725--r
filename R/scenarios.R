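#' Scaling parameter for genomic-prediction accuracy
#'
#' `lambda = T h2 / (M L)`, where `T` is the number of training
#' individuals, `h2` the heritability, `M` the effective number of loci per
#' Morgan (about `2 Ne`) and `L` the genome length in Morgan.  Designs with
#' equal lambda yield approximately equal prediction accuracy, which
#' justifies simulating a 1-Morgan genome with 200 training individuals in
#' place of a 30-Morgan genome with 6000.
#'
#' @param t_train Training-set size.
#' @param h2 Heritability.
#' @param m_loci Effective loci per Morgan.
#' @param genome_length Genome length in Morgan.
#' @return The scalar lambda.
#' @export
#' @examples
#' scaling_lambda(6000, 0.3, 400, 30) # 0.15
#' scaling_lambda(200, 0.3, 400, 1)   # 0.15
scaling_lambda <- function(t_train, h2, m_loci, genome_length) {
  stopifnot(t_train > 0, h2 >= 0, m_loci > 0, genome_length > 0)
  t_train * h2 / (m_loci * genome_length)
}

#' Evaluation scenario configuration
#'
#' The four reference/validation designs:
#' \describe{
#'   \item{1}{within-population: reference 200 A, validation 300 A;}
#'   \item{2}{across-population: reference 200 A, validation 300 B;}
#'   \item{3}{multi-breed: reference 200 A + 200 B, validation 300 A;}
#'   \item{4}{enlarged single-breed: reference 400 A, validation 300 A.}
#' }
#'
#' @param scenario Integer 1-4.
#' @param divergence Generations of divergence `T` between A and B (10 or
#'   50 in the default designs); total simulated depth is
#'   `total_generations`.
#' @param n_qtl Number of QTL (45 or 132).
#' @param h2 Trait heritability (0.30 or 0.07).
#' @param panel Panel name: `"wgs"`, `"data3000"`, `"data2000"`,
#'   `"data1000"` or `"data200"`.
#' @param method `"snp_blup"` or `"mixp"`.
#' @param total_generations Total generations from founders to census
#'   (default 2000); the burn-in is `total_generations - divergence`.
#' @param ne Effective size per population (default 200).
#' @return An object of class `scenario_config` (also a one-row data
#'   frame).
#' @export
scenario_config <- function(scenario = 1, divergence = 50, n_qtl = 45,
                            h2 = 0.30, panel = "wgs", method = "snp_blup",
                            total_generations = 2000, ne = 200) {
  stopifnot(scenario %in% 1:4, divergence >= 0,
            divergence <= total_generations,
            method %in% c("snp_blup", "mixp"))
  out <- data.frame(scenario = as.integer(scenario),
                    divergence = as.integer(divergence),
                    n_qtl = as.integer(n_qtl), h2 = h2,
                    panel = panel, method = method,
                    total_generations = as.integer(total_generations),
                    ne = as.integer(ne),
                    stringsAsFactors = FALSE)
  class(out) <- c("scenario_config", "data.frame")
  out
}

# Deterministic child seeds for the independent random streams of one
# replicate: simulation, sampling partitions, QTL draw, phenotype noise and
# panel subsampling.  Keeping the streams separate lets phenotypes be
# resampled (e.g. across heritabilities) on fixed genotypes.
replicate_seeds <- function(master) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(master)
  s <- sample.int(.Machine$integer.max, 5L)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(sim = s[1L], partition = s[2L], qtl = s[3L], pheno = s[4L],
       panel = s[5L])
}

#' Simulate one population replicate
#'
#' Runs the burn-in, the split into populations A and B, the divergence
#' generations and the census expansion; computes the MAF-filtered variant
#' table on the pooled final samples; and draws the reference/validation
#' partitions.  The heavy genotype state can then be reused across QTL
#' draws, panels, methods and heritabilities.
#'
#' @param design A [split_design()].
#' @param genome A [genome_spec()].
#' @param seed Master seed for the replicate.
#' @param min_maf Variants are retained when their pooled minor-allele
#'   frequency exceeds this (default 0.02).
#' @param max_reference Largest single-population reference size any
#'   evaluated scenario will need (default `design$reference_size`); the
#'   smaller reference sets are nested inside the largest one.
#' @return An object of class `sim_replicate` holding the populations, the
#'   variant table and the sampled individual partitions.
#' @export
simulate_replicate <- function(design = split_design(),
                               genome = genome_spec(), seed,
                               min_maf = 0.02,
                               max_reference = design$reference_size) {
  seeds <- replicate_seeds(seed)
  set.seed(seeds$sim)
  base <- run_base_population(genome, design$ne,
                              design$burn_in_generations)
  pops <- split_and_propagate(base, design)
  vt <- variant_table(pops$A, pops$B, min_maf = min_maf)

  nA <- pops$A$n; nB <- pops$B$n
  vsize <- design$validation_size
  if (vsize + max_reference > nA)
    stop("census of A too small for validation + largest reference",
         call. = FALSE)
  set.seed(seeds$partition)
  permA <- sample.int(nA)
  permB <- sample.int(nB)
  refA <- lapply(unique(c(design$reference_size, max_reference)),
                 function(k) sort(permA[vsize + seq_len(k)]))
  names(refA) <- paste0("ref", unique(c(design$reference_size,
                                        max_reference)))
  structure(
    list(design = design, genome = genome, seed = seed, seeds = seeds,
         A = pops$A, B = pops$B, vt = vt,
         valA = sort(permA[seq_len(vsize)]),
         refA = refA,
         valB = sort(permB[seq_len(min(vsize, nB))]),
         refB = sort(permB[min(vsize, nB) + seq_len(min(design$reference_size,
                                                        nB - vsize))])),
    class = "sim_replicate")
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat(sprintf(
    "sim_replicate (seed %d): T = %d, census A/B = %d/%d, %d variants (MAF filter)\n",
    x$seed, x$design$divergence_generations, x$A$n, x$B$n, nrow(x$vt)))
  invisible(x)
}

#' Attach trait, panels and genotype caches to a simulated replicate
#'
#' Draws the QTL set (standardizing effects against population A's
#' frequencies), computes true genetic values and per-population
#' environmental calibrations, draws the SNP panels, and caches dosage
#' matrices for every panel in both populations.
#'
#' @param st A [simulate_replicate()] result.
#' @param n_qtl Number of QTL to sample.
#' @param panel_sizes SNP panel sizes (default `c(3000, 2000, 1000, 200)`);
#'   sizes exceeding the available non-QTL loci are dropped with a warning.
#' @param standardize_freq Frequency column of the variant table used to
#'   standardize QTL effects (default `"freq_A"`).
#' @return An object of class `trait_state`.
#' @export
trait_state <- function(st, n_qtl, panel_sizes = c(3000, 2000, 1000, 200),
                        standardize_freq = "freq_A") {
  stopifnot(inherits(st, "sim_replicate"))
  set.seed((st$seeds$qtl + n_qtl) %% .Machine$integer.max)
  qtl <- sample_qtl(st$vt, n_qtl, freq_col = standardize_freq)

  g <- list(A = genetic_values(dosage_matrix(st$A, qtl$position), qtl$a),
            B = genetic_values(dosage_matrix(st$B, qtl$position), qtl$a))
  var_g <- lapply(g, var)

  set.seed(st$seeds$pheno)
  e_std <- list(A = rnorm(st$A$n), B = rnorm(st$B$n))

  n_avail <- nrow(st$vt) - n_qtl
  sizes <- panel_sizes[panel_sizes <= n_avail]
  if (length(sizes) < length(panel_sizes))
    warning("dropping panel sizes exceeding the available non-QTL loci",
            call. = FALSE)
  set.seed((st$seeds$panel + n_qtl) %% .Machine$integer.max)
  panels <- build_panels(st$vt, qtl, sizes)

  dosages <- lapply(list(A = st$A, B = st$B), function(pop) {
    lapply(panels, function(pn) dosage_matrix(pop, pn$positions))
  })
  structure(list(rep = st, n_qtl = n_qtl, qtl = qtl, g = g, var_g = var_g,
                 e_std = e_std, panels = panels, dosages = dosages),
            class = "trait_state")
}

# Reference and validation wiring of the four scenarios.
scenario_wiring <- function(ts, scenario) {
  st <- ts$rep
  ref200 <- st$refA[[1L]]
  switch(as.character(scenario),
    "1" = list(ref = list(A = ref200), val_pop = "A", val = st$valA),
    "2" = list(ref = list(A = ref200), val_pop = "B", val = st$valB),
    "3" = list(ref = list(A = ref200, B = st$refB), val_pop = "A",
               val = st$valA),
    "4" = {
      big <- st$refA[[length(st$refA)]]
      if (length(big) <= length(ref200))
        stop("scenario 4 needs a replicate simulated with max_reference ",
             "> reference_size (and a census that accommodates it)",
             call. = FALSE)
      list(ref = list(A = big), val_pop = "A", val = st$valA)
    },
    stop("scenario must be 1, 2, 3 or 4", call. = FALSE))
}

#' Run one scenario evaluation on a prepared replicate
#'
#' Wires the scenario's reference and validation sets, generates reference
#' phenotypes at the requested heritability (calibrating the environmental
#' variance per population against its realized genetic variance), fits
#' the requested method on the requested panel, predicts GEBV for the
#' validation individuals and scores the accuracy.
#'
#' @param ts A [trait_state()].
#' @param scenario Integer 1-4 (see [scenario_config()]).
#' @param panel Panel name present in `ts$panels`.
#' @param method `"snp_blup"` or `"mixp"`.
#' @param h2 Heritability.
#' @param pi Prior large-component probability for MixP; default
#'   `n_qtl / n_markers`.
#' @return A list with `accuracy`, `n_markers` (after monomorphic drops),
#'   and the `fit_result`.
#' @export
evaluate_scenario <- function(ts, scenario = 1, panel = "wgs",
                              method = "snp_blup", h2 = 0.30, pi = NULL) {
  stopifnot(inherits(ts, "trait_state"))
  if (!panel %in% names(ts$panels))
    stop("unknown panel '", panel, "'", call. = FALSE)
  wiring <- scenario_wiring(ts, scenario)

  ref_pops <- names(wiring$ref)
  G_ref <- do.call(rbind, lapply(ref_pops, function(p)
    ts$dosages[[p]][[panel]][wiring$ref[[p]], , drop = FALSE]))
  G_val <- ts$dosages[[wiring$val_pop]][[panel]][wiring$val, , drop = FALSE]
  rs <- reference_standardization(G_ref, G_val)

  # phenotypes: per-population environmental calibration, shared noise
  # stream across heritabilities
  y <- unlist(lapply(ref_pops, function(p) {
    ids <- wiring$ref[[p]]
    tr <- trait_spec(h2, var_g = ts$var_g[[p]])
    simulate_phenotypes(ts$g[[p]][ids], tr, e_std = ts$e_std[[p]][ids])
  }), use.names = FALSE)

  g_ref <- unlist(lapply(ref_pops, function(p) ts$g[[p]][wiring$ref[[p]]]),
                  use.names = FALSE)
  var_g_ref <- var(g_ref)
  n_ref_each <- lengths(wiring$ref)
  sigma_e2 <- sum(vapply(ref_pops, function(p)
    ts$var_g[[p]] * (1 - h2) / h2, numeric(1)) * n_ref_each) /
    sum(n_ref_each)

  nm <- ncol(rs$X_ref)
  fit <- if (method == "snp_blup") {
    fit_snp_blup(y, rs$X_ref, sigma_b2 = var_g_ref / nm, sigma_e2 = sigma_e2)
  } else if (method == "mixp") {
    if (is.null(pi)) pi <- ts$n_qtl / nm
    mv <- mixp_variances(pi, var_g_ref, nm)
    fit_mixp_ice(y, rs$X_ref, pi, mv$sigma1_2, mv$sigma2_2, sigma_e2)
  } else stop("unknown method '", method, "'", call. = FALSE)

  g_hat <- predict_gebv(rs$X_val, fit)
  list(accuracy = prediction_accuracy(ts$g[[wiring$val_pop]][wiring$val],
                                      g_hat),
       n_markers = nm, n_dropped = rs$n_dropped, fit = fit)
}

#' Run one full replicate of a single configuration
#'
#' Convenience wrapper executing simulate -> trait -> panels -> fit ->
#' predict -> accuracy for one [scenario_config()] and one replicate seed.
#' When several configurations share a replicate, prefer
#' [run_replication_design()], which shares the simulated genotypes.
#'
#' @param config A [scenario_config()].
#' @param seed Replicate master seed.
#' @param genome A [genome_spec()].
#' @return A list with `accuracy`, `n_markers`, `fit` and the replicate
#'   states (`rep`, `trait`).
#' @export
run_replicate <- function(config, seed, genome = genome_spec()) {
  stopifnot(inherits(config, "scenario_config"))
  max_ref <- if (config$scenario == 4) 400L else 200L
  census_a <- if (config$scenario == 4) 300L + 400L else 500L
  design <- split_design(
    burn_in_generations = config$total_generations - config$divergence,
    divergence_generations = config$divergence,
    ne = config$ne, census_a = census_a, census_b = 500L,
    reference_size = 200L, validation_size = 300L)
  st <- simulate_replicate(design, genome, seed, max_reference = max_ref)
  ts <- trait_state(st, config$n_qtl)
  out <- evaluate_scenario(ts, config$scenario, config$panel, config$method,
                           config$h2)
  out$rep <- st
  out$trait <- ts
  out
}

#' Run a replicated grid of evaluation configurations
#'
#' Simulates `n_reps` replicates per divergence time and evaluates every
#' configuration of the grid on each replicate.  Within a replicate, the
#' simulated populations are shared across heritabilities, panels and
#' methods (only the QTL draw, phenotype noise and panel subsampling use
#' their own child streams), mirroring the phenotype-resampling replication
#' design.  Separate replicate sets are simulated per divergence time.
#'
#' @param grid Data frame of configurations with columns `scenario`,
#'   `divergence`, `n_qtl`, `h2`, `panel`, `method` (e.g. rbind of
#'   [scenario_config()] rows).
#' @param n_reps Number of replicates per divergence time.
#' @param master_seed Master seed; replicate seeds are derived from it.
#' @param genome A [genome_spec()].
#' @param total_generations,ne See [scenario_config()].
#' @param panel_sizes Panel sizes simulated per replicate.
#' @param progress Print one line per replicate (default FALSE).
#' @return Data frame of per-replicate results (one row per configuration
#'   by replicate) with columns of the grid plus `rep`, `accuracy`,
#'   `n_markers`; pass to [summarize_replicates()].  Per-replicate
#'   diagnostics are attached as attributes: `"replicates"` (divergence,
#'   rep, n_variants) and `"panels"` (divergence, rep, n_qtl, panel, size,
#'   spacing_kb).
#' @export
run_replication_design <- function(grid, n_reps, master_seed,
                                   genome = genome_spec(),
                                   total_generations = 2000, ne = 200,
                                   panel_sizes = c(3000, 2000, 1000, 200),
                                   progress = FALSE) {
  stopifnot(nrow(grid) >= 1, n_reps >= 1)
  needed <- c("scenario", "divergence", "n_qtl", "h2", "panel", "method")
  missing_cols <- setdiff(needed, names(grid))
  if (length(missing_cols))
    stop("grid lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  t_values <- sort(unique(grid$divergence))
  set.seed(master_seed)
  seed_mat <- matrix(sample.int(.Machine$integer.max,
                                n_reps * length(t_values)),
                     nrow = n_reps,
                     dimnames = list(NULL, as.character(t_values)))

  rows <- list()
  rep_info <- list()
  panel_info <- list()
  for (tv in t_values) {
    g_t <- grid[grid$divergence == tv, , drop = FALSE]
    has_s4 <- any(g_t$scenario == 4)
    design <- split_design(
      burn_in_generations = total_generations - tv,
      divergence_generations = tv, ne = ne,
      census_a = if (has_s4) 700L else 500L, census_b = 500L,
      reference_size = 200L, validation_size = 300L)
    for (r in seq_len(n_reps)) {
      st <- simulate_replicate(design, genome,
                               seed = seed_mat[r, as.character(tv)],
                               max_reference = if (has_s4) 400L else 200L)
      rep_info[[length(rep_info) + 1L]] <-
        data.frame(divergence = tv, rep = r, n_variants = nrow(st$vt))
      for (nq in sort(unique(g_t$n_qtl))) {
        ts <- trait_state(st, nq, panel_sizes = panel_sizes)
        panel_info[[length(panel_info) + 1L]] <- do.call(rbind, lapply(
          ts$panels, function(pn) data.frame(
            divergence = tv, rep = r, n_qtl = nq, panel = pn$name,
            size = length(pn$positions),
            spacing_kb = if (length(pn$positions) >= 2)
              mean_inter_marker_distance(pn) else NA_real_,
            stringsAsFactors = FALSE)))
        g_q <- g_t[g_t$n_qtl == nq, , drop = FALSE]
        for (i in seq_len(nrow(g_q))) {
          cf <- g_q[i, ]
          # a replicate can lack a large panel when its variant count is
          # low; record NA and summarize over the replicates that have it
          if (cf$panel %in% names(ts$panels)) {
            ev <- evaluate_scenario(ts, cf$scenario, cf$panel, cf$method,
                                    cf$h2)
          } else {
            ev <- list(accuracy = NA_real_, n_markers = NA_integer_)
          }
          rows[[length(rows) + 1L]] <-
            data.frame(cf[needed], rep = r, accuracy = ev$accuracy,
                       n_markers = ev$n_markers,
                       stringsAsFactors = FALSE)
        }
      }
      if (progress)
        message(sprintf("T = %d: replicate %d/%d done", tv, r, n_reps))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- do.call(rbind, rep_info)
  pa <- do.call(rbind, panel_info)
  rownames(pa) <- NULL
  attr(out, "panels") <- pa
  out
}

#' Aggregate per-replicate accuracies into a summary table
#'
#' Means and standard errors (`SD / sqrt(n_reps)`) per configuration, plus
#' the percent decrease in accuracy relative to the WGS panel within each
#' (scenario, divergence, n_qtl, h2, method) cell, computed from the
#' unrounded means.  With a single replicate the SE is reported as `NA`.
#'
#' @param results Output of [run_replication_design()].
#' @return Data frame with one row per configuration: `mean_accuracy`,
#'   `se`, `n_reps` (replicates with a non-missing accuracy),
#'   `pct_decrease_vs_wgs`.
#' @export
summarize_replicates <- function(results) {
  key <- c("scenario", "divergence", "n_qtl", "h2", "panel", "method")
  agg <- aggregate(results$accuracy, by = results[key],
                   FUN = function(a) {
                     a <- a[!is.na(a)]
                     c(mean = mean(a), sd = sd(a), n = length(a))
                   })
  out <- cbind(agg[key], as.data.frame(agg$x))
  out$mean_accuracy <- out$mean
  out$se <- ifelse(out$n > 1, out$sd / sqrt(out$n), NA_real_)
  out$n_reps <- out$n
  out$mean <- out$sd <- out$n <- NULL

  cellkey <- c("scenario", "divergence", "n_qtl", "h2", "method")
  cell_id <- do.call(paste, c(out[cellkey], sep = "\r"))
  wgs_rows <- out$panel == "wgs"
  wgs_lookup <- out$mean_accuracy[wgs_rows]
  names(wgs_lookup) <- cell_id[wgs_rows]
  out$pct_decrease_vs_wgs <-
    (1 - out$mean_accuracy / wgs_lookup[cell_id]) * 100
  rownames(out) <- NULL
  out[order(out$scenario, out$divergence, out$n_qtl, -out$h2, out$method,
            out$panel), ]
}
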