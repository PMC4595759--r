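# Simulation experiment drivers: coverage sweeps, barcode-density and
# fixed-region scans, and the two-region missense library.

# E. coli-like amino-acid frequencies (approximate proteome composition),
# used to synthesise realistic stand-in proteins of a prescribed length.
AA_FREQS <- c(A = 0.095, C = 0.012, D = 0.054, E = 0.058, F = 0.039,
              G = 0.074, H = 0.022, I = 0.060, K = 0.044, L = 0.106,
              M = 0.028, N = 0.039, P = 0.044, Q = 0.044, R = 0.055,
              S = 0.058, T = 0.054, V = 0.071, W = 0.015, Y = 0.028)

#' Deterministic synthetic protein sequence
#'
#' Generates a stand-in protein of `n_aa` residues (Met first) with
#' realistic residue frequencies; used where a gene of a prescribed length
#' is needed but no real sequence is bundled. Synthetic: not a natural
#' protein.
#'
#' @param n_aa Protein length in residues.
#' @param seed Integer seed (default fixed, so the same length always gives
#'   the same protein).
#' @export
synthetic_protein <- function(n_aa, seed = 1014L) {
  with_seed(seed, {
    aa <- sample(names(AA_FREQS), n_aa - 1L, replace = TRUE, prob = AA_FREQS)
    paste(c("M", aa), collapse = "")
  })
}

#' Read coverage equivalent to a mean molecule depth
#'
#' The pruning and seed thresholds of the assembler act on k-mer depth,
#' which reflects the number of template molecules (cell population /
#' plasmid copies) carrying each window. A 150 nt read contains only
#' `read_len - (k-3) + 1` full `(k-3)`-mer windows, so the read-base
#' coverage required for a mean graph depth of `depth` is
#' `depth * read_len / (read_len - (k-3) + 1)` (about 4.4x `depth` at
#' `k = 120`). Experiment-level mean-coverage settings are expressed in
#' molecule-depth units and converted with this function.
#'
#' @param depth Target mean per-variant molecule depth.
#' @param read_len Read length.
#' @param k Assembly k-mer length.
#' @export
coverage_for_depth <- function(depth, read_len = 150L, k = 120L) {
  depth * read_len / (read_len - (k - 3L) + 1L)
}

# simulate + assemble + score one pool; shared by the experiment drivers
run_pool <- function(truth, depth, params, seq_error_rate = 0.001,
                     seed = 1L, cfg = NULL) {
  cfg <- cfg %||% read_sim_config(seq_error_rate = seq_error_rate)
  cov <- coverage_for_depth(depth, cfg$read_len, params$k)
  reads <- simulate_reads(truth, cfg, target_mean_coverage = cov,
                          seed = seed)
  rep <- assemble(reads, truth$fwd_flank, truth$rev_flank, params,
                  expected_insert_len = nchar(truth$variants$insert[1]))
  ev <- compare_to_truth(rep, truth)
  list(report = rep, eval = ev)
}

#' Run a named simulation experiment
#'
#' Drives the package's standard simulation designs end to end
#' (library generation, read simulation, assembly, truth scoring) and
#' returns a tidy result table.
#'
#' * `coverage_sweep`: recovery (recall) versus mean molecule depth under a
#'   uniform or negative-binomial coverage model.
#' * `barcode_density`: sensitivity versus barcode retention probability P
#'   (binomial down-sampling of the template's degenerate positions).
#' * `fixed_region`: effect of a growing non-randomized (barcode-free)
#'   window on sensitivity and false positives.
#' * `two_region`: the two-region missense library (one missense change in
#'   each of two distant windows per variant).
#'
#' @param name Experiment name.
#' @param n_aa Protein length of the synthetic design (default 493, a
#'   1482 nt gene with stop).
#' @param n_variants Library size per condition.
#' @param depths,p_values,window_codons Condition grids for the respective
#'   experiments.
#' @param model Coverage model kind for `coverage_sweep`.
#' @param depth Mean molecule depth for the single-condition experiments.
#' @param mutation_rate Error-prone-PCR substitution rate.
#' @param seq_error_rate Sequencing substitution error rate.
#' @param params An [assembly_params()].
#' @param seed Integer seed for the whole experiment.
#' @return Data frame, one row per condition, with recovery/sensitivity,
#'   precision and bookkeeping columns.
#' @export
run_experiment <- function(name = c("coverage_sweep", "barcode_density",
                                    "fixed_region", "two_region"),
                           n_aa = 493L, n_variants = 500L,
                           depths = c(12, 24, 36, 48, 60),
                           p_values = c(1, 0.8, 0.6),
                           window_codons = c(0L, 30L, 45L),
                           model = c("negative_binomial", "uniform"),
                           depth = 12, mutation_rate = 0.01,
                           seq_error_rate = 0.001,
                           params = assembly_params(), seed = 1L) {
  name <- match.arg(name)
  model <- match.arg(model)
  tpl <- reverse_translate(synthetic_protein(n_aa))
  fl <- random_flanks(150L, seed = seed + 7L)

  if (name == "coverage_sweep") {
    rows <- lapply(seq_along(depths), function(i) {
      mu <- depths[i]
      truth <- generate_library(tpl, n_variants, mutation_rate,
                                fl$fwd, fl$rev, seed = seed + i)
      truth <- assign_copy_numbers(truth, coverage_model(model, mean = mu),
                                   seed = seed + 100L + i)
      res <- run_pool(truth, mu, params, seq_error_rate, seed = seed + 200L + i)
      data.frame(experiment = name, condition = mu, model = model,
                 recall = res$eval$recall, precision = res$eval$precision,
                 n_truth = nrow(truth$variants),
                 n_contigs = res$eval$tp + res$eval$fp)
    })
    return(do.call(rbind, rows))
  }

  if (name == "barcode_density") {
    rows <- lapply(seq_along(p_values), function(i) {
      p <- p_values[i]
      ds <- downsample_barcodes(tpl, p, seed = seed + i)
      truth <- generate_library(ds$template, n_variants, mutation_rate,
                                fl$fwd, fl$rev, seed = seed + 50L + i)
      truth <- assign_copy_numbers(truth,
                                   coverage_model("uniform", mean = depth))
      res <- run_pool(truth, depth, params, seq_error_rate,
                      seed = seed + 200L + i)
      data.frame(experiment = name, condition = p,
                 n_barcodes = length(ds$template$barcode_positions),
                 recall = res$eval$recall, precision = res$eval$precision,
                 n_truth = nrow(truth$variants),
                 n_contigs = res$eval$tp + res$eval$fp,
                 truncated = res$report$log$traversal$truncated)
    })
    return(do.call(rbind, rows))
  }

  if (name == "fixed_region") {
    # a barcode-free window is shared by every molecule, so exact-match
    # re-alignment credits its reads to every candidate and the depth
    # profiles of even true contigs develop a bump over the window; the CV
    # stage (optional by design, calibrated for barcode-dense templates) is
    # therefore disabled in this sweep
    params$apply_cv_filter <- FALSE
    rows <- lapply(seq_along(window_codons), function(i) {
      wc <- window_codons[i]
      tpl_i <- tpl
      if (wc > 0L) {
        # fix (de-randomize) a window of codons in the gene middle
        start_codon <- max(1L, (n_aa %/% 2L) - (wc %/% 2L))
        lo <- (start_codon - 1L) * 3L       # 0-based
        hi <- lo + 3L * wc - 1L
        bp <- tpl$barcode_positions
        inwin <- bp >= lo & bp <= hi
        chars <- strsplit(tpl$dna, "")[[1]]
        fixed <- with_seed(seed + i, vapply(bp[inwin] + 1L, function(j) {
          e <- IUPAC_EXPAND[[chars[j]]]
          e[sample.int(length(e), 1L)]
        }, ""))
        chars[bp[inwin] + 1L] <- fixed
        tpl_i$dna <- paste(chars, collapse = "")
        tpl_i$barcode_positions <- bp[!inwin]
      }
      truth <- generate_library(tpl_i, n_variants, mutation_rate,
                                fl$fwd, fl$rev, seed = seed + 50L + i)
      truth <- assign_copy_numbers(truth,
                                   coverage_model("uniform", mean = depth))
      res <- run_pool(truth, depth, params, seq_error_rate,
                      seed = seed + 200L + i)
      data.frame(experiment = name, condition = wc,
                 recall = res$eval$recall, precision = res$eval$precision,
                 false_positives = res$eval$fp,
                 n_truth = nrow(truth$variants),
                 n_contigs = res$eval$tp + res$eval$fp)
    })
    return(do.call(rbind, rows))
  }

  # two_region
  region_a <- 50:83
  region_b <- 400:433   # > 800 bp downstream of region A
  if (max(region_b) > n_aa) stop("n_aa too short for the two-region layout")
  truth <- generate_two_region_library(tpl, region_a, region_b, n_variants,
                                       fl$fwd, fl$rev, seed = seed + 1L)
  truth <- assign_copy_numbers(truth, coverage_model("uniform", mean = depth))
  res <- run_pool(truth, depth, params, seq_error_rate, seed = seed + 2L)
  data.frame(experiment = name, condition = n_variants,
             recall = res$eval$recall, precision = res$eval$precision,
             n_truth = nrow(truth$variants),
             n_contigs = res$eval$tp + res$eval$fp)
}
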