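#' Simulate a structured diploid cohort as VCF + panel
#'
#' Generates a multi-population cohort under the Balding-Nichols drift
#' model. Per variant, an ancestral allele frequency `p` is drawn uniformly
#' from `ancestral_freq_range`; each population then draws its own
#' frequency from a Beta distribution with mean `p` and variance
#' `p * (1 - p) * fst` (shape parameters `p (1 - F) / F` and
#' `(1 - p)(1 - F) / F`), so `fst` acts as an F_ST-like divergence knob;
#' each individual's genotype is Binomial(2, population frequency), written
#' as `0|0` / `0|1` / `1|1` (heterozygotes are always emitted phased as
#' `0|1`; the dosage encoding is phase-blind so this loses nothing).
#' Variants that drift to fixation in every population are retained: they
#' encode to empty columns and deliberately exercise the uninformative-
#' column path of the preprocessing chain. Output is byte-identical for
#' identical arguments.
#'
#' The defaults describe the cohort used throughout the package's own
#' calibration: four populations of 100 diploid individuals at 2,000
#' unlinked sites with F = 0.2.
#'
#' @param n_pops number of populations.
#' @param samples_per_pop individuals per population; a single count is
#'   recycled across populations.
#' @param n_variants number of simulated sites.
#' @param fst drift parameter F in (0, 1).
#' @param ancestral_freq_range interval the ancestral frequencies are drawn
#'   from.
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @param chrom_name chromosome name written in the VCF.
#' @param missing_rate probability a genotype is emitted as `./.`.
#' @param out_vcf path for the VCF (a `.gz` suffix compresses).
#' @param out_panel optional path for a panel TSV readable by
#'   [read_panel()].
#' @return list with `vcf` (path), `panel` (path or `NULL`) and `truth`
#'   (named character vector mapping sample ID to population label).
#' @export
simulate_cohort <- function(n_pops = 4L, samples_per_pop = 100L,
                            n_variants = 2000L, fst = 0.2,
                            ancestral_freq_range = c(0.1, 0.9),
                            seed = 1L, chrom_name = "1", missing_rate = 0,
                            out_vcf, out_panel = NULL) {
  if (n_pops < 1L || n_variants < 1L) {
    stop_param("need at least one population and one variant")
  }
  if (!(fst > 0 && fst < 1)) stop_param("fst must lie in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_param("missing_rate must lie in [0, 1)")
  }
  if (length(samples_per_pop) == 1L) {
    samples_per_pop <- rep.int(as.integer(samples_per_pop), n_pops)
  }
  if (length(samples_per_pop) != n_pops || any(samples_per_pop < 1L)) {
    stop_param("samples_per_pop must give a positive count per population")
  }
  n_samples <- sum(samples_per_pop)
  pop_labels <- sprintf("POP%d", seq_len(n_pops))
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  truth <- stats::setNames(rep(pop_labels, samples_per_pop), sample_ids)
  pop_of <- rep(seq_len(n_pops), samples_per_pop)

  gt_codes <- c("0|0", "0|1", "1|1")
  with_seed(seed, {
    p_anc <- stats::runif(n_variants, ancestral_freq_range[1L],
                          ancestral_freq_range[2L])
    # population frequencies: n_variants x n_pops
    shape_scale <- (1 - fst) / fst
    p_pop <- matrix(stats::rbeta(n_variants * n_pops,
                                 shape1 = rep(p_anc, n_pops) * shape_scale,
                                 shape2 = rep(1 - p_anc, n_pops) * shape_scale),
                    nrow = n_variants, ncol = n_pops)
    # alt-allele counts: n_variants x n_samples
    counts <- matrix(stats::rbinom(n_variants * n_samples, size = 2L,
                                   prob = p_pop[, pop_of]),
                     nrow = n_variants, ncol = n_samples)
    gt <- matrix(gt_codes[counts + 1L], nrow = n_variants)
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n_variants * n_samples) < missing_rate,
                     nrow = n_variants)
      gt[miss] <- "./."
    }
  })

  v <- 0L
  gen <- function() {
    if (v >= n_variants) return(NULL)
    v <<- v + 1L
    list(chrom = chrom_name, pos = v, var_id = sprintf("var%d", v),
         ref = "A", alts = "T", gt_strings = gt[v, ])
  }
  write_vcf(sample_ids, gen, out_vcf)
  panel_path <- NULL
  if (!is.null(out_panel)) {
    truth_to_panel(truth, out_panel)
    panel_path <- out_panel
  }
  list(vcf = out_vcf, panel = panel_path, truth = truth)
}

#' Write ground-truth labels as a 1000 Genomes-style panel file
#'
#' Emits a tab-separated table with header `sample`, `pop`, `super_pop`
#' (both population columns carry the same label at the simulator's single
#' level of structure) that round-trips through [read_panel()].
#'
#' @param truth non-empty named character vector mapping sample ID to
#'   label.
#' @param dest output path.
#' @return number of data rows written, invisibly.
#' @export
truth_to_panel <- function(truth, dest) {
  if (length(truth) == 0L) stop_param("truth mapping is empty")
  if (is.null(names(truth)) || any(!nzchar(names(truth)))) {
    stop_param("truth must be named by sample ID")
  }
  lines <- c("sample\tpop\tsuper_pop",
             paste(names(truth), truth, truth, sep = "\t"))
  tryCatch(writeLines(lines, dest),
           error = function(e) stop_io("cannot write ", dest),
           warning = function(w) stop_io("cannot write ", dest))
  invisible(length(truth))
}
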