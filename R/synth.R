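# Seeded synthetic-data generators.
#
# Every analysis stage in the package has a matching generator that emulates
# the statistical structure the stage assumes: noisy pigment-template
# spectra (pure or mixed chromophore, optional baseline drift), populations
# of photoreceptor cells, crystallin-like protein sequences, negative
# binomial count matrices with unequal library sizes and asymmetric
# differential expression, and binomial 2x2 direction tables. All
# generators are pure functions of (configuration, seed) and return a
# machine-readable truth record for recovery tests.

#' Generate a synthetic MSP spectrum
#'
#' The truth model is `mixture_template x peak_absorbance + baseline + iid
#' Gaussian noise`. The default peak absorbance (0.015) is the realistic
#' scale of a single-outer-segment MSP measurement, so peak normalization is
#' exercised nontrivially; recovery tests that quote a noise SD relative to
#' a unit peak should pass `peak_absorbance = 1`.
#'
#' @param lambda_max_a1,lambda_max_a2 Component lambda-max values (nm).
#' @param fraction_a2 Proportion of A2 pigment in `[0, 1]` (0 = pure A1,
#'   1 = pure A2).
#' @param peak_absorbance True absorbance at the peak.
#' @param noise_sd SD of iid Gaussian noise added to absorbance.
#' @param baseline_slope Linear baseline increase per nm toward short
#'   wavelengths (0 = flat), emulating scatter in noisy scans.
#' @param wavelength_range,step Sampling grid (default 350--750 nm at 1 nm).
#' @param cell_id Identifier stored in the spectrum.
#' @param seed RNG seed.
#' @return A list: `spectrum` (an `"msp_spectrum"`) and `truth` (all
#'   generating parameters).
#' @export
gen_spectrum <- function(lambda_max_a1 = 505, lambda_max_a2 = 526,
                         fraction_a2 = 0, peak_absorbance = 0.015,
                         noise_sd = 0, baseline_slope = 0,
                         wavelength_range = c(350, 750), step = 1,
                         cell_id = "synthetic", seed = 1L) {
  stopifnot_scalar_number(fraction_a2, "fraction_a2", 0, 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", 0, Inf)
  stopifnot_scalar_number(peak_absorbance, "peak_absorbance", 1e-12, Inf)
  wl <- seq(wavelength_range[1], wavelength_range[2], by = step)
  shape <- mixture_template(template_spec("A1", lambda_max_a1),
                            template_spec("A2", lambda_max_a2),
                            fraction_a2, wl)
  baseline <- baseline_slope * (max(wl) - wl)
  ab <- with_seed(seed, {
    shape * peak_absorbance + baseline + stats::rnorm(length(wl), 0, noise_sd)
  })
  truth <- list(lambda_max_a1 = lambda_max_a1, lambda_max_a2 = lambda_max_a2,
                fraction_a2 = fraction_a2,
                lambda_max = if (fraction_a2 == 0) lambda_max_a1
                             else if (fraction_a2 == 1) lambda_max_a2
                             else wl[which.max(shape)],
                chromophore = if (fraction_a2 >= 0.5) "A2" else "A1",
                peak_absorbance = peak_absorbance, noise_sd = noise_sd,
                baseline_slope = baseline_slope, seed = seed)
  list(spectrum = spectrum(wl, ab, cell_id = cell_id),
       truth = truth)
}

#' Generate a population of photoreceptor cell spectra
#'
#' Each row of `class_specs` describes a cell class: its label, mean and SD
#' of true lambda-max across cells, chromophore (`"A1"` or `"A2"`), and the
#' number of cells. Per-cell lambda-max values are drawn normally, then each
#' cell gets a pure-chromophore template spectrum with Gaussian noise.
#'
#' @param class_specs Data frame with columns `class`, `lambda_mean`,
#'   `lambda_sd`, `chromophore`, `n`.
#' @param noise_sd Gaussian noise SD on absorbance.
#' @param peak_absorbance True peak absorbance of every cell.
#' @param seed RNG seed.
#' @return A list: `spectra` (list of `"msp_spectrum"`) and `truth` (data
#'   frame with one row per cell: `cell_id`, `class`, `lambda_max`,
#'   `chromophore`).
#' @export
gen_cell_population <- function(class_specs, noise_sd = 0.01,
                                peak_absorbance = 1, seed = 1L) {
  stopifnot(is.data.frame(class_specs),
            all(c("class", "lambda_mean", "lambda_sd", "chromophore", "n")
                %in% names(class_specs)))
  draws <- with_seed(seed, {
    lapply(seq_len(nrow(class_specs)), function(i) {
      s <- class_specs[i, ]
      if (s$n < 1) return(NULL)
      data.frame(class = s$class,
                 chromophore = s$chromophore,
                 lambda_max = stats::rnorm(s$n, s$lambda_mean, s$lambda_sd),
                 cell_seed = sample.int(.Machine$integer.max, s$n),
                 stringsAsFactors = FALSE)
    })
  })
  truth <- do.call(rbind, draws)
  if (is.null(truth) || !nrow(truth)) {
    return(list(spectra = list(), truth = NULL))
  }
  truth$cell_id <- sprintf("%s_%03d", truth$class, seq_len(nrow(truth)))
  spectra <- lapply(seq_len(nrow(truth)), function(i) {
    fr <- if (truth$chromophore[i] == "A2") 1 else 0
    lm <- min(max(truth$lambda_max[i], 350), 650)
    gen_spectrum(lambda_max_a1 = if (fr == 0) lm else 505,
                 lambda_max_a2 = if (fr == 1) lm else 526,
                 fraction_a2 = fr,
                 peak_absorbance = peak_absorbance,
                 noise_sd = noise_sd,
                 cell_id = truth$cell_id[i],
                 seed = truth$cell_seed[i])$spectrum
  })
  truth <- truth[, c("cell_id", "class", "lambda_max", "chromophore",
                     "cell_seed")]
  list(spectra = spectra, truth = truth)
}

#' Residue frequency profiles for synthetic proteins
#'
#' `"natural"` is the average composition of globular proteins;
#' `"gamma_like"` is aromatic-rich (high Trp/Tyr/Phe, as in gamma
#' crystallins, which raises dn/dc); `"alpha_like"` is aromatic-poor with
#' more small/charged residues (as in alpha crystallins, lowering dn/dc).
#'
#' @return A named list of frequency vectors over the 20 residues, each
#'   summing to 1.
#' @export
residue_profiles <- function() {
  natural <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, E = 6.72,
               Q = 3.93, G = 7.07, H = 2.27, I = 5.91, L = 9.65, K = 5.80,
               M = 2.41, F = 3.86, P = 4.74, S = 6.63, T = 5.35, W = 1.10,
               Y = 2.92, V = 6.86)
  gamma_like <- natural
  gamma_like[c("W", "Y", "F", "R", "M", "H")] <-
    gamma_like[c("W", "Y", "F", "R", "M", "H")] * c(4, 3, 1.5, 1.6, 1.5, 1.5)
  alpha_like <- natural
  alpha_like[c("W", "Y", "F")] <- alpha_like[c("W", "Y", "F")] * 0.4
  alpha_like[c("A", "E", "K", "S")] <- alpha_like[c("A", "E", "K", "S")] * 1.3
  lapply(list(natural = natural, gamma_like = gamma_like,
              alpha_like = alpha_like),
         function(p) p / sum(p))
}

#' Generate a synthetic protein sequence
#'
#' Residues are drawn iid from a frequency profile, so the expected
#' composition converges to the profile as length grows.
#'
#' @param profile Named residue frequency vector summing to 1 (see
#'   [residue_profiles()]).
#' @param length Sequence length.
#' @param id Record identifier.
#' @param seed RNG seed.
#' @return A data frame row with `id`, `sequence`, `n_dropped = 0`.
#' @export
gen_protein <- function(profile = residue_profiles()$natural, length = 180L,
                        id = "synthetic_protein", seed = 1L) {
  stopifnot(is.numeric(profile), !is.null(names(profile)), length >= 1L)
  if (abs(sum(profile) - 1) > 1e-6) {
    stop("'profile' frequencies must sum to 1", call. = FALSE)
  }
  seq <- with_seed(seed, {
    paste(sample(names(profile), length, replace = TRUE, prob = profile),
          collapse = "")
  })
  data.frame(id = id, sequence = seq, n_dropped = 0L,
             stringsAsFactors = FALSE)
}

#' Generate a negative binomial count matrix
#'
#' Gene baseline means are log-normal; a fraction of genes is
#' differentially expressed, all in the same direction (upregulated in the
#' second half of the samples) -- the asymmetric situation TMM is designed
#' to withstand. Library size factors scale whole samples.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param library_size_factors Per-sample depth multipliers (length
#'   `n_samples`).
#' @param de_fraction Fraction of genes differentially expressed, in
#'   `[0, 1)`.
#' @param de_log2fc log2 fold change of DE genes in the second sample group.
#' @param nb_dispersion Negative binomial dispersion (default 0.1; variance
#'   `mu + dispersion * mu^2`).
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline means.
#'   The default mean scale (500) reflects typical bulk RNA-seq depth, where
#'   per-gene counts are large enough that log-ratio statistics are
#'   essentially unbiased.
#' @param seed RNG seed.
#' @return A list: `counts` (genes x samples matrix) and `truth`
#'   (`de_genes`, `group`, `library_size_factors`, and the full config).
#' @export
gen_counts <- function(n_genes = 2000L, n_samples = 4L,
                       library_size_factors = rep(1, n_samples),
                       de_fraction = 0.05, de_log2fc = 2,
                       nb_dispersion = 0.1,
                       base_meanlog = log(500), base_sdlog = 1.2,
                       seed = 1L) {
  stopifnot_scalar_number(de_fraction, "de_fraction", 0, 1 - 1e-12)
  stopifnot_scalar_number(nb_dispersion, "nb_dispersion", 1e-12, Inf)
  stopifnot(length(library_size_factors) == n_samples,
            all(library_size_factors > 0))
  group <- rep(c("A", "B"), c(ceiling(n_samples / 2),
                              floor(n_samples / 2)))
  out <- with_seed(seed, {
    base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
    n_de <- floor(de_fraction * n_genes)
    de_genes <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    fc <- matrix(1, n_genes, n_samples)
    fc[de_genes, group == "B"] <- 2^de_log2fc
    mu <- base * fc * rep(library_size_factors, each = n_genes)
    counts <- matrix(
      stats::rnbinom(n_genes * n_samples, mu = mu, size = 1 / nb_dispersion),
      n_genes, n_samples)
    list(counts = counts, de_genes = de_genes)
  })
  counts <- out$counts
  dimnames(counts) <- list(sprintf("gene_%04d", seq_len(n_genes)),
                           sprintf("sample_%d", seq_len(n_samples)))
  list(counts = counts,
       truth = list(de_genes = rownames(counts)[out$de_genes],
                    group = group,
                    library_size_factors = library_size_factors,
                    de_fraction = de_fraction, de_log2fc = de_log2fc,
                    nb_dispersion = nb_dispersion, seed = seed))
}

#' Generate a binomial 2x2 direction table
#'
#' Independent binomial draws for the two gene classes, e.g. cone vs rod
#' phototransduction genes with "upregulated in tadpoles" as success.
#'
#' @param p_cone,p_rod True success probabilities.
#' @param n_cone,n_rod Numbers of genes per class.
#' @param seed RNG seed.
#' @return A list `(x1, n1, x2, n2)` ready for [zpooled_test()], plus the
#'   generating probabilities in `truth`.
#' @export
gen_direction_table <- function(p_cone, p_rod, n_cone = 10L, n_rod = 10L,
                                seed = 1L) {
  stopifnot_scalar_number(p_cone, "p_cone", 0, 1)
  stopifnot_scalar_number(p_rod, "p_rod", 0, 1)
  draws <- with_seed(seed, {
    c(stats::rbinom(1, n_cone, p_cone), stats::rbinom(1, n_rod, p_rod))
  })
  list(x1 = draws[1], n1 = n_cone, x2 = draws[2], n2 = n_rod,
       truth = list(p_cone = p_cone, p_rod = p_rod, seed = seed))
}
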