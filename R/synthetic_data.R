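#' Simulation configuration for the drought-screening pipeline
#'
#' Collects every parameter of the synthetic-data generators in one
#' validated list.  Defaults emulate the study design the package
#' targets: a 114-genotype field trial scored under non-stress and
#' stress environments, and a greenhouse factorial of 2 contrasting
#' genotypes x 3 soil-moisture levels (90-95%, 50-55% and 25-30% of
#' field capacity) with 3 replicates for traits and 2 biological x 2
#' technical replicates for qPCR.
#'
#' @param n_genotypes genotypes in the field yield trial.
#' @param frac archetype mix (must sum to 1): fractions of tolerant,
#'   intermediate and sensitive genotypes.
#' @param mean_yield mean control-environment yield (g/plot scale).
#' @param yield_cv coefficient of variation of genotype potential yields
#'   (log-normal across genotypes).
#' @param reduction per-archetype fractional yield loss under stress,
#'   each in [0, 1).
#' @param yield_noise_sd sd of the multiplicative noise on stress yields.
#' @param trait_mu grand mean of the simulated greenhouse trait.
#' @param genotype_effect,stress_effect,interaction_effect effect-size
#'   amplitudes (trait units) for the factorial generator; see
#'   [sim_trait_matrix()].
#' @param trait_sd residual (within-cell) standard deviation of traits.
#' @param reps_trait replicates per cell in the greenhouse factorial.
#' @param bio_reps,tech_reps biological and technical qPCR replicates.
#' @param ct_baseline named baseline CT per gene (reference first).
#' @param reference_gene name of the reference (housekeeping) gene.
#' @param log2_shift list, per genotype class (`tolerant`, `sensitive`),
#'   of gene x treatment matrices of log2 fold-change shifts relative to
#'   control.  Defaults encode the upregulation pattern of the dehydrin
#'   and antioxidant-enzyme genes under mild and severe drought, e.g. a
#'   12.51-fold Dhn1 induction in the tolerant class under severe stress.
#' @param ct_noise_sd technical-replicate CT noise sd (cycles).
#' @param ct_bio_sd biological-replicate CT spread sd (cycles).
#' @param seed integer random seed; mandatory for reproducibility.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genotypes = 114,
                       frac = c(tolerant = 0.15, intermediate = 0.65,
                                sensitive = 0.20),
                       mean_yield = 250,
                       yield_cv = 0.30,
                       reduction = c(tolerant = 0.20, intermediate = 0.45,
                                     sensitive = 0.70),
                       yield_noise_sd = 0.10,
                       trait_mu = 10,
                       genotype_effect = 1.0,
                       stress_effect = 2.0,
                       interaction_effect = 3,
                       trait_sd = 1.0,
                       reps_trait = 3,
                       bio_reps = 2,
                       tech_reps = 2,
                       ct_baseline = c(alpha_tubulin = 20, Dhn1 = 24,
                                       SOD = 22, POD = 23, CAT = 22),
                       reference_gene = "alpha_tubulin",
                       log2_shift = default_log2_shift(),
                       ct_noise_sd = 0.15,
                       ct_bio_sd = 0.25,
                       seed = 1L) {
  frac <- frac / 1  # keep names
  if (abs(sum(frac) - 1) > 1e-8)
    stop("archetype fractions must sum to 1", call. = FALSE)
  if (any(reduction < 0 | reduction >= 1))
    stop("stress reductions must lie in [0, 1)", call. = FALSE)
  if (!all(names(frac) == c("tolerant", "intermediate", "sensitive")) ||
      !all(names(reduction) == names(frac)))
    stop("frac and reduction must be named tolerant/intermediate/sensitive",
         call. = FALSE)
  if (is.null(seed) || !is.finite(seed))
    stop("a numeric seed is mandatory", call. = FALSE)
  if (!reference_gene %in% names(ct_baseline))
    stop("reference gene must have a CT baseline", call. = FALSE)
  structure(list(
    n_genotypes = as.integer(n_genotypes), frac = frac,
    mean_yield = mean_yield, yield_cv = yield_cv, reduction = reduction,
    yield_noise_sd = yield_noise_sd,
    trait_mu = trait_mu, genotype_effect = genotype_effect,
    stress_effect = stress_effect, interaction_effect = interaction_effect,
    trait_sd = trait_sd, reps_trait = as.integer(reps_trait),
    bio_reps = as.integer(bio_reps), tech_reps = as.integer(tech_reps),
    ct_baseline = ct_baseline, reference_gene = reference_gene,
    log2_shift = log2_shift,
    ct_noise_sd = ct_noise_sd, ct_bio_sd = ct_bio_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default per-treatment log2 expression shifts
#'
#' Log2 fold changes (relative to the control treatment) used by the CT
#' generator, per genotype class and gene.  The tolerant class shows the
#' strongest induction under severe drought (e.g. 12.51-fold for the
#' dehydrin gene Dhn1), the sensitive class a weaker response.
#'
#' @return list with matrices `tolerant` and `sensitive`
#'   (gene x treatment, log2 units).
#' @export
default_log2_shift <- function() {
  trt <- c("control_90_95FC", "mild_50_55FC", "severe_25_30FC")
  genes <- c("Dhn1", "SOD", "POD", "CAT")
  tol <- rbind(Dhn1 = c(0, log2(5.15), log2(12.51)),
               SOD  = c(0, log2(3.40), log2(7.39)),
               POD  = c(0, log2(3.20), log2(7.07)),
               CAT  = c(0, log2(3.55), log2(7.36)))
  sen <- rbind(Dhn1 = c(0, log2(4.69), log2(2.86)),
               SOD  = c(0, log2(2.10), log2(3.60)),
               POD  = c(0, log2(2.00), log2(3.89)),
               CAT  = c(0, log2(1.80), log2(2.50)))
  colnames(tol) <- colnames(sen) <- trt
  list(tolerant = tol, sensitive = sen)
}

stress_levels <- function() c("control_90_95FC", "mild_50_55FC",
                              "severe_25_30FC")

#' Simulate a two-environment yield trial with tolerance archetypes
#'
#' Potential yields `yp` are log-normal across genotypes (positive,
#' right-skewed); stress yields are
#' `ys = yp * (1 - reduction[archetype]) * (1 + noise)` with Gaussian
#' multiplicative noise.  Archetype truth labels are returned so recovery
#' tests never have to re-derive them from the outputs.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `genotype`, `archetype` (truth label),
#'   `yp`, `ys`.  Deterministic given `config$seed`.
#' @export
sim_yield_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genotypes
  counts <- round(config$frac * n)
  counts[1] <- n - sum(counts[-1])  # absorb rounding in the first class
  arch <- sample(rep(names(config$frac), counts))
  sdlog <- sqrt(log(1 + config$yield_cv^2))
  mulog <- log(config$mean_yield) - sdlog^2 / 2
  yp <- stats::rlnorm(n, mulog, sdlog)
  noise <- stats::rnorm(n, 0, config$yield_noise_sd)
  ys <- yp * (1 - config$reduction[arch]) * (1 + noise)
  ys <- pmax(ys, 0)
  data.frame(genotype = seq_len(n), archetype = arch, yp = yp, ys = ys,
             row.names = NULL)
}

#' Simulate a qPCR CT table for the greenhouse factorial
#'
#' Two genotypes (one tolerant, one sensitive) x three soil-moisture
#' treatments x four target genes plus a flat reference gene, with 2
#' biological x 2 technical replicates by default.  Target CT values are
#' the gene baseline minus the configured log2 fold-change shift (one
#' PCR cycle per doubling), plus biological and technical noise; the
#' reference gene carries noise only.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `genotype`, `class` (truth label),
#'   `treatment`, `gene`, `bio_rep`, `tech_rep`, `ct`.
#' @export
sim_ct_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  trt <- stress_levels()
  genos <- c(tolerant = "G-tol", sensitive = "G-sen")
  genes <- names(config$ct_baseline)
  grid <- expand.grid(class = names(genos), treatment = trt, gene = genes,
                      bio_rep = seq_len(config$bio_reps),
                      tech_rep = seq_len(config$tech_reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$genotype <- genos[grid$class]
  shift <- mapply(function(cl, g, t) {
    if (g == config$reference_gene) 0 else config$log2_shift[[cl]][g, t]
  }, grid$class, grid$gene, grid$treatment)
  # one biological-noise draw per (class, treatment, gene, bio_rep) cell
  cellkey <- paste(grid$class, grid$treatment, grid$gene, grid$bio_rep,
                   sep = "\r")
  cells <- unique(cellkey)
  bio_noise <- stats::rnorm(length(cells), 0, config$ct_bio_sd)
  names(bio_noise) <- cells
  grid$ct <- config$ct_baseline[grid$gene] - shift +
    bio_noise[cellkey] + stats::rnorm(nrow(grid), 0, config$ct_noise_sd)
  rownames(grid) <- NULL
  grid[c("genotype", "class", "treatment", "gene", "bio_rep", "tech_rep",
         "ct")]
}

#' Simulate a balanced genotype x stress trait matrix
#'
#' Cell means follow the additive-plus-interaction model
#' `mu + g_i + s_j + (gs)_ij` with sum-to-zero effect patterns scaled by
#' the configured amplitudes, plus iid Gaussian replicate noise:
#' the tolerant genotype sits `genotype_effect` above the sensitive one,
#' stress levels step down linearly by `stress_effect`, and the
#' interaction (amplitude `interaction_effect`) makes the sensitive
#' genotype lose disproportionately under severe stress.
#'
#' @param config a [sim_config()].
#' @param trait trait label stamped on the rows.
#' @return data frame with columns `genotype`, `stress_level`,
#'   `replicate`, `trait`, `value`, plus the true cell means as
#'   attribute `"truth"`.
#' @export
sim_trait_matrix <- function(config, trait = "chl_a") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  gl <- c("G-tol", "G-sen")
  sl <- stress_levels()
  ge <- config$genotype_effect * c(0.5, -0.5)
  se <- config$stress_effect * c(1, 0, -1)
  gs <- config$interaction_effect *
    rbind(c(-0.5, 0, 0.5), c(0.5, 0, -0.5))  # sum-to-zero pattern
  truth <- config$trait_mu + outer(ge, se, "+") + gs
  dimnames(truth) <- list(gl, sl)
  d <- expand.grid(replicate = seq_len(config$reps_trait),
                   stress_level = sl, genotype = gl,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$trait <- trait
  d$value <- truth[cbind(d$genotype, d$stress_level)] +
    stats::rnorm(nrow(d), 0, config$trait_sd)
  d <- d[c("genotype", "stress_level", "replicate", "trait", "value")]
  attr(d, "truth") <- truth
  d
}

#' Simulate an absorbance panel from target pigment profiles
#'
#' Draws per-sample pigment targets (chlorophyll a and b and carotenoids
#' in ug/ml) around class means and inverts the pigment formulas to the
#' absorbance triple that produces them, so the pigment module's forward
#' computation recovers the targets exactly.
#'
#' @param config a [sim_config()].
#' @param n_samples rows to generate.
#' @return data frame `sample_id`, `a663`, `a646`, `a470`, with the
#'   target concentrations attached as attribute `"truth"`.
#' @export
sim_absorbance_panel <- function(config, n_samples = 12) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  chl_a <- stats::runif(n_samples, 4, 14)
  chl_b <- stats::runif(n_samples, 1, 6)
  car <- stats::runif(n_samples, 1, 4)
  ab <- invert_pigments(chl_a, chl_b, car)
  out <- cbind(data.frame(sample_id = paste0("S", seq_len(n_samples))), ab)
  attr(out, "truth") <- data.frame(chl_a = chl_a, chl_b = chl_b,
                                   carotenoids = car)
  out
}
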