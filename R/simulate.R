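#' Build a multiplexed count-panel sample design
#'
#' The reference layout follows the ageing-liver panel study: eight age
#' classes (3 to 24 months in 3-month steps), twelve evenly spaced zeitgeber
#' times (ZT0 to ZT22, 2 h apart) and two replicates per (age, ZT) cell,
#' giving 192 samples.
#'
#' @param ages Age classes in months.
#' @param zts Zeitgeber times in hours, each in [0, 24).
#' @param replicates Replicates per (age, ZT) cell.
#' @return A validated sample design data.frame.
#' @export
panel_design <- function(ages = c(3, 6, 9, 12, 15, 18, 21, 24),
                         zts = seq(0, 22, by = 2), replicates = 2) {
  grid <- expand.grid(replicate = seq_len(replicates), zeitgeber_time_h = zts,
                      age_months = ages, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("age_months", "zeitgeber_time_h", "replicate")]
  grid$sample_id <- sprintf("a%02d_zt%02d_r%d", grid$age_months,
                            grid$zeitgeber_time_h, grid$replicate)
  grid$condition_label <- as.character(grid$age_months)
  validate_sample_design(grid[, c("sample_id", "age_months",
                                  "zeitgeber_time_h", "replicate",
                                  "condition_label")])
}

#' Per-gene simulation parameters
#'
#' Vectorised constructor for the generative model used by
#' [simulate_panel()]. The expected count of gene `g` in sample `s` is
#' `baseline * exp(age_effect(age_s)) * (1 + amplitude * cos(2 pi (ZT_s -
#' acrophase) / 24)) * tech_factor_s`, where the age effect ramps linearly
#' (on the log scale) from 0 at the youngest design age to
#' `age_log_fold_change` at the oldest. Counts are drawn negative-binomially
#' with dispersion `dispersion + noise_inflation_per_age * (age - youngest)`,
#' modelling transcriptional noise that grows with age; `dispersion = 0`
#' gives the deterministic noise-free limit.
#'
#' @param gene_id Gene identifiers.
#' @param baseline Expected count at the youngest age, averaged over the
#'   cycle (positive).
#' @param circadian_amplitude Relative amplitude in [0, 1).
#' @param acrophase_h Peak time in hours, [0, 24).
#' @param age_log_fold_change Log fold-change at the oldest versus youngest
#'   design age.
#' @param dispersion Negative-binomial dispersion (variance = mu + disp *
#'   mu^2) at the youngest age.
#' @param noise_inflation_per_age Extra dispersion per month of age.
#' @return data.frame of class `gene_sim_params`.
#' @export
gene_params <- function(gene_id, baseline, circadian_amplitude = 0,
                        acrophase_h = 0, age_log_fold_change = 0,
                        dispersion = 0.002, noise_inflation_per_age = 0) {
  df <- data.frame(gene_id = gene_id, baseline = baseline,
                   circadian_amplitude = circadian_amplitude,
                   acrophase_h = acrophase_h,
                   age_log_fold_change = age_log_fold_change,
                   dispersion = dispersion,
                   noise_inflation_per_age = noise_inflation_per_age,
                   stringsAsFactors = FALSE)
  if (any(df$baseline <= 0)) stop("baseline must be positive")
  if (any(df$circadian_amplitude < 0 | df$circadian_amplitude >= 1))
    stop("circadian_amplitude must lie in [0, 1)")
  if (any(df$dispersion < 0) || any(df$noise_inflation_per_age < 0))
    stop("dispersion parameters must be non-negative")
  if (any(duplicated(df$gene_id))) stop("duplicated gene_id in parameters")
  class(df) <- c("gene_sim_params", "data.frame")
  df
}

#' Default 52-gene panel parameters
#'
#' Mirrors the composition of the motivating targeted panel: 16 candidate
#' normalisation genes (stable: no rhythm, no age trend, low dispersion),
#' and 36 test genes of which 12 are core-clock/clock-controlled genes with
#' circadian amplitudes 0.15-0.6 (the least variable of them, "Cry2", is the
#' reference for the stability criterion), 4 carry age effects at the
#' magnitudes reported for an ageing liver (fold-changes 1.52, 0.74, 1.33
#' and 1.25 at 24 vs 3 months), and 20 are unremarkable fillers with mild
#' rhythms. Dispersion defaults to 0.002 (about 5% CV at typical
#' panel counts, Poisson noise included) with a mild age inflation of
#' 1e-4 per month, so that counting noise in the oldest animals roughly
#' doubles; these levels are calibrated so the procedure's working regime
#' (recoverable technical factors from 7 markers, detectable 1.25-fold age
#' effects at N = 24) is reachable, as documented in the vignette.
#'
#' @return A `gene_sim_params` data.frame with 52 rows.
#' @export
default_panel_params <- function() {
  candidates <- c("Atp5h", "Gsk3b", "Sirt2", "Nono", "Tprkb", "Tspo", "Ttr",
                  "Gr", "H3f3a", "Pqbp1", "Rora", "S100a1", "Aox3", "H3f3b",
                  "Tomm7", "Gapdh")
  clock <- c("Cry2", "Bmal1", "Per1", "Per2", "Cry1", "Nr1d1", "Nr1d2",
             "Dbp", "Tef", "Hlf", "Rorc", "Ciart")
  clock_amp <- c(0.15, 0.6, 0.5, 0.55, 0.35, 0.6, 0.5, 0.6, 0.45, 0.4, 0.3, 0.5)
  clock_phase <- c(14, 22, 10, 12, 16, 6, 8, 10, 10, 12, 18, 8)
  aged <- c("Csnk1e", "Glut2", "Sfpq", "Csnk1d")
  aged_lfc <- log(c(1.52, 0.74, 1.33, 1.25))
  fillers <- sprintf("test%02d", seq_len(20))
  rbind(
    gene_params(candidates, baseline = seq(3000, 800, length.out = 16),
                dispersion = 0.002, noise_inflation_per_age = 1e-4),
    gene_params(clock, baseline = seq(1500, 400, length.out = 12),
                circadian_amplitude = clock_amp, acrophase_h = clock_phase,
                dispersion = 0.002, noise_inflation_per_age = 1e-4),
    gene_params(aged, baseline = c(900, 1200, 1000, 800),
                circadian_amplitude = 0.1, acrophase_h = c(4, 12, 6, 4),
                age_log_fold_change = aged_lfc,
                dispersion = 0.002, noise_inflation_per_age = 1e-4),
    gene_params(fillers, baseline = round(seq(200, 2000, length.out = 20)),
                circadian_amplitude = 0.05,
                acrophase_h = seq(0, 22, length.out = 20),
                dispersion = 0.002, noise_inflation_per_age = 1e-4)
  )
}

.nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(rep(mu, length.out = n))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a targeted count panel over ages and zeitgeber times
#'
#' Draws counts from the generative model documented in [gene_params()],
#' with per-sample technical scale factors (library-size-like) that the
#' normalisation stage is meant to remove.
#'
#' @param design Sample design (see [panel_design()]).
#' @param params `gene_sim_params` for the panel genes.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param tech_sdlog Standard deviation of the log-normal technical factors
#'   (default 0.2, a typical library-size variation); ignored when
#'   `tech_factors` is supplied.
#' @param tech_factors Optional named per-sample technical factors.
#' @return List with `matrix` (genes x samples counts), `design`, and
#'   `truth` — a list with `params`, `tech_factors`, `stable_genes`
#'   (no rhythm, no age trend) and `perturbed_genes` (non-zero age effect).
#' @export
simulate_panel <- function(design, params = default_panel_params(), seed,
                           tech_sdlog = 0.2, tech_factors = NULL) {
  design <- validate_sample_design(design)
  if (!inherits(params, "gene_sim_params")) stop("params must come from gene_params()")
  set.seed(seed)
  n_s <- nrow(design)
  if (is.null(tech_factors)) {
    tech_factors <- stats::setNames(stats::rlnorm(n_s, 0, tech_sdlog),
                                    design$sample_id)
  } else {
    tech_factors <- tech_factors[design$sample_id]
    if (anyNA(tech_factors)) stop("tech_factors must cover every sample")
  }
  age0 <- min(design$age_months)
  age_span <- max(design$age_months) - age0
  age_frac <- if (age_span > 0) (design$age_months - age0) / age_span else
    rep(0, n_s)
  m <- matrix(0, nrow(params), n_s,
              dimnames = list(params$gene_id, design$sample_id))
  for (g in seq_len(nrow(params))) {
    p <- params[g, ]
    mu <- p$baseline *
      exp(p$age_log_fold_change * age_frac) *
      (1 + p$circadian_amplitude *
         cos(2 * pi * (design$zeitgeber_time_h - p$acrophase_h) / 24)) *
      tech_factors
    if (any(mu <= 0)) stop("non-positive simulated mean for gene ", p$gene_id)
    disp <- p$dispersion + p$noise_inflation_per_age * (design$age_months - age0)
    m[g, ] <- vapply(seq_len(n_s),
                     function(s) .nb_draw(1L, mu[s], disp[s]), numeric(1L))
  }
  truth <- list(
    params = params, tech_factors = tech_factors,
    stable_genes = params$gene_id[params$circadian_amplitude == 0 &
                                    params$age_log_fold_change == 0],
    perturbed_genes = params$gene_id[params$age_log_fold_change != 0]
  )
  list(matrix = m, design = design, truth = truth)
}

#' Simulate a genome-wide pooled RNA-seq age screen
#'
#' One library per age pool (pooling across the day removes circadian
#' structure), with log-normal baselines spanning several orders of
#' magnitude. A `stable_fraction` of genes is constructed stable: well
#' expressed (log-normal around 500 counts) with small pool-to-pool
#' biological variation (sd 0.05 on the log scale). The remaining genes get
#' heterogeneous pool-to-pool variability (per-gene sd uniform on
#' [0.1, 1]). Per-pool sequencing-depth factors (log-normal, sd 0.2) are
#' included, which the clr analysis must cancel.
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_age_pools Number of age-pool libraries (default 4).
#' @param stable_fraction Fraction of genes constructed stable.
#' @param seed Integer seed.
#' @param dispersion Count dispersion shared by all genes.
#' @return List with `matrix` (genes x pools) and `truth` (`stable_genes`,
#'   `variable_genes`, `depth_factors`, per-gene `baseline` and `bio_sd`).
#' @export
simulate_rnaseq_screen <- function(n_genes = 500, n_age_pools = 4,
                                   stable_fraction = 0.1, seed,
                                   dispersion = 0.01) {
  if (n_genes < 10) stop("n_genes must be at least 10")
  set.seed(seed)
  n_stable <- round(n_genes * stable_fraction)
  stable <- seq_len(n_stable)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  baseline <- stats::rlnorm(n_genes, meanlog = log(50), sdlog = 2.3)
  baseline[stable] <- stats::rlnorm(n_stable, meanlog = log(500), sdlog = 0.8)
  bio_sd <- stats::runif(n_genes, 0.1, 1)
  bio_sd[stable] <- 0.05
  depth <- stats::rlnorm(n_age_pools, 0, 0.2)
  pools <- sprintf("pool%d", seq_len(n_age_pools))
  m <- matrix(0, n_genes, n_age_pools, dimnames = list(gene_ids, pools))
  for (j in seq_len(n_age_pools)) {
    mu <- baseline * exp(stats::rnorm(n_genes, 0, bio_sd)) * depth[j]
    m[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  list(matrix = m,
       truth = list(stable_genes = gene_ids[stable],
                    variable_genes = gene_ids[-stable],
                    depth_factors = stats::setNames(depth, pools),
                    baseline = stats::setNames(baseline, gene_ids),
                    bio_sd = stats::setNames(bio_sd, gene_ids)))
}

#' Simulate a multi-study fold-change table
#'
#' Emulates a literature meta-analysis export: for each gene and study, a
#' symmetrised fold-change magnitude `exp(|z|)` with `z ~ N(0, scale_g)`.
#' Stable genes (small scale) concentrate below 1.2; a gene whose median
#' fold-change is to sit at `f` needs `scale = log(f) / qnorm(0.75)`.
#'
#' @param genes Gene ids.
#' @param n_studies Number of studies (default 130).
#' @param stability_profile Named per-gene scale of the log fold-change
#'   distribution; unnamed scalar recycled; default 0.05 for every gene.
#' @param seed Integer seed.
#' @return Fold-change table (`gene_id`, `study_id`, `fold_change`).
#' @export
simulate_meta_studies <- function(genes, n_studies = 130,
                                  stability_profile = 0.05, seed) {
  if (n_studies < 1) stop("n_studies must be at least 1")
  set.seed(seed)
  if (is.null(names(stability_profile))) {
    scales <- stats::setNames(rep_len(stability_profile, length(genes)), genes)
  } else {
    missing <- setdiff(genes, names(stability_profile))
    if (length(missing))
      stop("stability_profile missing gene(s): ", paste(missing, collapse = ", "))
    scales <- stability_profile[genes]
  }
  studies <- sprintf("study%03d", seq_len(n_studies))
  out <- lapply(genes, function(g) {
    data.frame(gene_id = g, study_id = studies,
               fold_change = exp(abs(stats::rnorm(n_studies, 0, scales[g]))),
               stringsAsFactors = FALSE)
  })
  validate_fold_change_table(do.call(rbind, out))
}

#' Simulate positive spike-in control counts
#'
#' Controls at known input amounts are read out through the same per-sample
#' technical factor as the genes, plus multiplicative measurement noise:
#' `observed_{s,i} = expected_i * tech_factor_s * lognormal(0, cv)`. The
#' constants recovered by [positive_control_constants()] then estimate
#' `1 / tech_factor_s`.
#'
#' @param tech_factors Named per-sample technical factors (e.g. from a
#'   [simulate_panel()] truth).
#' @param expected Named vector of control input amounts; the default spans
#'   128-fold in 2-fold steps like a typical spike-in ladder.
#' @param seed Integer seed.
#' @param cv Standard deviation of the log-normal measurement noise.
#' @return List with `observed` (controls x samples matrix) and `expected`.
#' @export
simulate_positive_controls <- function(tech_factors,
                                       expected = stats::setNames(
                                         128 / 2^(0:6), sprintf("ctl%d", 1:7)),
                                       seed, cv = 0.05) {
  set.seed(seed)
  samples <- names(tech_factors)
  if (is.null(samples)) stop("tech_factors must be named by sample")
  obs <- outer(expected, tech_factors) *
    matrix(stats::rlnorm(length(expected) * length(tech_factors), 0, cv),
           length(expected))
  dimnames(obs) <- list(names(expected), samples)
  list(observed = obs, expected = expected)
}

#' Simulate a complete multi-assay selection study with known truth
#'
#' Builds the full set of inputs the marker-selection procedure consumes,
#' with designated ground truth: two genome-wide pooled age screens (an
#' in-house one and an independent replication), a targeted circadian count
#' panel carrying the candidates alongside rhythmic clock genes, and a
#' multi-study fold-change table. Candidates are split into
#' `n_stable_candidates` constructed-stable genes (well expressed, no rhythm,
#' no age trend, low dispersion, tight fold-change profile) and `n_decoys`
#' constructed-variable decoys (rhythmic, age-trending, overdispersed, wide
#' fold-change profile).
#'
#' @param seed Integer seed; sub-stages use fixed offsets from it.
#' @param n_genes Genome-wide screen size.
#' @param n_stable_candidates Number of constructed-stable candidate genes.
#' @param n_decoys Number of constructed-variable decoy candidates.
#' @return List with `screens` (named list of count matrices), `panel`
#'   (`matrix`, `design`, `reference_gene`), `fold_changes`, `candidates`,
#'   and `truth` (`stable_candidates`, `decoy_candidates`).
#' @export
simulate_selection_study <- function(seed, n_genes = 500,
                                     n_stable_candidates = 20, n_decoys = 20) {
  screen1 <- simulate_rnaseq_screen(n_genes, n_age_pools = 4,
                                    stable_fraction = 0.1, seed = seed)
  screen2 <- simulate_rnaseq_screen(n_genes, n_age_pools = 4,
                                    stable_fraction = 0.1, seed = seed + 1000L)
  stable <- screen1$truth$stable_genes[seq_len(n_stable_candidates)]
  decoys <- screen1$truth$variable_genes[seq_len(n_decoys)]
  candidates <- c(stable, decoys)

  params <- rbind(
    gene_params(stable, baseline = 1500, dispersion = 0.005,
                noise_inflation_per_age = 1e-4),
    gene_params(decoys, baseline = 1000, circadian_amplitude = 0.35,
                acrophase_h = seq(0, 22, length.out = n_decoys),
                age_log_fold_change = log(1.6), dispersion = 0.02,
                noise_inflation_per_age = 2e-4),
    gene_params("Cry2", baseline = 1200, circadian_amplitude = 0.2,
                acrophase_h = 14, dispersion = 0.005),
    gene_params(sprintf("clock%02d", 1:10), baseline = 800,
                circadian_amplitude = seq(0.3, 0.6, length.out = 10),
                acrophase_h = seq(1, 21, length.out = 10), dispersion = 0.01)
  )
  panel <- simulate_panel(panel_design(), params, seed = seed + 2000L)

  scales <- stats::setNames(
    c(rep(0.05, n_stable_candidates),
      rep(log(1.3) / stats::qnorm(0.75), n_decoys)), candidates)
  meta <- simulate_meta_studies(candidates, n_studies = 130,
                                stability_profile = scales,
                                seed = seed + 3000L)
  list(screens = list(rnaseq = screen1$matrix, public = screen2$matrix),
       panel = list(matrix = panel$matrix, design = panel$design,
                    reference_gene = "Cry2"),
       fold_changes = meta, candidates = candidates,
       truth = list(stable_candidates = stable, decoy_candidates = decoys))
}
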