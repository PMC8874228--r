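#' Simulation configuration for the organoid/embryonic study design
#'
#' Defines the generative model used throughout the test-bench: a
#' gamma-Poisson (negative binomial) count law over a structured gene
#' universe (per-type marker programs, developmental time-varying genes,
#' genotype-responsive genes, a mitochondrial block) and a latent
#' developmental-time axis per cell. The default values encode the study
#' conditions the pipeline is meant to exercise: four organoid conditions
#' (WT35, WT70, MUT35, MUT70) of ~2,500 cells each, an embryonic reference
#' atlas of weeks 6-11, eight generic cell types led by a large
#' neuroblast-like ("NB in vitro") population, and a mutant phenotype of
#' accelerated early differentiation followed by maturation arrest.
#'
#' Latent developmental time is measured in embryonic-week units: day-35
#' organoids sit near week 9 and day-70 near week 10 (the developmental
#' stages their transcriptomes match), and the reference atlas spans weeks
#' 6-11 directly.
#'
#' @param n_genes total genes, including structured blocks.
#' @param n_cells_per_condition cells per organoid condition.
#' @param n_cells_per_week cells per reference-atlas week.
#' @param cell_types generic cell-type names in lineage order.
#' @param type_proportions condition x type matrix of mixture weights (rows
#'   sum to 1). Defaults encode a neuroblast-dominated day-35 composition that
#'   diversifies by day-70 in WT, while MUT lacks progenitors/pericytes, has
#'   excess early glia, and its neuroblast share grows over time.
#' @param atlas_proportions type proportions shared by all atlas weeks.
#' @param type_time_offset per-type offset (weeks) added to the condition's
#'   latent time. Defaults to zero for every type: the developmental stage is
#'   modeled as a property of the sample, with lineage identity expressed
#'   through marker programs. Nonzero offsets (e.g. NB earliest, mDN latest)
#'   turn a single condition into a lineage ladder for trajectory tests.
#'   Offsets are centered against the condition's expected composition so the
#'   sample's mean latent time always equals its nominal stage.
#' @param n_markers_per_type marker genes per type (disjoint programs).
#' @param marker_fold multiplicative elevation (>= 1) of a marker in its type.
#' @param n_time_genes genes whose expected expression varies with latent
#'   time as `exp(slope * t)`.
#' @param time_slope_range absolute slope range (per week); signs alternate.
#' @param weeks ordered reference timepoints.
#' @param condition_time named latent time (weeks) per organoid condition,
#'   before any genotype effect.
#' @param mutant_shift forward latent-time shift (weeks) applied to MUT
#'   early-timepoint cells (accelerated differentiation).
#' @param mutant_arrest latent-time cap (weeks) applied to MUT
#'   late-timepoint cells (maturation arrest).
#' @param n_de_genes genes given a genotype (MUT vs WT) expression effect.
#' @param de_log2fc absolute injected log2 fold change (half up, half down).
#' @param latent_time_sd per-cell Gaussian jitter of latent time (weeks).
#' @param nb_dispersion negative-binomial dispersion phi (> 0), so that
#'   `var = mu + phi * mu^2`.
#' @param library_size_lognormal `c(meanlog, sdlog)` of the per-cell size
#'   factor.
#' @param baseline_lognormal `c(meanlog, sdlog)` of per-gene baseline means
#'   for unstructured background genes.
#' @param structured_baseline_lognormal `c(meanlog, sdlog)` of baseline means
#'   for the structured blocks (markers, time-varying and
#'   genotype-responsive genes). These are kept moderately expressed:
#'   canonical markers and responsive genes are, by definition, measurably
#'   expressed, and effects injected into unexpressed genes are
#'   unidentifiable by any method.
#' @param mt_fraction_beta `c(shape1, shape2)` of the per-cell mitochondrial
#'   count fraction.
#' @param n_mt_genes size of the mitochondrial gene block (prefix "MT-").
#' @param doublet_rate probability that a cell is a doublet (its counts are
#'   the sum of two independent expression profiles).
#' @param seed integer master seed; identical configs give identical data.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_cells_per_condition = 2500,
                       n_cells_per_week = 2000,
                       cell_types = c("NB_invitro", "progenitor", "yNEUR",
                                      "mDN", "nonDN", "glia", "pericyte",
                                      "endothelial"),
                       type_proportions = NULL,
                       atlas_proportions = NULL,
                       type_time_offset = NULL,
                       n_markers_per_type = 20,
                       marker_fold = 4,
                       n_time_genes = 150,
                       time_slope_range = c(0.4, 1.0),
                       weeks = 6:11,
                       condition_time = c(WT35 = 9, WT70 = 10,
                                          MUT35 = 9, MUT70 = 10),
                       mutant_shift = 0.5,
                       mutant_arrest = 9.5,
                       n_de_genes = 100,
                       de_log2fc = 1,
                       latent_time_sd = 0.3,
                       nb_dispersion = 0.5,
                       library_size_lognormal = c(meanlog = 0, sdlog = 0.3),
                       baseline_lognormal = c(meanlog = -0.5, sdlog = 1),
                       structured_baseline_lognormal = c(meanlog = 0.3,
                                                         sdlog = 0.5),
                       mt_fraction_beta = c(2, 18),
                       n_mt_genes = 13,
                       doublet_rate = 0.02,
                       seed = 1L) {
  k <- length(cell_types)
  if (is.null(type_proportions)) {
    stopifnot(identical(cell_types, eval(formals(sim_config)$cell_types)))
    type_proportions <- rbind(
      WT35  = c(0.62, 0.03, 0.17, 0.06, 0.04, 0.05, 0.02, 0.01),
      WT70  = c(0.51, 0.05, 0.12, 0.10, 0.07, 0.10, 0.04, 0.01),
      MUT35 = c(0.30, 0.01, 0.20, 0.12, 0.10, 0.25, 0.01, 0.01),
      MUT70 = c(0.55, 0.01, 0.15, 0.08, 0.07, 0.12, 0.01, 0.01))
    colnames(type_proportions) <- cell_types
  }
  if (is.null(atlas_proportions)) {
    stopifnot(length(cell_types) == 8L)
    atlas_proportions <- stats::setNames(
      c(0.02, 0.25, 0.15, 0.12, 0.12, 0.20, 0.06, 0.08), cell_types)
  }
  if (is.null(type_time_offset))
    type_time_offset <- stats::setNames(rep(0, k), cell_types)
  cfg <- structure(list(
    n_genes = as.integer(n_genes),
    n_cells_per_condition = as.integer(n_cells_per_condition),
    n_cells_per_week = as.integer(n_cells_per_week),
    cell_types = cell_types,
    type_proportions = as.matrix(type_proportions),
    atlas_proportions = atlas_proportions,
    type_time_offset = type_time_offset,
    n_markers_per_type = as.integer(n_markers_per_type),
    marker_fold = marker_fold,
    n_time_genes = as.integer(n_time_genes),
    time_slope_range = time_slope_range,
    weeks = weeks,
    condition_time = condition_time,
    mutant_shift = mutant_shift,
    mutant_arrest = mutant_arrest,
    n_de_genes = as.integer(n_de_genes),
    de_log2fc = de_log2fc,
    latent_time_sd = latent_time_sd,
    nb_dispersion = nb_dispersion,
    library_size_lognormal = library_size_lognormal,
    baseline_lognormal = baseline_lognormal,
    structured_baseline_lognormal = structured_baseline_lognormal,
    mt_fraction_beta = mt_fraction_beta,
    n_mt_genes = as.integer(n_mt_genes),
    doublet_rate = doublet_rate,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the simplex constraint on type proportions (to 1e-8), disjointness
#' and sizing of the gene blocks, and that every distributional parameter is
#' strictly inside its legal domain. Called by [sim_config()]; exported so a
#' hand-edited configuration can be re-checked.
#'
#' @param cfg a `sim_config` object.
#' @return `cfg`, invisibly, or an error describing the violated constraint.
#' @export
validate_sim_config <- function(cfg) {
  err <- function(...) stop("configuration error: ", ..., call. = FALSE)
  if (cfg$n_genes < 1 || cfg$n_cells_per_condition < 1 || cfg$n_cells_per_week < 1)
    err("zero genes or cells")
  tp <- cfg$type_proportions
  if (!setequal(colnames(tp), cfg$cell_types))
    err("type_proportions columns must match cell_types")
  if (any(tp < 0)) err("negative type proportion")
  bad <- abs(rowSums(tp) - 1) > 1e-8
  if (any(bad))
    err("type_proportions must sum to 1 per condition (violated: ",
        paste(rownames(tp)[bad], collapse = ", "), ")")
  if (abs(sum(cfg$atlas_proportions) - 1) > 1e-8)
    err("atlas_proportions must sum to 1")
  n_struct <- length(cfg$cell_types) * cfg$n_markers_per_type +
    cfg$n_time_genes + cfg$n_de_genes + cfg$n_mt_genes
  if (cfg$n_genes < n_struct + 1)
    err("n_genes too small for the configured gene blocks (need > ", n_struct, ")")
  if (cfg$marker_fold < 1) err("marker_fold must be >= 1")
  if (cfg$nb_dispersion <= 0) err("nb_dispersion must be > 0")
  if (cfg$latent_time_sd < 0) err("latent_time_sd must be >= 0")
  if (cfg$library_size_lognormal[2] < 0) err("library size sdlog must be >= 0")
  if (any(cfg$mt_fraction_beta <= 0)) err("mt_fraction_beta must be > 0")
  if (cfg$doublet_rate < 0 || cfg$doublet_rate > 1)
    err("doublet_rate must be in [0,1]")
  if (length(cfg$weeks) && anyDuplicated(cfg$weeks)) err("duplicate weeks")
  invisible(cfg)
}

# curated marker names so the synthetic programs read like midbrain biology;
# padded with generic names per type
.curated_markers <- list(
  NB_invitro  = c("PTN", "HES5", "VIM2L"),
  progenitor  = c("SOX2", "MSI1", "CENPF"),
  yNEUR       = c("NCAM1", "STMN1", "DCX"),
  mDN         = c("TH", "FOXA2", "EN1", "EN2", "KCNJ6", "NR4A2", "LMX1A"),
  nonDN       = c("MAP2", "SYP", "SYT1", "SLC17A6", "GAD1"),
  glia        = c("SLC1A3", "GFAP", "S100B", "VIM"),
  pericyte    = c("CSPG4", "MCAM", "SPARC"),
  endothelial = c("CDH5", "CLDN5", "PECAM1"))

.mt_gene_names <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-CO3",
                    "MT-ATP6", "MT-ATP8", "MT-ND3", "MT-ND4", "MT-ND4L",
                    "MT-ND5", "MT-ND6", "MT-CYB")

# internal: deterministic gene universe (names, block indices, per-gene
# baselines, slopes, genotype effects, marker-matrix truth)
.gene_universe <- function(cfg) {
  k <- length(cfg$cell_types)
  nm_per <- cfg$n_markers_per_type
  names_mk <- unlist(lapply(seq_len(k), function(i) {
    ty <- cfg$cell_types[i]
    cur <- .curated_markers[[ty]]
    if (is.null(cur)) cur <- character()
    cur <- cur[seq_len(min(length(cur), nm_per))]
    extra <- nm_per - length(cur)
    c(cur, if (extra > 0) sprintf("M-%s-%02d", ty, seq_len(extra)))
  }))
  idx_mk <- matrix(seq_len(k * nm_per), nrow = nm_per)  # column per type
  colnames(idx_mk) <- cfg$cell_types
  off <- k * nm_per
  idx_time <- off + seq_len(cfg$n_time_genes)
  off <- off + cfg$n_time_genes
  idx_de <- off + seq_len(cfg$n_de_genes)
  off <- off + cfg$n_de_genes
  n_mt <- cfg$n_mt_genes
  n_bg <- cfg$n_genes - off - n_mt
  idx_bg <- off + seq_len(n_bg)
  idx_mt <- off + n_bg + seq_len(n_mt)
  gene_ids <- character(cfg$n_genes)
  gene_ids[seq_along(names_mk)] <- names_mk
  gene_ids[idx_time] <- sprintf("TDG-%04d", seq_along(idx_time))
  gene_ids[idx_de] <- sprintf("GRG-%04d", seq_along(idx_de))
  gene_ids[idx_bg] <- sprintf("BG-%05d", seq_along(idx_bg))
  gene_ids[idx_mt] <- c(.mt_gene_names, sprintf("MT-X%02d", seq_len(max(0, n_mt - 13))))[seq_len(n_mt)]

  # slopes and genotype effects: deterministic in the config, no RNG draws
  sl <- cfg$time_slope_range
  mag <- if (cfg$n_time_genes > 0)
    seq(sl[1], sl[2], length.out = cfg$n_time_genes) else numeric()
  slopes <- mag * rep_len(c(1, -1), cfg$n_time_genes)
  de_lfc <- rep_len(c(cfg$de_log2fc, -cfg$de_log2fc), cfg$n_de_genes)

  set.seed(cfg$seed)
  base <- stats::rlnorm(cfg$n_genes, cfg$baseline_lognormal[1],
                        cfg$baseline_lognormal[2])
  idx_struct <- c(as.vector(idx_mk), idx_time, idx_de)
  if (length(idx_struct))
    base[idx_struct] <- stats::rlnorm(length(idx_struct),
                                      cfg$structured_baseline_lognormal[1],
                                      cfg$structured_baseline_lognormal[2])

  mk_truth <- matrix(0L, cfg$n_genes, k,
                     dimnames = list(gene_ids, cfg$cell_types))
  for (i in seq_len(k)) mk_truth[idx_mk[, i], i] <- 1L

  list(gene_ids = gene_ids, base = base,
       idx_marker = idx_mk, idx_time = idx_time, idx_de = idx_de,
       idx_mt = idx_mt, slopes = slopes, de_lfc = de_lfc,
       marker_matrix_truth = mk_truth)
}

#' Extract the ground-truth marker matrix from a simulation
#'
#' @param truth a `SyntheticTruth` list as returned by [simulate_dataset()].
#' @return a [marker_matrix()] with the identity subtype-to-class mapping.
#' @export
truth_marker_matrix <- function(truth) {
  marker_matrix(truth$marker_matrix_truth)
}

#' Apply the mutant genotype effect to simulated ground truth
#'
#' Encodes the LRRK2-mutant phenotype on the latent developmental-time axis:
#' early-timepoint mutant cells are shifted forward by `mutant_shift`
#' (accelerated differentiation) and late-timepoint mutant cells are capped
#' at `mutant_arrest` (maturation arrest). Also records the injected
#' genotype expression effects (`de_gene_truth`).
#'
#' @param truth a `SyntheticTruth` list for a MUT condition.
#' @param cfg the `sim_config` in force.
#' @return the modified truth list.
#' @export
apply_genotype_effect <- function(truth, cfg) {
  if (!identical(truth$genotype, "MUT"))
    stop("genotype effect applies only to MUT conditions")
  wt_late_mean <- max(cfg$condition_time) + cfg$mutant_shift
  if (is.finite(cfg$mutant_arrest) &&
      cfg$mutant_arrest < min(cfg$condition_time) + cfg$mutant_shift)
    stop("configuration error: mutant_arrest below the shifted early-timepoint ",
         "mean would invert the phenotype")
  t <- truth$true_latent_time + cfg$mutant_shift
  if (truth$timepoint == "late") t <- pmin(t, cfg$mutant_arrest)
  truth$true_latent_time <- t
  uni <- truth$.universe
  truth$de_gene_truth <- if (cfg$n_de_genes > 0)
    data.frame(gene = uni$gene_ids[uni$idx_de], log2fc = uni$de_lfc,
               stringsAsFactors = FALSE)
  else data.frame(gene = character(), log2fc = numeric())
  truth$de_marker_overlap <- intersect(truth$de_gene_truth$gene,
                                       rownames(uni$marker_matrix_truth)[
                                         rowSums(uni$marker_matrix_truth) > 0])
  truth
}

# internal: dense negative-binomial draws
.draw_counts <- function(mu, phi) {
  n <- length(mu)
  cnt <- stats::rnbinom(n, size = 1 / phi, mu = mu)
  dim(cnt) <- dim(mu)
  cnt
}

# internal: expected-expression matrix (genes x cells) for given truth
.expected_mu <- function(cfg, uni, type, latent_time, genotype, size_factor,
                         mt_frac) {
  n <- length(type)
  mu <- matrix(rep(uni$base, n), nrow = cfg$n_genes)
  # marker elevation in own type
  for (ty in colnames(uni$idx_marker)) {
    cols <- which(type == ty)
    if (length(cols))
      mu[uni$idx_marker[, ty], cols] <- mu[uni$idx_marker[, ty], cols] * cfg$marker_fold
  }
  # time-varying genes, centered at mid-reference so magnitudes stay tame
  if (length(uni$idx_time)) {
    t0 <- mean(range(cfg$weeks))
    mu[uni$idx_time, ] <- mu[uni$idx_time, ] *
      exp(outer(uni$slopes, latent_time - t0))
  }
  # genotype-responsive genes
  if (genotype == "MUT" && length(uni$idx_de))
    mu[uni$idx_de, ] <- mu[uni$idx_de, ] * 2^uni$de_lfc
  # mitochondrial block: scaled per cell to hit the drawn MT count fraction
  if (length(uni$idx_mt)) {
    non_mt_tot <- colSums(mu[-uni$idx_mt, , drop = FALSE])
    mt_base <- uni$base[uni$idx_mt]
    mt_w <- mt_base / sum(mt_base)
    target_mt <- mt_frac / (1 - mt_frac) * non_mt_tot
    mu[uni$idx_mt, ] <- outer(mt_w, target_mt)
  }
  sweep(mu, 2, size_factor, "*")
}

#' Simulate one condition's count matrix with ground truth
#'
#' Draws cells for one organoid condition (WT35/WT70/MUT35/MUT70 by default)
#' or one atlas week (`"w6"` ... `"w11"`). Expected expression per gene and
#' cell is `baseline * marker_fold^(marker of own type) * exp(slope * t) *
#' 2^(genotype effect) * size_factor`, and counts are drawn from a negative
#' binomial with dispersion `nb_dispersion`. MUT conditions receive the
#' genotype effect of [apply_genotype_effect()] before counts are drawn, so
#' the phenotype is present in the data.
#'
#' @param cfg a `sim_config`.
#' @param condition one of the configured condition names, or `"w<week>"`.
#' @return a list `(counts, truth)`: a [count_matrix()] and a
#'   `SyntheticTruth` list (`true_type`, `true_latent_time`,
#'   `marker_matrix_truth`, `de_gene_truth`, `doublet_flags`).
#' @export
simulate_dataset <- function(cfg, condition) {
  validate_sim_config(cfg)
  uni <- .gene_universe(cfg)
  atlas_names <- paste0("w", cfg$weeks)
  all_conds <- c(rownames(cfg$type_proportions), atlas_names)
  ci <- match(condition, all_conds)
  if (is.na(ci)) stop("configuration error: unknown condition '", condition, "'")
  is_atlas <- condition %in% atlas_names
  n <- if (is_atlas) cfg$n_cells_per_week else cfg$n_cells_per_condition
  set.seed((cfg$seed %% 200000L) * 10000L + 100L + ci)

  if (is_atlas) {
    probs <- cfg$atlas_proportions[cfg$cell_types]
    t_cond <- cfg$weeks[match(condition, atlas_names)]
    genotype <- "WT"
    day_or_week <- t_cond
    timepoint <- "atlas"
  } else {
    probs <- cfg$type_proportions[condition, cfg$cell_types]
    t_cond <- cfg$condition_time[[condition]]
    genotype <- if (grepl("^MUT", condition)) "MUT" else "WT"
    day_or_week <- sub("^(WT|MUT)", "", condition)
    timepoint <- if (t_cond >= max(cfg$condition_time) - 1e-9) "late" else "early"
  }

  type <- sample(cfg$cell_types, n, replace = TRUE, prob = probs)
  # condition_time is the composition-averaged developmental time of the
  # sample: per-type offsets are centered against the expected composition
  # so a sample's mean latent time equals its nominal stage
  t_center <- t_cond - sum(probs * cfg$type_time_offset[names(probs)])
  latent <- t_center + cfg$type_time_offset[type] +
    stats::rnorm(n, 0, cfg$latent_time_sd)
  size_factor <- stats::rlnorm(n, cfg$library_size_lognormal[1],
                               cfg$library_size_lognormal[2])
  mt_frac <- stats::rbeta(n, cfg$mt_fraction_beta[1], cfg$mt_fraction_beta[2])
  doublet <- stats::runif(n) < cfg$doublet_rate

  truth <- list(true_type = type, true_latent_time = latent,
                genotype = genotype, condition = condition,
                timepoint = timepoint,
                marker_matrix_truth = uni$marker_matrix_truth,
                de_gene_truth = data.frame(gene = character(),
                                           log2fc = numeric()),
                de_marker_overlap = character(),
                doublet_flags = doublet, .universe = uni)
  if (genotype == "MUT") truth <- apply_genotype_effect(truth, cfg)

  # doublets add a second, independently drawn profile of a random partner
  partner <- rep(NA_integer_, n)
  if (any(doublet))
    partner[doublet] <- sample(seq_len(n), sum(doublet), replace = TRUE)

  # draw counts in cell blocks to bound dense memory
  blocks <- split(seq_len(n), ceiling(seq_len(n) / 500))
  parts <- lapply(blocks, function(ix) {
    mu <- .expected_mu(cfg, uni, type[ix], truth$true_latent_time[ix],
                       genotype, size_factor[ix], mt_frac[ix])
    cnt <- .draw_counts(mu, cfg$nb_dispersion)
    dbl <- which(doublet[ix])
    if (length(dbl)) {
      pt <- partner[ix][dbl]
      mu2 <- .expected_mu(cfg, uni, type[pt], truth$true_latent_time[pt],
                          genotype, size_factor[pt], mt_frac[pt])
      cnt[, dbl] <- cnt[, dbl, drop = FALSE] + .draw_counts(mu2, cfg$nb_dispersion)
    }
    methods::as(methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                            "CsparseMatrix"), "generalMatrix")
  })
  counts <- do.call(cbind, parts)

  cell_ids <- sprintf("%s_c%05d", condition, seq_len(n))
  meta <- data.frame(condition = rep(condition, n),
                     genotype = rep(genotype, n),
                     day_or_week = rep(day_or_week, n),
                     stringsAsFactors = FALSE)
  rownames(counts) <- uni$gene_ids
  colnames(counts) <- cell_ids
  cm <- count_matrix(counts, cell_meta = meta)
  list(counts = cm, truth = truth)
}

#' Simulate the embryonic reference atlas
#'
#' One dataset per configured week, sharing the gene universe with the
#' organoid conditions; latent time equals the week (plus per-type offsets
#' and jitter), so time-varying genes increase or decrease monotonically
#' across weeks.
#'
#' @param cfg a `sim_config`.
#' @return named list (one element per week, `"w6"` ...) of
#'   `(counts, truth)` pairs as in [simulate_dataset()].
#' @export
simulate_reference_atlas <- function(cfg) {
  validate_sim_config(cfg)
  if (length(cfg$weeks) < 2)
    stop("configuration error: the reference atlas needs at least 2 weeks")
  out <- lapply(cfg$weeks, function(w) simulate_dataset(cfg, paste0("w", w)))
  names(out) <- paste0("w", cfg$weeks)
  out
}
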