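#' Configuration for the synthetic single-cell cohort generator
#'
#' The generator emulates the statistical structure the subTME analysis
#' assumes: per-sample cell-subtype proportions with planted co-abundance
#' modules (a shared per-sample latent factor shifts the log-concentration of
#' a Dirichlet draw for every subtype in a module), a tumor/normal abundance
#' shift per module, subtype marker genes with controlled expressing-cell
#' fractions inside vs outside the subtype (Bernoulli expressing gate times a
#' negative-binomial count), planted ligand-receptor pairs up-scaled in their
#' sender/receiver subtypes, and exponential survival driven by bulk marker
#' expression.
#'
#' Defaults describe a 40-sample cohort (60% tumor), 3 major cell types with 4
#' subtypes each, and two planted modules that each recruit one subtype from
#' every major type. Cross-major module membership is deliberate: subtypes of
#' one major type are compositionally coupled (their Dirichlet proportions sum
#' to 1), so only cross-major members can be independent when
#' `module_strength = 0`.
#'
#' @param n_samples number of samples (>= 4).
#' @param tumor_fraction fraction of samples labelled tumor.
#' @param cells_per_sample expected cells per sample.
#' @param majors named list: major type -> character vector of subtype names.
#' @param module_assignment named character vector: subtype -> module id.
#' @param module_strength latent-factor loading (>= 0) on log-concentrations.
#' @param tumor_shift named numeric: module id -> additive log-concentration
#'   shift applied in tumor samples.
#' @param base_concentration Dirichlet concentration of an unshifted subtype.
#' @param n_markers marker genes per subtype.
#' @param p_in,p_out expressing-cell probability for a marker inside / outside
#'   its subtype (0 <= p_out < p_in <= 1).
#' @param nb_mean,nb_dispersion negative-binomial mean and size of marker
#'   counts in expressing cells.
#' @param n_background background genes expressed everywhere.
#' @param bg_expr_prob,bg_mean expressing probability and NB mean of
#'   background genes.
#' @param planted_lr data.frame with columns `pair_id`, `ligand`, `sender`,
#'   `receptor`, `receiver`, `fold`; ligand/receptor genes are added to the
#'   gene universe, expressed broadly, and their NB mean is multiplied by
#'   `fold` in the sender/receiver subtype respectively.
#' @param baseline_hazard,betas,censor_rate survival generator: exponential
#'   baseline hazard, named log-hazard coefficients on z-scored normalized
#'   bulk expression, and target censoring fraction in `[0, 1)`.
#' @param n_spots,spatial_noise spatial generator: number of spots (a near
#'   square grid) and spot-level noise.
#' @param seed integer RNG seed.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(
    n_samples = 40,
    tumor_fraction = 0.6,
    cells_per_sample = 300,
    majors = list(
      Lymphoid = c("CD8Tex", "Treg", "CD8Teff", "NK"),
      Myeloid = c("Macro_APOE", "Macro_SPP1", "cDC", "Mono"),
      Stromal = c("ecm_myCAF", "iCAF", "Endo_cap", "Endo_tip")
    ),
    module_assignment = c(
      CD8Tex = "module1", Macro_APOE = "module1", ecm_myCAF = "module1",
      CD8Teff = "module2", cDC = "module2", Endo_cap = "module2"
    ),
    module_strength = 2,
    tumor_shift = c(module1 = 4, module2 = 0),
    base_concentration = 5,
    n_markers = 10, p_in = 0.8, p_out = 0.05,
    nb_mean = 4, nb_dispersion = 2,
    n_background = 60, bg_expr_prob = 0.6, bg_mean = 2,
    planted_lr = data.frame(
      pair_id = c("PLR1", "PLR2"),
      ligand = c("LIGA", "LIGB"), sender = c("ecm_myCAF", "Macro_APOE"),
      receptor = c("RECA", "RECB"), receiver = c("CD8Tex", "ecm_myCAF"),
      fold = c(3, 3), stringsAsFactors = FALSE
    ),
    baseline_hazard = 0.01, betas = numeric(0), censor_rate = 0.3,
    n_spots = 400, spatial_noise = 0.3,
    seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_samples >= 4, tumor_fraction > 0, tumor_fraction < 1,
    p_out >= 0, p_out < p_in, p_in <= 1,
    module_strength >= 0, censor_rate >= 0, censor_rate < 1,
    all(module_assignment %in% names(tumor_shift) | !length(module_assignment))
  )
  subtypes <- unlist(cfg$majors, use.names = FALSE)
  if (anyDuplicated(subtypes)) stop("subtype names must be globally unique")
  bad <- setdiff(names(cfg$module_assignment), subtypes)
  if (length(bad)) stop("module_assignment names unknown subtype(s): ",
    paste(bad, collapse = ", "))
  class(cfg) <- "sim_config"
  cfg
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

marker_gene_name <- function(subtype, i) toupper(sprintf("%s.M%02d", subtype, i))

#' Simulate a single-cell cohort with planted structure
#'
#' @param config a [simulation_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return list with `matrix` (an [expression_matrix()], counts only),
#'   `annotation` (a [cell_annotation()]), and `truth` — a list with the
#'   planted module assignment, a marker table (gene, subtype, p_in, p_out)
#'   and the planted L-R table.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  majors <- cfg$majors
  subtypes <- unlist(majors, use.names = FALSE)
  major_of <- rep(names(majors), lengths(majors))
  names(major_of) <- subtypes
  mods <- cfg$module_assignment
  module_ids <- unique(mods)

  n_t <- round(cfg$n_samples * cfg$tumor_fraction)
  tissue <- rep(c("tumor", "normal"), c(n_t, cfg$n_samples - n_t))
  sample_ids <- sprintf("S%02d", seq_len(cfg$n_samples))

  ann_list <- vector("list", cfg$n_samples)
  for (k in seq_len(cfg$n_samples)) {
    f <- stats::setNames(stats::rnorm(length(module_ids)), module_ids)
    major_share <- .rdirichlet(rep(20, length(majors)))
    n_major <- as.vector(stats::rmultinom(1, cfg$cells_per_sample, major_share))
    rows <- list()
    for (mi in seq_along(majors)) {
      subs <- majors[[mi]]
      conc <- rep(cfg$base_concentration, length(subs))
      for (si in seq_along(subs)) {
        m <- mods[subs[si]]
        if (!is.na(m)) {
          lsh <- cfg$module_strength * f[[m]] +
            if (tissue[k] == "tumor") cfg$tumor_shift[[m]] else 0
          conc[si] <- conc[si] * exp(lsh)
        }
      }
      p <- .rdirichlet(conc)
      n_sub <- as.vector(stats::rmultinom(1, n_major[mi], p))
      rows[[mi]] <- data.frame(
        subtype = rep(subs, n_sub),
        major_type = names(majors)[mi], stringsAsFactors = FALSE
      )
    }
    rows <- do.call(rbind, rows)
    if (nrow(rows)) {
      rows$sample_id <- sample_ids[k]
      rows$tissue <- tissue[k]
    }
    ann_list[[k]] <- rows
  }
  ann <- do.call(rbind, ann_list)
  ann$cell_id <- sprintf("C%06d", seq_len(nrow(ann)))
  n_cells <- nrow(ann)

  # gene universe: per-subtype markers, shared background, planted L-R genes
  marker_tab <- do.call(rbind, lapply(subtypes, function(s) {
    data.frame(
      gene = marker_gene_name(s, seq_len(cfg$n_markers)), subtype = s,
      p_in = cfg$p_in, p_out = cfg$p_out, stringsAsFactors = FALSE
    )
  }))
  bg_genes <- sprintf("BG%03d", seq_len(cfg$n_background))
  lr <- cfg$planted_lr
  lr_genes <- if (nrow(lr)) toupper(unique(c(lr$ligand, lr$receptor))) else character(0)
  all_genes <- c(marker_tab$gene, bg_genes, lr_genes)

  counts <- matrix(0L, nrow = length(all_genes), ncol = n_cells,
    dimnames = list(all_genes, ann$cell_id))
  draw_block <- function(p_expr, mu) {
    n <- length(p_expr)
    stats::rbinom(n, 1L, p_expr) *
      stats::rnbinom(n, size = cfg$nb_dispersion, mu = mu)
  }
  for (i in seq_len(nrow(marker_tab))) {
    inside <- ann$subtype == marker_tab$subtype[i]
    p <- ifelse(inside, cfg$p_in, cfg$p_out)
    counts[marker_tab$gene[i], ] <- draw_block(p, cfg$nb_mean)
  }
  for (g in bg_genes) {
    counts[g, ] <- draw_block(rep(cfg$bg_expr_prob, n_cells), cfg$bg_mean)
  }
  if (nrow(lr)) {
    for (g in lr_genes) {
      fold <- rep(1, n_cells)
      for (r in seq_len(nrow(lr))) {
        if (toupper(lr$ligand[r]) == g) fold[ann$subtype == lr$sender[r]] <- lr$fold[r]
        if (toupper(lr$receptor[r]) == g) fold[ann$subtype == lr$receiver[r]] <- lr$fold[r]
      }
      counts[g, ] <- draw_block(rep(0.5, n_cells), cfg$bg_mean * fold)
    }
  }

  m <- expression_matrix(counts)
  truth <- list(
    module_assignment = mods,
    markers = marker_tab,
    planted_lr = lr,
    seed = seed
  )
  list(matrix = m, annotation = cell_annotation(ann, m), truth = truth)
}

#' Pseudo-bulk aggregation of a single-cell cohort
#'
#' Sums raw counts over each sample's cells, giving a gene x sample matrix.
#'
#' @param sc an `expr_matrix` of single-cell counts.
#' @param ann matching [cell_annotation()].
#' @return an `expr_matrix` of bulk counts (one column per sample).
#' @export
simulate_bulk <- function(sc, ann) {
  stopifnot(inherits(sc, "expr_matrix"))
  ann <- cell_annotation(ann, sc)
  ord <- match(observations(sc), ann$cell_id)
  if (anyNA(ord)) stop("annotation must cover every cell in the matrix")
  samp <- factor(ann$sample_id[ord])
  ind <- Matrix::sparseMatrix(
    i = seq_along(samp), j = as.integer(samp), x = 1,
    dims = c(length(samp), nlevels(samp))
  )
  bulk <- sc$counts %*% ind
  dimnames(bulk) <- list(genes(sc), levels(samp))
  expression_matrix(bulk)
}

#' Simulate exponential survival driven by bulk expression
#'
#' Event times are exponential with subject hazard
#' `baseline_hazard * exp(sum(beta_g * z_g))`, where `z_g` is the per-gene
#' z-scored normalized bulk expression. Censoring times are independent
#' uniform on `(0, tau)` with `tau` solved so that the expected censoring
#' fraction matches `censor_rate`.
#'
#' @param config a [simulation_config()] (uses `baseline_hazard`, `betas`,
#'   `censor_rate`).
#' @param bulk an `expr_matrix` of bulk expression with a normalized layer.
#' @param seed optional seed overriding `config$seed`.
#' @return data.frame with `sample_id`, `time`, `event`.
#' @export
simulate_survival <- function(config, bulk, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(bulk, "expr_matrix"))
  set.seed(seed)
  betas <- config$betas
  missing_genes <- setdiff(names(betas), genes(bulk))
  if (length(missing_genes)) {
    stop("beta gene(s) absent from bulk: ", paste(missing_genes, collapse = ", "))
  }
  n <- ncol(bulk$counts)
  lp <- rep(0, n)
  if (length(betas)) {
    x <- as.matrix(.norm_layer(bulk)[names(betas), , drop = FALSE])
    z <- t(scale(t(x)))
    z[is.nan(z)] <- 0
    lp <- as.vector(crossprod(z, betas))
  }
  h <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate = h)
  if (config$censor_rate > 0) {
    p_cens <- function(log_tau) {
      tau <- exp(log_tau)
      mean((1 - exp(-h * tau)) / (h * tau)) - config$censor_rate
    }
    log_tau <- stats::uniroot(p_cens, lower = -20, upper = 40)$root
    c_time <- stats::runif(n, 0, exp(log_tau))
    data.frame(
      sample_id = observations(bulk),
      time = pmin(t_event, c_time),
      event = as.integer(t_event <= c_time), stringsAsFactors = FALSE
    )
  } else {
    data.frame(sample_id = observations(bulk), time = t_event,
      event = 1L, stringsAsFactors = FALSE)
  }
}

# smooth random field on [0,1]^2: superposition of random sinusoids; enough
# waves that two independent fields decorrelate over a few hundred spots
.smooth_field <- function(xy, n_waves = 12, scale = 2) {
  z <- rep(0, nrow(xy))
  for (j in seq_len(n_waves)) {
    u <- stats::runif(2, -4, 4)
    phi <- stats::runif(1, 0, 2 * pi)
    z <- z + stats::rnorm(1, sd = 1) * sin(2 * pi * (xy[, 1] * u[1] + xy[, 2] * u[2]) + phi)
  }
  scale * z / sqrt(n_waves / 2)
}

#' Simulate spatial spots as mixtures of signature profiles
#'
#' Spot expression is a mixture of per-signature expression profiles with
#' spatially smooth mixing weights (low-frequency random fields on the slide).
#' Signatures listed together in `shared_fields` ride on one common weight
#' field (planted co-localization); all others get independent fields.
#'
#' @param config a [simulation_config()] (uses `n_spots`, `spatial_noise`).
#' @param signatures named list (>= 2) of gene-symbol vectors.
#' @param shared_fields list of character vectors of signature names sharing a
#'   weight field; default plants co-localization of the first two signatures.
#' @param seed optional seed overriding `config$seed`.
#' @return list with `matrix` (normalized `expr_matrix`, genes x spots),
#'   `coordinates` (data.frame spot_id, x, y) and `weights` (spot x signature
#'   matrix of true mixing weights).
#' @export
simulate_spatial <- function(config, signatures,
                             shared_fields = list(names(signatures)[1:2]),
                             seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (length(signatures) < 2) stop("need at least 2 signatures")
  if (is.null(names(signatures)) || anyDuplicated(names(signatures))) {
    stop("signatures must be uniquely named")
  }
  if (config$n_spots < 1) stop("n_spots must be positive")
  set.seed(seed)
  g <- ceiling(sqrt(config$n_spots))
  xy <- expand.grid(x = seq(0, 1, length.out = g), y = seq(0, 1, length.out = g))
  xy <- as.matrix(xy[seq_len(config$n_spots), , drop = FALSE])

  field_of <- stats::setNames(names(signatures), names(signatures))
  for (grp in shared_fields) field_of[grp] <- grp[1]
  fields <- lapply(unique(field_of), function(f) .smooth_field(xy))
  names(fields) <- unique(field_of)
  w <- vapply(names(signatures), function(s) {
    stats::plogis(fields[[field_of[[s]]]] +
      stats::rnorm(nrow(xy), sd = config$spatial_noise))
  }, numeric(nrow(xy)))

  # signature genes: mean 1 + 8 * weight; background: heterogeneous baselines
  # large enough (800 genes) that signatures do not dominate the rank scale
  sig_genes <- lapply(signatures, toupper)
  bg_genes <- sprintf("SBG%03d", seq_len(800))
  all_genes <- unique(c(unlist(sig_genes), bg_genes))
  mu <- matrix(exp(stats::rnorm(length(all_genes), log(3), 1)),
    nrow = length(all_genes), ncol = nrow(xy),
    dimnames = list(all_genes, NULL))
  for (s in names(sig_genes)) {
    gidx <- match(sig_genes[[s]], all_genes)
    mu[gidx, ] <- 1 + 8 * matrix(w[, s], nrow = length(gidx),
      ncol = nrow(xy), byrow = TRUE)
  }
  counts <- matrix(
    stats::rnbinom(length(mu), size = 6, mu = as.vector(mu)),
    nrow = nrow(mu), dimnames = list(all_genes,
      sprintf("SPOT%04d", seq_len(nrow(xy))))
  )
  m <- normalize_counts(expression_matrix(counts))
  list(
    matrix = m,
    coordinates = data.frame(spot_id = observations(m), x = xy[, 1], y = xy[, 2],
      stringsAsFactors = FALSE),
    weights = w
  )
}
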