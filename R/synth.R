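#' Configuration for the synthetic cohort generator
#'
#' Captures the study conditions emulated by [gen_cohort()]: two groups
#' (patients and healthy controls), globally reduced structural edge
#' weights in patients, a planted subnetwork with stronger structural
#' reduction, increased within-module functional correlation in patients,
#' and cognitive scores generated from the structure-x-function moderation
#' model.
#'
#' @param n_patients,n_controls group sizes.
#' @param n_nodes number of grey-matter nodes.
#' @param seed integer seed; the full cohort is reproducible bit-for-bit.
#' @param subnet_nodes integer vector of planted-subnetwork node ids, or
#'   `NULL` to auto-select `n_subnet` spatially clustered nodes.
#' @param n_subnet size of the auto-selected subnetwork.
#' @param global_effect fractional reduction of every structural edge
#'   weight in patients (0 <= effect < 1).
#' @param subnet_effect additional fractional reduction applied to
#'   subnetwork edges in patients.
#' @param fc_module_boost increment of the within-module signal loading in
#'   patients (drives increased functional modularity).
#' @param fc_base_cor within-module BOLD correlation in controls.
#' @param n_modules number of equal-size functional modules.
#' @param n_timepoints length of the latent BOLD-like series.
#' @param noise_sd_struct additive Gaussian noise SD on structural edge
#'   weights (signal-fraction units).
#' @param noise_sd_func SD of the idiosyncratic component of the node
#'   series (unitless; 1 makes the within-module correlation equal
#'   `fc_base_cor`).
#' @param template_density fraction of node pairs connected in the
#'   structural template.
#' @param weight_decay spatial decay length of template edge weights.
#' @param cog_betas 6-vector (intercept, disruption, deviation,
#'   disruption x deviation, age, sex) generating cognitive scores.
#' @param cog_noise_sd SD of the score noise.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 46L, n_controls = 49L, n_nodes = 100L,
                         seed = 1L, subnet_nodes = NULL, n_subnet = 8L,
                         global_effect = 0.02, subnet_effect = 0.25,
                         fc_module_boost = 0.15, fc_base_cor = 0.30,
                         n_modules = 5L, n_timepoints = 200L,
                         noise_sd_struct = 0.1, noise_sd_func = 1.0,
                         template_density = 0.30, weight_decay = 0.5,
                         cog_betas = c(16.364, 15.809, -10.793, -28.636,
                                       -0.070, -0.681),
                         cog_noise_sd = 1.0) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              n_nodes = as.integer(n_nodes), seed = as.integer(seed),
              subnet_nodes = subnet_nodes, n_subnet = as.integer(n_subnet),
              global_effect = global_effect, subnet_effect = subnet_effect,
              fc_module_boost = fc_module_boost, fc_base_cor = fc_base_cor,
              n_modules = as.integer(n_modules),
              n_timepoints = as.integer(n_timepoints),
              noise_sd_struct = noise_sd_struct,
              noise_sd_func = noise_sd_func,
              template_density = template_density,
              weight_decay = weight_decay,
              cog_betas = cog_betas, cog_noise_sd = cog_noise_sd)
  with(cfg, {
    stopifnot(n_patients > 0, n_controls > 0, n_nodes > 1,
              global_effect >= 0, global_effect < 1,
              subnet_effect >= 0, subnet_effect < 1,
              fc_module_boost >= 0, fc_base_cor >= 0,
              fc_base_cor + fc_module_boost < 1,
              noise_sd_struct >= 0, noise_sd_func >= 0,
              length(cog_betas) == 6)
  })
  if (!is.null(subnet_nodes) &&
      (anyDuplicated(subnet_nodes) || any(subnet_nodes < 1) ||
       any(subnet_nodes > cfg$n_nodes)))
    stop("subnet_nodes must be distinct node ids within 1..n_nodes")
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a toy tractogram with known ground-truth weights
#'
#' Streamlines are straight axis-aligned voxel paths on a small 3-D grid
#' whose endpoints fall in voxels mapped to grey-matter nodes. Each
#' streamline records traversed voxels, per-voxel segment lengths (1 mm
#' voxels), local tangents and its endpoint node pair. Ground-truth
#' intra-axonal signal fractions are drawn uniformly on \[0.1, 1\].
#'
#' @param grid_shape integer 3-vector of voxel counts (<= 10 per axis).
#' @param n_streamlines number of streamlines (> 0).
#' @param node_map integer array/vector of length `prod(grid_shape)`
#'   assigning a node id (> 0) to each voxel, 0 = unmapped white matter.
#' @param seed integer seed.
#' @return List with `tractogram` (class `tractogram`: `grid_shape`,
#'   `node_map`, `streamlines`) and `truth` (class `ground_truth`:
#'   `streamline_weights`).
#' @export
gen_toy_tractogram <- function(grid_shape, n_streamlines, node_map, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1) || prod(grid_shape) > 1000)
    stop("grid_shape must be 3 positive counts with at most 1000 voxels")
  if (n_streamlines < 1) stop("n_streamlines must be > 0")
  node_map <- as.integer(node_map)
  if (length(node_map) != prod(grid_shape))
    stop("node_map must cover every voxel")
  if (sum(node_map > 0) < 2) stop("node_map must mark at least two node voxels")

  # enumerate every admissible straight placement: an axis-aligned voxel
  # span whose two end voxels are mapped to two different nodes
  axes <- diag(3)
  placements <- list()
  for (ax in 1:3) {
    len_ax <- grid_shape[ax]
    if (len_ax < 2) next
    other <- setdiff(1:3, ax)
    perp <- as.matrix(expand.grid(seq_len(grid_shape[other[1]]),
                                  seq_len(grid_shape[other[2]])))
    for (r in seq_len(nrow(perp))) {
      pos <- integer(3)
      pos[other] <- perp[r, ]
      line <- matrix(rep(pos, each = len_ax), len_ax, 3)
      line[, ax] <- seq_len(len_ax)
      ids <- node_map[voxel_index(line, grid_shape)]
      mapped <- which(ids > 0)
      if (length(mapped) < 2) next
      for (ai in seq_len(length(mapped) - 1))
        for (bi in (ai + 1):length(mapped)) {
          lo <- mapped[ai]; hi <- mapped[bi]
          if (ids[lo] == ids[hi]) next  # self-connection: not a bundle
          placements[[length(placements) + 1L]] <-
            list(ax = ax, line = line, lo = lo, hi = hi,
                 ends = c(ids[lo], ids[hi]))
        }
    }
  }
  if (length(placements) < n_streamlines)
    stop("could not place ", n_streamlines, " distinct streamlines with ",
         "both endpoints in mapped node voxels (", length(placements),
         " placements available)")

  set.seed(seed)
  sel <- sample.int(length(placements), n_streamlines)
  streamlines <- lapply(placements[sel], function(p) {
    vox <- p$line[p$lo:p$hi, , drop = FALSE]
    nv <- nrow(vox)
    list(voxels = vox,
         seg_lengths = rep(1.0, nv),
         tangents = matrix(rep(axes[p$ax, ], each = nv), nv, 3),
         endpoints = p$ends,
         length = nv * 1.0)
  })
  weights <- stats::runif(n_streamlines, 0.1, 1.0)
  list(tractogram = structure(list(grid_shape = grid_shape,
                                   node_map = node_map,
                                   streamlines = streamlines),
                              class = "tractogram"),
       truth = structure(list(streamline_weights = weights),
                         class = "ground_truth"))
}

#' Simulate the diffusion signal of a toy tractogram
#'
#' Direct evaluation of the two-compartment forward model: in each voxel,
#' the signal of a volume is the sum over traversing streamlines of
#' weight x segment length x stick attenuation, plus the isotropic
#' fractions times their ball attenuations, plus optional Gaussian noise.
#' With `noise_sd = 0` the result equals the [build_operator()] forward
#' model exactly.
#'
#' @param tractogram a `tractogram`.
#' @param truth a `ground_truth` with `streamline_weights`.
#' @param gradients a [gradient_table()].
#' @param iso_fractions n_vox x n_iso matrix of per-voxel isotropic signal
#'   fractions (recycled from a single pair).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param model a [commit_model()].
#' @param seed seed for the noise draw.
#' @return n_vox x n_vol signal matrix.
#' @export
gen_dwi_signal <- function(tractogram, truth, gradients,
                           iso_fractions = c(0.1, 0.1), noise_sd = 0,
                           model = commit_model(), seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_vox <- prod(tractogram$grid_shape)
  bv <- gradients$b_values
  n_vol <- length(bv)
  n_iso <- length(model$d_iso)
  if (is.null(dim(iso_fractions)))
    iso_fractions <- matrix(iso_fractions, n_vox, n_iso, byrow = TRUE)
  if (nrow(iso_fractions) != n_vox || ncol(iso_fractions) != n_iso)
    stop("iso_fractions must be n_vox x n_iso")
  if (any(iso_fractions < 0)) stop("iso fractions must be >= 0")

  sig <- matrix(0, n_vox, n_vol)
  for (v in seq_len(n_vol)) {
    for (j in seq_len(n_iso))
      sig[, v] <- sig[, v] +
        iso_fractions[, j] * ball_attenuation(bv[v], model$d_iso[j])
    for (k in seq_along(tractogram$streamlines)) {
      s <- tractogram$streamlines[[k]]
      vi <- voxel_index(s$voxels, tractogram$grid_shape)
      for (q in seq_along(vi)) {
        att <- if (bv[v] == 0) 1 else
          stick_attenuation(bv[v], gradients$directions[v, ],
                            s$tangents[q, ], model)
        sig[vi[q], v] <- sig[vi[q], v] +
          truth$streamline_weights[k] * s$seg_lengths[q] * att
      }
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    sig <- sig + matrix(stats::rnorm(n_vox * n_vol, 0, noise_sd), n_vox, n_vol)
  }
  sig
}

# Structural template: random geometric graph on the unit cube with
# distance-decaying weights. Deterministic given the config seed.
make_template <- function(config) {
  set.seed(config$seed)
  n <- config$n_nodes
  coords <- matrix(stats::runif(n * 3), n, 3)
  d <- as.matrix(stats::dist(coords))
  ut <- upper.tri(d)
  radius <- stats::quantile(d[ut], config$template_density, names = FALSE)
  adj <- d <= radius & ut
  w <- matrix(0, n, n)
  w[adj] <- exp(-d[adj] / config$weight_decay)
  w <- w + t(w)
  subnet <- config$subnet_nodes
  if (is.null(subnet)) {
    centroid <- colMeans(coords)
    d0 <- sqrt(colSums((t(coords) - centroid)^2))
    seed_node <- which.min(d0)
    nb <- order(d[seed_node, ])
    subnet <- sort(c(seed_node,
                     setdiff(nb, seed_node)[seq_len(config$n_subnet - 1L)]))
  }
  se <- which(w > 0 & ut &
                (row(w) %in% subnet) & (col(w) %in% subnet), arr.ind = TRUE)
  list(coords = coords, weights = w, subnet_nodes = subnet,
       subnet_edges = se[order(se[, 1], se[, 2]), , drop = FALSE])
}

#' Generate a synthetic two-group cohort of connectomes
#'
#' Produces per-subject structural connectomes (template weights reduced
#' in patients globally and further on a planted subnetwork, plus additive
#' noise clipped at zero), functional connectomes (Fisher-z correlation
#' matrices of a block-modular latent time-series model with boosted
#' within-module loading in patients), covariates (age, sex, motion) and
#' cognitive scores generated from the moderation model
#' `score = betas . (1, disruption, deviation, disruption x deviation,
#' age, sex) + noise`, where disruption/deviation are the
#' healthy-control-referenced subnetwork indices computed by
#' [disruption_index()] on the generated data itself.
#'
#' @param config a [synth_config()].
#' @param modalities which connectome modalities to generate; dropping
#'   `"functional"` skips the series model (deviation is then 0 in the
#'   score model). Stage-wise seeding keeps the structural draw identical
#'   either way.
#' @return List of class `cohort`: `config`, `nodes`, `coords`,
#'   `template`, `struct` (list of n x n matrices), `func` (list of raw
#'   signed Fisher-z matrices or `NULL`), `covariates` (data.frame:
#'   subject_id, group, age, sex, motion, score), `ground_truth`
#'   (`subnet_nodes`, `subnet_edges`, `true_disruption`,
#'   `true_deviation`, `cog_betas`).
#' @export
gen_cohort <- function(config = synth_config(),
                       modalities = c("structural", "functional")) {
  n <- config$n_nodes
  n_sub <- config$n_patients + config$n_controls
  tmpl <- make_template(config)
  group <- factor(rep(c("patient", "control"),
                      c(config$n_patients, config$n_controls)),
                  levels = c("control", "patient"))

  set.seed(config$seed + 1L)
  covar <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_sub)),
    group = group,
    age = pmin(80, pmax(18, round(stats::rnorm(n_sub, 42, 15), 1))),
    sex = stats::rbinom(n_sub, 1, 0.5),
    motion = stats::rlnorm(n_sub, log(0.15), 0.4),
    stringsAsFactors = FALSE)

  struct <- NULL
  if ("structural" %in% modalities) {
    set.seed(config$seed + 2L)
    ut <- upper.tri(tmpl$weights)
    edge_idx <- which(tmpl$weights > 0 & ut)
    patient_w <- tmpl$weights * (1 - config$global_effect)
    patient_w[tmpl$subnet_edges] <- patient_w[tmpl$subnet_edges] *
      (1 - config$subnet_effect)
    patient_w[tmpl$subnet_edges[, 2:1, drop = FALSE]] <-
      patient_w[tmpl$subnet_edges]
    struct <- lapply(seq_len(n_sub), function(s) {
      base <- if (group[s] == "patient") patient_w else tmpl$weights
      w <- matrix(0, n, n)
      w[edge_idx] <- pmax(0, base[edge_idx] +
                            stats::rnorm(length(edge_idx), 0,
                                         config$noise_sd_struct))
      w + t(w)
    })
  }

  func <- NULL
  if ("functional" %in% modalities) {
    set.seed(config$seed + 3L)
    modules <- sort(rep_len(seq_len(config$n_modules), n))
    tp <- config$n_timepoints
    func <- lapply(seq_len(n_sub), function(s) {
      rho <- config$fc_base_cor +
        if (group[s] == "patient") config$fc_module_boost else 0
      shared <- matrix(stats::rnorm(tp * config$n_modules), tp)
      eps <- matrix(stats::rnorm(tp * n, 0, config$noise_sd_func), tp, n)
      series <- sqrt(rho) * shared[, modules] + sqrt(1 - rho) * eps
      fisher_connectome(series)
    })
  }

  gt <- list(subnet_nodes = tmpl$subnet_nodes,
             subnet_edges = tmpl$subnet_edges,
             cog_betas = config$cog_betas)
  hc <- which(group == "control")
  # degenerate (noise-free) cohorts have no control variance to
  # reference against; the index is then undefined, not zero
  try_index <- function(mats, modality) tryCatch(
    disruption_index(mats, tmpl$subnet_edges, covar, hc,
                     modality = modality),
    error = function(e) {
      message("ground-truth ", modality, " index undefined: ",
              conditionMessage(e))
      rep(NA_real_, n_sub)
    })
  gt$true_disruption <- if (!is.null(struct))
    try_index(struct, "structural") else rep(0, n_sub)
  gt$true_deviation <- if (!is.null(func))
    try_index(func, "functional") else rep(0, n_sub)

  set.seed(config$seed + 4L)
  b <- config$cog_betas
  score <- b[1] + b[2] * gt$true_disruption + b[3] * gt$true_deviation +
    b[4] * gt$true_disruption * gt$true_deviation +
    b[5] * covar$age + b[6] * covar$sex +
    stats::rnorm(n_sub, 0, config$cog_noise_sd)
  covar$score <- ifelse(group == "patient", score, NA_real_)

  structure(list(
    config = config,
    nodes = data.frame(node_id = seq_len(n),
                       name = sprintf("node_%03d", seq_len(n)),
                       stringsAsFactors = FALSE),
    coords = tmpl$coords, template = tmpl$weights,
    struct = struct, func = func, covariates = covar,
    ground_truth = gt), class = "cohort")
}

#' Subnetwork effect needed to reach a target disruption effect size
#'
#' Inverts the generator's noise model analytically: the planted
#' subnetwork reduction that makes the patient-vs-control Cohen's d of
#' the structural disruption index approximately `target_d`. With m
#' independent subnetwork edges the index SD is about 1/sqrt(m) z-units
#' in both groups, so the required mean weight reduction is
#' |d| * noise_sd / sqrt(m).
#'
#' @param config a [synth_config()] (its seed fixes the template).
#' @param target_d desired Cohen's d (sign ignored; disruption is
#'   negative in patients by construction).
#' @return The `subnet_effect` value to use.
#' @export
calibrate_subnet_effect <- function(config, target_d) {
  tmpl <- make_template(config)
  wbar <- mean(tmpl$weights[tmpl$subnet_edges])
  m <- nrow(tmpl$subnet_edges)
  dw <- abs(target_d) * config$noise_sd_struct / sqrt(m)
  e <- 1 - (1 - dw / wbar) / (1 - config$global_effect)
  if (e < 0 || e >= 1)
    stop("target effect size is out of the generator's reachable range")
  e
}
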