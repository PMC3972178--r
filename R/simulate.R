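# Synthetic MeDIP-chip data generator. Probe values are generated directly as
# log2(MeDIP/input) ratios -- the abstraction level the analysis consumes --
# with planted promoter-level group effects, optional spatial clustering of
# planted promoters, and an optional link between planted direction and
# promoter CpG density.

#' Synthetic-data configuration
#'
#' Default values mirror the study design the analysis targets: two groups of
#' 8 cases (CPA) and 12 controls, promoters of ~20,000 genes tiled by probes
#' covering 1000 bp upstream to 250 bp downstream of the TSS on a 244k-probe
#' array (8-16 probes per promoter over 22 chromosomes).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of every chromosome in bp.
#' @param n_promoters Total promoters, spread evenly over chromosomes.
#' @param probes_per_promoter Integer vector `c(min, max)`: each promoter is
#'   tiled by a uniform draw in this range.
#' @param n_cpa,n_control Samples per group.
#' @param planted_fraction Fraction of promoters carrying a true group effect.
#' @param effect_log2 Mean absolute planted shift in log2 ratio units; the
#'   per-promoter shift is `sign * Normal(effect_log2, effect_sd)`.
#' @param effect_sd SD of the planted shift magnitude.
#' @param noise_sd Per-probe, per-sample residual SD of the log2 ratios.
#' @param cluster_block_length If > 0, planted promoters are chosen inside
#'   randomly placed genomic blocks of this length (bp) instead of uniformly,
#'   giving the window scan and distance correlation a spatial ground truth.
#' @param cpg_density_link `"none"` (sign of the planted effect is random) or
#'   `"directional"` (promoters gaining methylation in CPA are drawn from the
#'   high CpG-density side, matching the density contrast the analysis tests).
#' @param seed Integer seed; identical configs give identical outputs.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 22,
                             chromosome_length = 1.3e8,
                             n_promoters = 20000,
                             probes_per_promoter = c(8L, 16L),
                             n_cpa = 8L,
                             n_control = 12L,
                             planted_fraction = 0.05,
                             effect_log2 = 1.0,
                             effect_sd = 0.2,
                             noise_sd = 0.25,
                             cluster_block_length = 0,
                             cpg_density_link = c("none", "directional"),
                             seed = 1L) {
  cpg_density_link <- match.arg(cpg_density_link)
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = chromosome_length,
              n_promoters = as.integer(n_promoters),
              probes_per_promoter = as.integer(probes_per_promoter),
              n_cpa = as.integer(n_cpa), n_control = as.integer(n_control),
              planted_fraction = planted_fraction,
              effect_log2 = effect_log2, effect_sd = effect_sd,
              noise_sd = noise_sd,
              cluster_block_length = cluster_block_length,
              cpg_density_link = cpg_density_link,
              seed = as.integer(seed))
  if (cfg$planted_fraction < 0 || cfg$planted_fraction > 1) {
    stop("'planted_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (cfg$n_cpa < 2 || cfg$n_control < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  if (cfg$chromosome_length <= 0 || cfg$n_chromosomes < 1) {
    stop("chromosome dimensions must be positive", call. = FALSE)
  }
  if (length(cfg$probes_per_promoter) != 2 ||
      cfg$probes_per_promoter[1] < 1 ||
      cfg$probes_per_promoter[1] > cfg$probes_per_promoter[2]) {
    stop("'probes_per_promoter' must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("'noise_sd' must be > 0", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

PROBE_LENGTH <- 60L  # tiling oligo length in bp

#' Generate a synthetic promoter annotation
#'
#' Promoters are placed uniformly at random without overlap on each
#' chromosome, assigned a random strand, and tiled by evenly spaced probes
#' inside their -1000..+250 TSS region. CpG, C and G counts are drawn from a
#' two-component mixture so that normalized CpG density spans the bimodal
#' (island / non-island) range seen on real promoter arrays.
#'
#' @param config A [synthetic_config()].
#' @return A `medip_annotation`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "annotation"))
  region_len <- PROMOTER_UPSTREAM + PROMOTER_DOWNSTREAM
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  lens <- stats::setNames(rep(config$chromosome_length, config$n_chromosomes),
                          chroms)

  if (config$n_promoters == 0) {
    probes <- data.frame(probe_id = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         promoter_id = character())
    promoters <- data.frame(promoter_id = character(),
                            gene_symbol = character(), chrom = character(),
                            tss = numeric(), strand = character(),
                            cpg_count = integer(), c_count = integer(),
                            g_count = integer(), length_bp = integer())
    return(medip_annotation(lens, probes, promoters))
  }

  # spread promoters as evenly as possible over chromosomes
  per_chrom <- diff(round(seq(0, config$n_promoters,
                              length.out = config$n_chromosomes + 1)))
  region_starts <- vector("list", config$n_chromosomes)
  for (ci in seq_len(config$n_chromosomes)) {
    k <- per_chrom[ci]
    if (k == 0) { region_starts[[ci]] <- numeric(0); next }
    slack <- config$chromosome_length - k * region_len
    if (slack < 0) {
      stop("cannot place ", k, " non-overlapping promoter regions on a ",
           config$chromosome_length, " bp chromosome; increase chromosome_length",
           call. = FALSE)
    }
    # classic non-overlap placement: sorted uniform gaps plus cumulative widths
    gaps <- sort(floor(stats::runif(k, min = 0, max = slack + 1)))
    region_starts[[ci]] <- gaps + (seq_len(k) - 1) * region_len
  }

  chrom_vec <- rep(chroms, per_chrom)
  start_vec <- unlist(region_starts, use.names = FALSE)
  n <- length(start_vec)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", start_vec + PROMOTER_UPSTREAM,
                start_vec + PROMOTER_DOWNSTREAM)

  # bimodal CpG density: island-like promoters (high observed/expected) vs
  # depleted promoters, with island-like also slightly GC-richer
  island <- stats::runif(n) < 0.5
  gc <- pmin(pmax(stats::rnorm(n, ifelse(island, 0.52, 0.40), 0.04), 0.2), 0.8)
  c_count <- pmax(round(gc * region_len / 2 + stats::rnorm(n, 0, 10)), 1L)
  g_count <- pmax(round(gc * region_len / 2 + stats::rnorm(n, 0, 10)), 1L)
  target_density <- pmax(stats::rnorm(n, ifelse(island, 0.75, 0.25),
                                      ifelse(island, 0.10, 0.08)), 0.02)
  expected_cpg <- (c_count / region_len) * (g_count / region_len) *
    (region_len - 1)
  cpg_count <- pmin(round(target_density * expected_cpg),
                    pmin(c_count, g_count))
  cpg_count <- pmax(cpg_count, 0L)

  promoters <- data.frame(
    promoter_id = sprintf("PROM%05d", seq_len(n)),
    gene_symbol = sprintf("GENE%05d", seq_len(n)),
    chrom = chrom_vec, tss = tss, strand = strand,
    cpg_count = as.integer(cpg_count), c_count = as.integer(c_count),
    g_count = as.integer(g_count), length_bp = region_len,
    stringsAsFactors = FALSE
  )

  probe_range <- seq(config$probes_per_promoter[1],
                     config$probes_per_promoter[2])
  n_probes <- if (length(probe_range) == 1) {
    rep(probe_range, n)
  } else {
    sample(probe_range, n, replace = TRUE)
  }
  prom_idx <- rep(seq_len(n), n_probes)
  # evenly spaced probe starts inside each promoter region
  offset <- unlist(lapply(n_probes, function(k) {
    if (k == 1) return((region_len - PROBE_LENGTH) / 2)
    round(seq(0, region_len - PROBE_LENGTH, length.out = k))
  }), use.names = FALSE)
  probes <- data.frame(
    probe_id = sprintf("PROBE%07d", seq_along(prom_idx)),
    chrom = chrom_vec[prom_idx],
    start = start_vec[prom_idx] + offset,
    end = start_vec[prom_idx] + offset + PROBE_LENGTH,
    promoter_id = promoters$promoter_id[prom_idx],
    stringsAsFactors = FALSE
  )
  medip_annotation(lens, probes, promoters)
}

# choose which promoters carry a planted effect; contiguous genomic blocks
# when cluster_block_length > 0. Returns the promoter indices and a block id
# per chosen promoter (all distinct when planting is unclustered).
select_planted <- function(config, annotation) {
  n <- nrow(annotation$promoters)
  n_planted <- round(config$planted_fraction * n)
  if (n_planted == 0) return(list(idx = integer(0), block = integer(0)))
  if (config$cluster_block_length <= 0) {
    idx <- sort(sample.int(n, n_planted))
    return(list(idx = idx, block = seq_along(idx)))
  }
  prom <- annotation$promoters
  chosen <- integer(0)
  block_of <- integer(0)
  n_blocks <- 0
  guard <- 0
  while (length(chosen) < n_planted && guard < 10000) {
    guard <- guard + 1
    ci <- sample(names(annotation$chromosome_lengths), 1)
    len <- annotation$chromosome_lengths[[ci]]
    start <- floor(stats::runif(1, 0, max(len - config$cluster_block_length, 1)))
    hit <- which(prom$chrom == ci & prom$tss >= start &
                   prom$tss < start + config$cluster_block_length)
    hit <- setdiff(hit, chosen)
    if (length(hit) == 0) next
    n_blocks <- n_blocks + 1
    chosen <- c(chosen, hit)
    block_of <- c(block_of, rep(n_blocks, length(hit)))
  }
  if (length(chosen) < n_planted) {
    stop("could not cover ", n_planted, " promoters with blocks; ",
         "increase cluster_block_length or promoter density", call. = FALSE)
  }
  keep <- seq_len(n_planted)
  o <- order(chosen[keep])
  list(idx = chosen[keep][o], block = block_of[keep][o])
}

#' Generate a synthetic methylation matrix with planted effects
#'
#' Unplanted probes are Normal(0, `noise_sd`) in both groups. Each planted
#' promoter draws a shift `sign * Normal(effect_log2, effect_sd)` which is
#' added to all of its probes in the CPA samples only, so the planted
#' log2 fold difference is constant across a promoter. The returned truth
#' table supports recovery scoring downstream.
#'
#' @param config A [synthetic_config()].
#' @param annotation Annotation from [generate_annotation()] with the same
#'   config.
#' @return A list with elements `matrix` (a `medip_matrix`) and `truth`
#'   (data.frame: promoter_id, planted, direction, shift).
#' @export
generate_matrix <- function(config, annotation) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(annotation, "medip_annotation"))
  set.seed(derive_seed(config$seed, "matrix"))
  n_probes <- nrow(annotation$probes)
  n_prom <- nrow(annotation$promoters)
  n_samples <- config$n_cpa + config$n_control
  sample_ids <- c(sprintf("CPA%02d", seq_len(config$n_cpa)),
                  sprintf("CTRL%02d", seq_len(config$n_control)))
  groups <- c(rep("CPA", config$n_cpa), rep("control", config$n_control))

  sel <- select_planted(config, annotation)
  planted_idx <- sel$idx
  shift <- numeric(n_prom)
  direction <- rep(NA_character_, n_prom)
  if (length(planted_idx) > 0) {
    if (config$cpg_density_link == "directional") {
      # methylation gained in CPA comes from the CpG-dense side: planted
      # promoters above the planted-set median density go up, the rest down
      dens <- with(annotation$promoters[planted_idx, ],
                   normalized_cpg_density(cpg_count, c_count, g_count,
                                          length_bp))
      dens[is.na(dens)] <- 0
      up <- rank(dens, ties.method = "first") > length(planted_idx) / 2
      sign_vec <- ifelse(up, 1, -1)
    } else if (config$cluster_block_length > 0) {
      # one sign per planted block so clustered effects are spatially
      # coherent, giving the window scan and the distance correlation a
      # recoverable ground truth
      block_sign <- sample(c(-1, 1), max(sel$block), replace = TRUE)
      sign_vec <- block_sign[sel$block]
    } else {
      sign_vec <- sample(c(-1, 1), length(planted_idx), replace = TRUE)
    }
    magnitude <- stats::rnorm(length(planted_idx), config$effect_log2,
                              config$effect_sd)
    shift[planted_idx] <- sign_vec * magnitude
    direction[planted_idx] <- ifelse(sign_vec > 0, "up_in_cpa", "down_in_cpa")
  }

  values <- matrix(stats::rnorm(n_probes * n_samples, 0, config$noise_sd),
                   nrow = n_probes, ncol = n_samples)
  prom_of_probe <- probe_promoter_index(annotation)
  probe_shift <- shift[prom_of_probe]
  cpa_cols <- seq_len(config$n_cpa)
  values[, cpa_cols] <- values[, cpa_cols] + probe_shift

  truth <- data.frame(promoter_id = annotation$promoters$promoter_id,
                      planted = seq_len(n_prom) %in% planted_idx,
                      direction = direction, shift = shift,
                      stringsAsFactors = FALSE)
  list(matrix = medip_matrix(values, annotation$probes$probe_id,
                             sample_ids, groups),
       truth = truth)
}

#' Generate a random cohort table
#'
#' Emits a cohort summary table with the same structure as a typical
#' case/control characteristics table: per variable either group means/SDs
#' with sample sizes or 2x2 yes/no counts. Used as a randomized fixture for
#' the cohort statistics stage.
#'
#' @param config A [synthetic_config()] (group sizes and seed are used).
#' @param n_summary,n_count Number of summary-type and count-type variables.
#' @return A `cohort_table` data.frame (see [read_cohort_table()]).
#' @export
generate_cohort <- function(config, n_summary = 3, n_count = 3) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  rows <- list()
  for (i in seq_len(n_summary)) {
    rows[[length(rows) + 1]] <- data.frame(
      variable = sprintf("summary_var_%d", i), type = "summary",
      mean_control = round(stats::rnorm(1, 10, 3), 2),
      sd_control = round(stats::runif(1, 0.5, 3), 2),
      n_control = config$n_control,
      mean_cpa = round(stats::rnorm(1, 10, 3), 2),
      sd_cpa = round(stats::runif(1, 0.5, 3), 2),
      n_cpa = config$n_cpa,
      control_yes = NA_integer_, control_no = NA_integer_,
      cpa_yes = NA_integer_, cpa_no = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(n_count)) {
    cy <- stats::rbinom(1, config$n_control, 0.4)
    py <- stats::rbinom(1, config$n_cpa, 0.4)
    rows[[length(rows) + 1]] <- data.frame(
      variable = sprintf("count_var_%d", i), type = "count",
      mean_control = NA_real_, sd_control = NA_real_, n_control = NA_integer_,
      mean_cpa = NA_real_, sd_cpa = NA_real_, n_cpa = NA_integer_,
      control_yes = cy, control_no = config$n_control - cy,
      cpa_yes = py, cpa_no = config$n_cpa - py,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) == 0) empty_cohort_table() else do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}
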