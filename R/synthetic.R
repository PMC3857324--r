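#' Configuration for a synthetic grouped time-series cohort
#'
#' Describes a two-group cohort in which modules of co-regulated genes
#' follow smooth latent trajectories, each individual traverses the
#' shared program at its own speed and offset (time warping), and a
#' planted set of genes is co-expressed with its module in group X but
#' follows an independent trajectory in group Y (decoupling). This is the
#' heterogeneity regime in which group-average profiles lose the
#' within-individual correlation structure.
#'
#' Latent model, for gene g in module M, individual i, nominal time t on
#' the common grid \{0, 1/(m-1), ..., 1\}:
#' `value = loading_g * f_M(speed_i * t + offset_i) + N(0, noise_sd)`,
#' with `speed_i = exp(N(0, log_speed_sd))` and
#' `offset_i = N(0, offset_sd)`. Background genes are pure noise.
#' Decoupled genes replace `f_M` in group Y by a gene-specific smooth
#' sinusoid with random frequency and phase. The optional switch gene
#' follows module 1's trajectory in group X and module 2's in group Y.
#'
#' @param n_genes Total genes; default 300.
#' @param module_sizes Integer vector of module sizes; default
#'   c(100, 100, 100), i.e. every gene co-regulated — emulating data that
#'   has already passed a variance filter, where unstructured genes do not
#'   survive. Sizes summing below `n_genes` leave the remainder as pure
#'   observation noise. Modules cycle through the trajectory library
#'   (sigmoid, pulse, down-up-down).
#' @param n_individuals Individuals per group; default 6.
#' @param m Time points per individual (common nominal grid); default 8.
#' @param log_speed_sd SD of the individual log-speed multiplier;
#'   default 0.3.
#' @param offset_sd SD of the individual time offset; default 0.15.
#' @param loading_sd SD of per-gene loadings around 1; default 0.2.
#' @param noise_sd SD of the Gaussian observation noise; default 0.3.
#' @param n_decoupled Number of module genes decoupled in group Y;
#'   default 20, spread across modules.
#' @param switch_gene Plant a switching focal gene? Default FALSE.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 300, module_sizes = c(100, 100, 100),
                             n_individuals = 6, m = 8,
                             log_speed_sd = 0.3, offset_sd = 0.15,
                             loading_sd = 0.2, noise_sd = 0.3,
                             n_decoupled = 20, switch_gene = FALSE, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), module_sizes = as.integer(module_sizes),
              n_individuals = as.integer(n_individuals), m = as.integer(m),
              log_speed_sd = log_speed_sd, offset_sd = offset_sd,
              loading_sd = loading_sd, noise_sd = noise_sd,
              n_decoupled = as.integer(n_decoupled),
              switch_gene = isTRUE(switch_gene), seed = as.integer(seed))
  if (cfg$n_genes < 1) abort_("invalid config: n_genes must be positive")
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    abort_("invalid config: module_sizes sum exceeds n_genes")
  }
  if (any(cfg$module_sizes < 2)) abort_("invalid config: each module needs >= 2 genes")
  if (cfg$m < 3) abort_("invalid config: m must be >= 3")
  if (cfg$noise_sd < 0) abort_("invalid config: noise_sd must be >= 0")
  if (cfg$log_speed_sd < 0 || cfg$offset_sd < 0) {
    abort_("invalid config: warp SDs must be >= 0")
  }
  if (cfg$n_individuals < 1) abort_("invalid config: n_individuals must be >= 1")
  if (cfg$n_decoupled > sum(cfg$module_sizes)) {
    abort_("invalid config: n_decoupled exceeds the number of module genes")
  }
  if (cfg$switch_gene && length(cfg$module_sizes) < 2) {
    abort_("invalid config: a switch gene needs at least two modules")
  }
  structure(cfg, class = "synthetic_config")
}

# smooth latent trajectory library on [0, 1] (extended smoothly beyond),
# scaled to roughly zero mean and unit amplitude so that with the default
# loading (~1) and noise sd 0.3 module pairs correlate at |r| > 0.8 within
# an individual
trajectory_library_ <- list(
  sigmoid      = function(u) 2 / (1 + exp(-10 * (u - 0.5))) - 1,
  pulse        = function(u) 2 * exp(-((u - 0.5) / 0.15)^2) - 0.5,
  down_up_down = function(u) cos(3 * pi * u)
)

#' Simulate a grouped time-series cohort with planted decoupling
#'
#' Generates an [expr_dataset] under the model described in
#' [synthetic_config()], together with the full ground truth needed for
#' recovery metrics.
#'
#' @param config A [synthetic_config()].
#' @return List with `dataset` (an [expr_dataset]) and `truth`, itself a
#'   list with `genes` (tibble: gene_id, module, decoupled, switch),
#'   `individuals` (tibble: individual_id, group, speed, offset), and the
#'   `config`.
#' @examples
#' sim <- simulate_cohort(synthetic_config(n_genes = 50, module_sizes = c(20, 20),
#'                                         n_decoupled = 4, seed = 3))
#' dplyr::count(sim$truth$genes, module, decoupled)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed_(cfg$seed, {
    width <- max(3, nchar(as.character(cfg$n_genes)))
    gene_ids <- sprintf(paste0("g%0", width, "d"), seq_len(cfg$n_genes))
    n_mod_genes <- sum(cfg$module_sizes)
    module <- rep(NA_integer_, cfg$n_genes)
    module[seq_len(n_mod_genes)] <- rep(seq_along(cfg$module_sizes), cfg$module_sizes)

    # decoupled genes: evenly spread over modules, deterministic positions
    decoupled <- rep(FALSE, cfg$n_genes)
    if (cfg$n_decoupled > 0) {
      pool <- seq_len(n_mod_genes)
      decoupled[pool[floor(seq(1, n_mod_genes, length.out = cfg$n_decoupled))]] <- TRUE
    }
    switch_idx <- NA_integer_
    if (cfg$switch_gene) {
      # first non-decoupled gene of module 1
      switch_idx <- which(module == 1L & !decoupled)[1]
    }

    loading <- stats::rnorm(cfg$n_genes, mean = 1, sd = cfg$loading_sd)
    # decoupled dynamics in group Y: smooth sinusoids whose phase is specific
    # to both gene and individual, so the gene stays smooth within each
    # individual but carries no reproducible relation to the shared program
    dec_freq <- stats::runif(cfg$n_genes, 0.75, 1.5)
    dec_phase <- matrix(stats::runif(cfg$n_genes * 2 * cfg$n_individuals),
                        cfg$n_genes, 2 * cfg$n_individuals)

    traj_of_module <- function(mod) {
      trajectory_library_[[((mod - 1) %% length(trajectory_library_)) + 1]]
    }

    groups <- c("X", "Y")
    t_grid <- seq(0, 1, length.out = cfg$m)
    ind_tbl <- tibble::tibble(
      individual_id = as.vector(vapply(groups, function(g) {
        sprintf("%s%02d", g, seq_len(cfg$n_individuals))
      }, character(cfg$n_individuals))),
      group = rep(groups, each = cfg$n_individuals),
      speed = exp(stats::rnorm(2 * cfg$n_individuals, 0, cfg$log_speed_sd)),
      offset = stats::rnorm(2 * cfg$n_individuals, 0, cfg$offset_sd))

    blocks <- lapply(seq_len(nrow(ind_tbl)), function(ii) {
      u <- ind_tbl$speed[ii] * t_grid + ind_tbl$offset[ii]
      vals <- matrix(stats::rnorm(cfg$n_genes * cfg$m, 0, cfg$noise_sd),
                     cfg$n_genes, cfg$m)
      in_Y <- ind_tbl$group[ii] == "Y"
      for (gi in seq_len(cfg$n_genes)) {
        if (is.na(module[gi])) next
        f <- if (in_Y && decoupled[gi]) {
          function(x) sin(2 * pi * (dec_freq[gi] * x + dec_phase[gi, ii]))
        } else if (!is.na(switch_idx) && gi == switch_idx && in_Y) {
          traj_of_module(2L)
        } else {
          traj_of_module(module[gi])
        }
        vals[gi, ] <- vals[gi, ] + loading[gi] * f(u)
      }
      colnames(vals) <- sprintf("%s_t%02d", ind_tbl$individual_id[ii], seq_len(cfg$m))
      vals
    })
    values <- do.call(cbind, blocks)
    rownames(values) <- gene_ids

    design <- tibble::tibble(
      sample_id = colnames(values),
      individual_id = rep(ind_tbl$individual_id, each = cfg$m),
      group = rep(ind_tbl$group, each = cfg$m),
      time = rep(t_grid, nrow(ind_tbl)))

    truth_genes <- tibble::tibble(gene_id = gene_ids, module = module,
                                  decoupled = decoupled,
                                  switch = seq_len(cfg$n_genes) == switch_idx &
                                    !is.na(switch_idx))
    list(dataset = expr_dataset(values, design),
         truth = list(genes = truth_genes, individuals = ind_tbl, config = cfg))
  })
}

#' Recovery of planted decoupled genes by a ranking
#'
#' @param result A `dcen_result` or ranked tibble (`gene_id`, `score`).
#' @param truth The `truth` element from [simulate_cohort()] (or its
#'   `genes` tibble).
#' @return One-row tibble with `auroc` (rank-based, midrank tie handling,
#'   so all-equal scores give 0.5) and `precision_at_k` within the top
#'   `|positives|` ranked genes.
#' @export
recovery_metrics <- function(result, truth) {
  ranking <- if (inherits(result, "dcen_result")) result$scores else result
  genes_tbl <- if (is.data.frame(truth)) truth else truth$genes
  pos_set <- genes_tbl$gene_id[genes_tbl$decoupled]
  if (length(pos_set) == 0) abort_("ground truth contains no positive (decoupled) genes")
  stopifnot(setequal(ranking$gene_id, genes_tbl$gene_id))
  is_pos <- ranking$gene_id %in% pos_set
  rr <- rank(ranking$score)  # midranks under ties
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  auroc <- (sum(rr[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  top <- ranking$gene_id[ranking$rank <= n_pos]
  tibble::tibble(auroc = auroc, precision_at_k = mean(top %in% pos_set),
                 k = n_pos)
}
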