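#' Per-time-point Pearson correlation between two ages
#'
#' Averages replicates into one profile per time point in each matrix and
#' computes the Pearson correlation between every (reference ZT, query ZT)
#' pair over a shared gene set; the best and second-best reference match is
#' annotated per query ZT. This is the matrix behind "which young time of
#' day does each old sample most resemble".
#'
#' @param reference,query [zt_matrix] objects.
#' @param genes Gene set used for the correlation (default: all shared
#'   genes).
#' @return List with `cor` (matrix, reference ZTs x query ZTs), `best`
#'   (data.frame: `query_zt`, `best_match`, `second_match`).
#' @export
correlation_matrix <- function(reference, query, genes = NULL) {
  stopifnot(inherits(reference, "zt_matrix"), inherits(query, "zt_matrix"))
  if (is.null(genes)) genes <- intersect(rownames(reference$values), rownames(query$values))
  if (length(genes) == 0) stop("shared gene set is empty")
  prof <- function(x) {
    zts <- sort(unique(x$samples$zt))
    sapply(zts, function(z) rowMeans(x$values[genes, x$samples$zt == z, drop = FALSE]))
  }
  pr <- prof(reference); pq <- prof(query)
  zr <- sort(unique(reference$samples$zt)); zq <- sort(unique(query$samples$zt))
  flat_r <- apply(pr, 2, stats::sd) == 0
  flat_q <- apply(pq, 2, stats::sd) == 0
  if (any(flat_r) || any(flat_q)) {
    warning("zero-variance profile(s): correlation undefined for some cells")
  }
  cm <- suppressWarnings(stats::cor(pr, pq))
  dimnames(cm) <- list(reference_zt = zr, query_zt = zq)
  best <- t(apply(cm, 2, function(col) {
    o <- order(col, decreasing = TRUE)
    c(best = zr[o[1]], second = zr[o[2]])
  }))
  list(cor = cm,
       best = data.frame(query_zt = zq, best_match = best[, 1],
                         second_match = best[, 2], row.names = NULL))
}

#' PCA projection of diurnal samples
#'
#' Standard principal component analysis of the samples of one or more age
#' matrices over a shared gene set. With `normalize = TRUE` each gene is
#' first divided by its across-sample mean within each age, which removes
#' age-dependent amplitude differences and brings the ages onto a common
#' cycling plane.
#'
#' @param matrices Named list of [zt_matrix] objects (or a single one).
#' @param n_components Number of components to return (default 3).
#' @param normalize Per-gene division by the per-age across-time mean
#'   before PCA.
#' @param genes Gene set (default: genes shared by all matrices).
#' @return List with `coordinates` (data.frame: `age`, `zt`, `replicate`,
#'   `PC1..PCk`) and `variance_explained`.
#' @export
pca_projection <- function(matrices, n_components = 3, normalize = FALSE,
                           genes = NULL) {
  if (inherits(matrices, "zt_matrix")) matrices <- list(matrices)
  if (is.null(genes)) {
    genes <- Reduce(intersect, lapply(matrices, function(x) rownames(x$values)))
  }
  blocks <- lapply(matrices, function(x) {
    v <- x$values[genes, , drop = FALSE]
    if (normalize) {
      mu <- rowMeans(v)
      if (any(mu <= 0)) stop("mean normalization needs positive per-gene means")
      v <- v / mu
    }
    v
  })
  vals <- do.call(cbind, blocks)
  meta <- do.call(rbind, lapply(matrices, function(x) x$samples))
  n_samp <- ncol(vals)
  if (n_samp < 2) stop("PCA needs at least 2 samples")
  pc <- stats::prcomp(t(vals), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  if (k < n_components) warning("degenerate covariance: returning ", k, " components")
  coords <- data.frame(age = meta$age, zt = meta$zt, replicate = meta$replicate,
                       pc$x[, seq_len(k), drop = FALSE], row.names = NULL)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = coords, variance_explained = ve[seq_len(k)])
}

#' Polar histogram of peak times by FWHM-change direction
#'
#' Bins genes with a significant FWHM change by their daily peak time and
#' change direction — the tabular form of the polar plots showing that
#' day-peaked genes shorten and night-peaked genes lengthen their daily
#' expression with age.
#'
#' @param changes Data frame with columns `gene`, `direction`,
#'   `significant` (e.g. assembled from [fwhm_change_test()] results).
#' @param peaks Data frame with columns `gene` and `peak` (hours in
#'   `[0, 24)`; e.g. cosinor acrophases or permutation crest means).
#' @param bin_width Bin width in hours (default 4, matching a 6-time-point
#'   sampling grid).
#' @return Data frame: `bin_start`, `direction`, `count`; counts sum to the
#'   number of significant genes with a known peak.
#' @export
polar_peak_histogram <- function(changes, peaks, bin_width = 4) {
  sig <- changes[changes$significant, , drop = FALSE]
  m <- merge(sig, peaks, by = "gene")
  m <- m[is.finite(m$peak), , drop = FALSE]
  bins <- seq(0, 24 - bin_width, by = bin_width)
  out <- expand.grid(bin_start = bins,
                     direction = c("shortened", "lengthened"),
                     stringsAsFactors = FALSE)
  out$count <- mapply(function(b, d) {
    sum(m$direction == d & m$peak %% 24 >= b & m$peak %% 24 < b + bin_width)
  }, out$bin_start, out$direction)
  out
}

#' Full-analysis run configuration
#'
#' @param sim A [sim_config] describing the synthetic experiment (with at
#'   least two ages), or `NULL` when `matrices` are supplied.
#' @param matrices Named list of [zt_matrix] objects (alternative to `sim`).
#' @param reference_age Age label used as reference (default: first age).
#' @param alpha Cosinor cycling threshold (default 0.0005).
#' @param n_perm Permutation ensemble size (default 10000).
#' @param n_null Label resamples for the FWHM-change null (default 1000).
#' @param sog_threshold Single-ratio threshold for the SOG call.
#' @param p_cutoff,delta_gate FWHM-change significance gates (0.05, 2 h).
#' @param penalty Ridge penalty of the time model.
#' @param bin_width Peak-histogram bin width (hours).
#' @param seed Master seed (required when simulating).
#' @param out_dir Optional directory; when set, every stage table is
#'   written as TSV plus a JSON report.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = NULL, matrices = NULL, reference_age = NULL,
                       alpha = 5e-4, n_perm = 10000, n_null = 1000,
                       sog_threshold = 0.95, p_cutoff = 0.05, delta_gate = 2,
                       penalty = 1, bin_width = 4, seed = 1, out_dir = NULL) {
  if (is.null(sim) && is.null(matrices)) stop("provide `sim` or `matrices`")
  if (!is.null(sim) && !inherits(sim, "sim_config")) stop("`sim` must be a sim_config()")
  if (any(c(alpha, n_perm, n_null, sog_threshold, p_cutoff, delta_gate, bin_width) <= 0)) {
    stop("all thresholds and gates must be positive")
  }
  structure(
    list(sim = sim, matrices = matrices, reference_age = reference_age,
         alpha = alpha, n_perm = n_perm, n_null = n_null,
         sog_threshold = sog_threshold, p_cutoff = p_cutoff,
         delta_gate = delta_gate, penalty = penalty, bin_width = bin_width,
         seed = seed, out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Maps a plain YAML document onto [run_config()] (and [sim_config()] /
#' [age_effect()] for the `sim` block).
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    ages <- lapply(y$sim$ages, function(a) do.call(age_effect, as.list(a)))
    sim_args <- y$sim
    sim_args$ages <- ages
    sim <- do.call(sim_config, sim_args)
  }
  y$sim <- sim
  do.call(run_config, y)
}

stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full rhythmic-alteration analysis
#'
#' Orchestrates the pipeline: simulate (or take matrices) -> cosinor
#' cycling detection per age -> SOG permutation scan per age -> SOG set
#' partition -> FWHM-change permutation test on the common SOGs ->
#' physiological-time model on the reference age -> subjective-time curve
#' of the query age -> descriptive summaries (correlation matrix with best
#' matches, PCA projections, polar peak histogram). Deterministic given the
#' seed; when `out_dir` is set, each stage writes a TSV plus a JSON
#' report so every count is recomputable from the emitted tables.
#'
#' @param config A [run_config()].
#' @return An object of class `report_bundle`: list with elements
#'   `cycling`, `cycling_counts`, `cycling_overlap`, `sog`, `sog_sets`,
#'   `fwhm_changes`, `change_counts`, `time_model`, `subjective_curve`,
#'   `distance_from_noon`, `correlation`, `pca`, `pca_normalized`,
#'   `polar_histogram`, `meta`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name, expr) {
    s <- Sys.time()
    res <- stage(name, expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    res
  }

  matrices <- tick("simulate", {
    if (!is.null(cfg$sim)) {
      simulate_expression_matrix(cfg$sim, truth_fwhm = FALSE)$matrices
    } else cfg$matrices
  })
  ages <- names(matrices)
  if (length(ages) < 2) stop("the analysis needs at least two ages")
  ref <- if (is.null(cfg$reference_age)) ages[1] else cfg$reference_age
  qry <- setdiff(ages, ref)[1]

  cycling <- tick("detect_cycling", lapply(matrices, detect_cycling, alpha = cfg$alpha))
  cyc_sets <- lapply(cycling, function(d) d$gene[d$is_cycling])
  cycling_counts <- vapply(cyc_sets, length, integer(1))
  cycling_overlap <- list(
    common = intersect(cyc_sets[[ref]], cyc_sets[[qry]]),
    reference_only = setdiff(cyc_sets[[ref]], cyc_sets[[qry]]),
    query_only = setdiff(cyc_sets[[qry]], cyc_sets[[ref]])
  )

  sog <- tick("sog_scan", lapply(matrices, sog_scan, n = cfg$n_perm,
                                 threshold = cfg$sog_threshold, seed = cfg$seed))
  sog_sets <- tick("classify_sog_sets", classify_sog_sets(sog[[ref]], sog[[qry]]))

  fwhm_changes <- tick("fwhm_change", {
    rows <- lapply(seq_along(sog_sets$common), function(i) {
      g <- sog_sets$common[i]
      gy <- gene_replicate_matrix(matrices[[ref]], g)
      go <- gene_replicate_matrix(matrices[[qry]], g)
      ch <- tryCatch(
        fwhm_change_test(attr(gy, "zt"), gy, go, n = cfg$n_perm,
                         n_null = cfg$n_null, seed = derive_seed(cfg$seed, 8L, i),
                         p_cutoff = cfg$p_cutoff, delta_gate = cfg$delta_gate,
                         sog_threshold = NULL),
        error = function(e) NULL
      )
      if (is.null(ch)) return(NULL)
      data.frame(gene = g, fwhm_young = ch$fwhm_young, fwhm_old = ch$fwhm_old,
                 delta_fwhm = ch$delta_fwhm, p_value = ch$p_value,
                 significant = ch$significant, direction = ch$direction,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  change_counts <- c(
    shortened = sum(fwhm_changes$direction == "shortened"),
    lengthened = sum(fwhm_changes$direction == "lengthened"),
    unchanged = sum(fwhm_changes$direction == "unchanged")
  )

  time_model <- tick("fit_time_model", {
    feats <- if (length(sog_sets$common) >= 3) sog_sets$common else cyc_sets[[ref]]
    fit_time_model(matrices[[ref]], penalty = cfg$penalty, features = feats)
  })
  subjective <- tick("subjective_time_curve",
                     subjective_time_curve(time_model, matrices[[qry]]))
  dist_noon <- distance_from_reference_time(subjective)

  correlation <- tick("correlation_matrix", {
    gs <- if (length(sog_sets$common) >= 2) sog_sets$common else NULL
    correlation_matrix(matrices[[ref]], matrices[[qry]], genes = gs)
  })
  pca <- tick("pca", pca_projection(matrices, normalize = FALSE))
  pca_norm <- tick("pca_normalized", pca_projection(matrices, normalize = TRUE))

  polar <- tick("polar_histogram", {
    peaks <- data.frame(gene = sog[[ref]]$gene, peak = sog[[ref]]$crest_mean)
    polar_peak_histogram(fwhm_changes, peaks, bin_width = cfg$bin_width)
  })

  cfg_for_hash <- cfg
  cfg_for_hash$out_dir <- NULL
  bundle <- structure(list(
    cycling = cycling, cycling_counts = cycling_counts,
    cycling_overlap = cycling_overlap,
    sog = sog, sog_sets = sog_sets,
    fwhm_changes = fwhm_changes, change_counts = change_counts,
    pct_changed = 100 * sum(fwhm_changes$significant) / max(1L, length(sog_sets$common)),
    time_model = time_model, subjective_curve = subjective,
    distance_from_noon = dist_noon,
    correlation = correlation, pca = pca, pca_normalized = pca_norm,
    polar_histogram = polar,
    meta = list(seed = cfg$seed, reference_age = ref, query_age = qry,
                config_hash = rlang::hash(cfg_for_hash), timings = timings,
                total_secs = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  ), class = "report_bundle")

  if (!is.null(cfg$out_dir)) write_report_bundle(bundle, matrices, cfg$out_dir)
  bundle
}

write_report_bundle <- function(bundle, matrices, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (a in names(matrices)) {
    write_expression_tsv(matrices[[a]], file.path(out_dir, paste0("matrix_", a, ".tsv")))
    utils::write.table(bundle$cycling[[a]], file.path(out_dir, paste0("cycling_", a, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bundle$sog[[a]], file.path(out_dir, paste0("sog_", a, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(bundle$fwhm_changes, file.path(out_dir, "fwhm_changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(bundle$subjective_curve),
                     file.path(out_dir, "subjective_time.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$polar_histogram, file.path(out_dir, "polar_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    seed = bundle$meta$seed, config_hash = bundle$meta$config_hash,
    cycling_counts = as.list(bundle$cycling_counts),
    cycling_common = length(bundle$cycling_overlap$common),
    sog_counts = lapply(bundle$sog, function(d) sum(d$is_sog)),
    common_sogs = length(bundle$sog_sets$common),
    change_counts = as.list(bundle$change_counts),
    pct_changed = bundle$pct_changed,
    timings = bundle$meta$timings
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<report_bundle> reference '%s' vs query '%s' (seed %s)\n",
              m$reference_age, m$query_age, m$seed))
  cat("  cycling genes:  ", paste(sprintf("%s = %d", names(x$cycling_counts), x$cycling_counts),
                                  collapse = ", "),
      sprintf(" | common %d\n", length(x$cycling_overlap$common)))
  cat(sprintf("  SOGs: %s | common %d\n",
              paste(sprintf("%s = %d", names(x$sog), vapply(x$sog, function(d) sum(d$is_sog), integer(1))),
                    collapse = ", "),
              length(x$sog_sets$common)))
  cat(sprintf("  FWHM change: %d shortened, %d lengthened, %d unchanged (%.1f%% of common SOGs significant)\n",
              x$change_counts["shortened"], x$change_counts["lengthened"],
              x$change_counts["unchanged"], x$pct_changed))
  invisible(x)
}
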