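#' Enrichment of instance features among important instances
#'
#' Compares the `n_top` reference instances with highest forest
#' importance against `n_random` instances sampled (without
#' replacement) from bags predicted non-pathogenic. Per feature, a
#' two-sample t-test is run and a standardized mean difference
#' `z = (mean_top - mean_random) / pooled sd` is reported (capped at
#' `z_cap` for display); p-values are Bonferroni-adjusted across
#' `n_tests` tests (default: number of features, multiplied by the
#' number of cancer types when several are analysed together).
#'
#' @param model a `tadmil_model`.
#' @param predictions prediction tibble with `pair_id` and `call`
#'   (from [predict.tadmil_model()] with an operating point set) or
#'   `prob` (thresholded at the model's operating point).
#' @param instances raw instance tibble the predictions refer to.
#' @param n_top,n_random group sizes (default 100 each; shrunk with a
#'   log entry when fewer are available).
#' @param n_tests Bonferroni denominator (default: feature count).
#' @param z_cap cap on |z| (default 10).
#' @param seed integer seed for the random draw.
#' @return tibble: `feature`, `mean_top`, `mean_random`, `z`, `p`,
#'   `p_adj`, `direction`.
#' @export
instance_enrichment <- function(model, predictions, instances,
                                n_top = 100, n_random = 100,
                                n_tests = NULL, z_cap = 10, seed = 1) {
  schema <- model$schema
  imp <- rf_instance_importance(model)
  if (nrow(imp) < n_top) {
    message("only ", nrow(imp), " reference instances available for the ",
            "top group (requested ", n_top, ")")
    n_top <- nrow(imp)
  }
  top_meta <- imp[seq_len(n_top), , drop = FALSE]
  top <- dplyr::semi_join(
    normalize_with(instances, model$mins, model$maxs, schema),
    top_meta[, c("pair_id", "element_kind", "chrom", "start", "end",
                 "direction")],
    by = c("pair_id", "element_kind", "chrom", "start", "end", "direction")
  )

  call <- predictions[["call"]]
  if (is.null(call) || all(is.na(call))) {
    if (is.na(model$operating_point)) {
      stop("predictions carry no calls and the model has no operating point")
    }
    call <- predictions$prob >= model$operating_point
  }
  neg_pairs <- predictions$pair_id[!call]
  pool <- instances[instances$pair_id %in% neg_pairs, , drop = FALSE]
  pool <- normalize_with(pool, model$mins, model$maxs, schema)
  if (nrow(pool) < n_random) {
    message("only ", nrow(pool), " non-pathogenic instances available ",
            "(requested ", n_random, ")")
    n_random <- nrow(pool)
  }
  rnd <- with_seed(seed, pool[sample(nrow(pool), n_random), , drop = FALSE])

  enrichment_ztest(top, rnd, schema, n_tests = n_tests, z_cap = z_cap)
}

#' Feature-wise comparison of two instance groups
#'
#' The statistical core of [instance_enrichment()]: per feature, a
#' two-sample t-test between the top-importance group and the random
#' non-pathogenic group, with a standardized mean difference
#' `z = (mean_top - mean_random) / pooled sd`, capped at `z_cap`.
#' Degenerate features (both groups constant) give `z = 0`, `p = 1`
#' when equal and a capped z with `p = 0` when fully separated.
#'
#' @param top,random instance tibbles carrying the schema columns.
#' @param schema feature names to compare.
#' @param n_tests Bonferroni denominator (default: feature count).
#' @param z_cap cap on |z|.
#' @return tibble as in [instance_enrichment()].
#' @export
enrichment_ztest <- function(top, random, schema, n_tests = NULL,
                             z_cap = 10) {
  stopifnot(nrow(top) > 0, nrow(random) > 0)
  n_tests <- n_tests %||% length(schema)
  res <- purrr::map(schema, function(f) {
    a <- top[[f]]
    b <- random[[f]]
    s_pool <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                     (length(a) + length(b) - 2))
    diff <- mean(a) - mean(b)
    z <- if (is.na(s_pool) || s_pool == 0) {
      if (diff == 0) 0 else sign(diff) * z_cap
    } else diff / s_pool
    z <- max(-z_cap, min(z_cap, z))
    p <- tryCatch(t.test(a, b)$p.value,
                  error = function(e) if (diff == 0) 1 else 0)
    if (is.na(p)) p <- if (diff == 0) 1 else 0
    tibble::tibble(feature = f, mean_top = mean(a), mean_random = mean(b),
                   z = z, p = p,
                   p_adj = min(1, p * n_tests),
                   direction = sign(diff))
  })
  dplyr::bind_rows(res)
}

#' Driver-potential permutation test
#'
#' Tests whether candidate genes (those hit by predicted pathogenic
#' non-coding SVs) carry more moderate/high-impact coding SNVs across
#' the cohort than expected by random chance. The null is built from
#' `n_draws` random gene sets of the same size drawn from
#' `gene_universe`; each candidate's count is assigned the one-sided
#' empirical (permutation) tail probability under the pooled null
#' counts, Bonferroni-adjusted across candidates. The reported
#' `t_stat` standardizes the observed count against the null mean and
#' standard deviation.
#'
#' @param candidate_genes character vector of predicted genes.
#' @param snv_counts tibble `gene_id`, `count` (driver SNVs per gene
#'   across the cancer type's patients).
#' @param gene_universe all genes eligible for the random draws.
#' @param driver_catalog optional gene list; counts of genes outside it
#'   are zeroed (catalog filter of the driver definition).
#' @param n_draws number of random gene sets (default 10000).
#' @param seed integer seed.
#' @return tibble per candidate: `gene_id`, `observed`, `null_mean`,
#'   `null_sd`, `t_stat`, `p`, `p_adj`.
#' @export
driver_potential_test <- function(candidate_genes, snv_counts, gene_universe,
                                  driver_catalog = NULL, n_draws = 10000,
                                  seed = 1) {
  counts <- setNames(rep(0, length(gene_universe)), gene_universe)
  known <- intersect(snv_counts$gene_id, gene_universe)
  counts[known] <- snv_counts$count[match(known, snv_counts$gene_id)]
  if (!is.null(driver_catalog)) {
    counts[!names(counts) %in% driver_catalog] <- 0
  }
  missing <- setdiff(candidate_genes, gene_universe)
  if (length(missing) > 0) {
    message(length(missing), " candidate gene(s) absent from the universe, ",
            "excluded")
  }
  candidates <- intersect(candidate_genes, gene_universe)
  if (length(candidates) == 0) {
    return(tibble::tibble(gene_id = character(), observed = double(),
                          null_mean = double(), null_sd = double(),
                          t_stat = double(), p = double(), p_adj = double()))
  }
  set_size <- length(candidates)
  null_idx <- with_seed(seed, {
    replicate(n_draws, sample(length(counts), set_size))
  })
  null_counts <- counts[as.integer(null_idx)]
  mu <- mean(null_counts)
  s <- sd(null_counts)
  res <- purrr::map(candidates, function(g) {
    obs <- counts[[g]]
    # permutation-style one-sided tail with add-one correction; the
    # tested gene's own draws are excluded from its null ("random
    # chance" means the other genes)
    own <- match(g, names(counts))
    keep <- as.integer(null_idx) != own
    p <- (1 + sum(null_counts[keep] >= obs)) / (1 + sum(keep))
    if (obs <= mu) p <- max(p, 0.5)  # at or below the null: never signal
    tibble::tibble(gene_id = g, observed = obs, null_mean = mu, null_sd = s,
                   t_stat = if (!is.na(s) && s > 0) (obs - mu) / s else
                     if (obs == mu) 0 else Inf * sign(obs - mu),
                   p = p, p_adj = min(1, p * length(candidates)))
  })
  dplyr::arrange(dplyr::bind_rows(res), .data$p_adj, .data$gene_id)
}

#' Regulatory-track swap z-scores
#'
#' Quantifies, for one target tissue, how replacing its regulatory
#' tracks with each source tissue's tracks shifts model performance.
#' Per swap, the signed AUC differences to the original run are summed
#' across SV types; a z-score standardizes each swap's sum against the
#' mean and standard deviation over all swaps, then is quantized into
#' non-significant (|z| < 1), significant (1 <= |z| < 2) and highly
#' significant (|z| >= 2) classes.
#'
#' @param auc_original tibble `sv_type`, `auc` of the original run.
#' @param auc_swapped tibble `source`, `sv_type`, `auc`, one row per
#'   swap and SV type. SV types missing from any run are skipped
#'   symmetrically.
#' @return tibble `source`, `d` (summed AUC difference), `z`, `class`.
#' @export
regulatory_swap_analysis <- function(auc_original, auc_swapped) {
  shared <- Reduce(intersect, c(list(auc_original$sv_type),
                                split(auc_swapped$sv_type,
                                      auc_swapped$source)))
  if (length(shared) == 0) stop("no SV type shared by all runs")
  orig <- setNames(auc_original$auc, auc_original$sv_type)[shared]
  d <- auc_swapped |>
    dplyr::filter(.data$sv_type %in% shared) |>
    dplyr::group_by(source = .data$source) |>
    dplyr::summarise(
      d = sum(.data$auc - orig[.data$sv_type]), .groups = "drop")
  s <- sd(d$d)
  d$z <- if (is.na(s) || s == 0) rep(0, nrow(d)) else (d$d - mean(d$d)) / s
  d$class <- dplyr::case_when(
    abs(d$z) >= 2 ~ "highly significant",
    abs(d$z) >= 1 ~ "significant",
    TRUE ~ "ns"
  )
  d
}
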