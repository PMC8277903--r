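#' Prepare annotation tracks for feature encoding
#'
#' Applies the standard preprocessing: eQTL p-value filtering followed
#' by fixed-width binning of eQTLs, histone marks and TF binding sites
#' (other peak tracks and chromHMM segments are used as-is).
#'
#' @param genome bundle from [simulate_reference()], or any list with
#'   the same track layout.
#' @param bin_width window width in bp (default 1000).
#' @param eqtl_p_threshold eQTL p-value cutoff (default 0.05).
#' @return list with `elements` ([element_table()]) and `tracks`
#'   (named list for [encode_instances()]).
#' @export
prepare_tracks <- function(genome, bin_width = 1000, eqtl_p_threshold = 0.05) {
  eqtl <- bin_track(filter_eqtls(genome$eqtl, eqtl_p_threshold), bin_width)
  tracks <- genome$tracks
  for (nm in c("h3k4me3", "h3k27me3", "h3k27ac", "h3k4me1", "tfbs")) {
    if (!is.null(tracks[[nm]])) tracks[[nm]] <- bin_track(tracks[[nm]],
                                                          bin_width)
  }
  list(
    elements = element_table(eqtl, genome$enhancer, genome$super_enhancer),
    tracks = tracks
  )
}

#' Run the full SV-gene pairing and MIL classification pipeline
#'
#' End-to-end driver: regulatory-track preparation, mutation-index
#' construction, derivative-domain rewiring into SV-gene pairs,
#' instance encoding, expression labeling, class balancing, per-SV-type
#' bag capping, leave-one-patient-out cross-validation and
#' operating-point selection, and a final per-SV-type model trained on
#' all bags.
#'
#' @param genome reference bundle ([simulate_reference()] or
#'   equivalently structured real tracks).
#' @param cohort cohort list ([simulate_cohort()] or real calls):
#'   `svs`, `snvs`, `cnvs`, `expression`.
#' @param bin_width,eqtl_p_threshold track preprocessing parameters.
#' @param z_threshold,min_reference labeling parameters.
#' @param bag_cap per-SV-type bag cap (default 700).
#' @param min_precision precision floor for the operating point.
#' @param num_trees forest size.
#' @param schema feature schema.
#' @param seed master seed; all stochastic steps derive from it.
#' @return list with `pairs`, `instances`, `bags` (all labelled),
#'   `balanced` (after balancing and capping), `cv` (pooled
#'   predictions), `models` (per SV type, with `cv_predictions` and
#'   `operating_point` filled), and `auc_table`.
#' @export
run_mil_pipeline <- function(genome, cohort,
                             bin_width = 1000, eqtl_p_threshold = 0.05,
                             z_threshold = 1.5, min_reference = 5,
                             bag_cap = 700, min_precision = 0.5,
                             num_trees = 100, schema = feature_schema(),
                             seed = 1) {
  prep <- prepare_tracks(genome, bin_width, eqtl_p_threshold)
  index <- build_mutation_index(cohort$snvs, cohort$cnvs, cohort$svs,
                                genome$genes)
  pairs <- build_sv_gene_pairs(cohort$svs, genome$domains, genome$genes,
                               prep$elements, index)
  instances <- encode_instances(pairs, prep$tracks, schema)
  bags <- assign_labels(pairs, cohort$expression, index,
                        z_threshold = z_threshold,
                        min_reference = min_reference)
  balanced <- balance_classes(bags, seed = child_seed(seed, 10))
  balanced <- dplyr::bind_rows(purrr::imap(
    split(balanced, balanced$sv_type),
    function(b, type) subsample_bags(b, bag_cap,
                                     seed = child_seed(seed, 11))
  ))

  models <- list(); cvs <- list(); auc_rows <- list()
  for (type in sort(unique(balanced$sv_type))) {
    b <- balanced[balanced$sv_type == type, , drop = FALSE]
    if (length(unique(b$patient)) < 2 ||
        length(unique(b$label)) < 2 || min(table(b$label)) < 2) next
    cv <- leave_one_patient_out_cv(b, instances, schema,
                                   num_trees = num_trees,
                                   seed = child_seed(seed, 20))
    op <- select_operating_point(cv$truth, cv$prob, min_precision)
    model <- train_model(b, instances, schema, num_trees = num_trees,
                         seed = child_seed(seed, 30))
    model$cv_predictions <- cv
    model$operating_point <- op$threshold
    models[[type]] <- model
    cvs[[type]] <- cv
    auc_rows[[type]] <- tibble::tibble(
      sv_type = type, n_bags = nrow(b),
      auc = compute_auc(cv$truth, cv$prob),
      threshold = op$threshold, precision = op$precision,
      recall = op$recall
    )
  }
  list(
    pairs = pairs, instances = instances, bags = bags, balanced = balanced,
    cv = dplyr::bind_rows(cvs), models = models,
    auc_table = dplyr::bind_rows(auc_rows)
  )
}
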