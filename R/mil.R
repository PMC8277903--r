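#' MILES embedding and per-SV-type random forest
#'
#' Bags (SV-gene pairs) are mapped into a bag-to-instance feature space:
#' entry (i, j) of the embedding is the absolute (L1) distance between
#' the mean instance vector of bag i and reference instance j, where the
#' reference instances are all instances of the training bags. A random
#' forest with probability output is trained in this space, one model
#' per SV type, and evaluated with leave-one-patient-out
#' cross-validation.
#'
#' @name mil
NULL

instance_matrix <- function(instances, schema) {
  schema <- intersect(schema, names(instances))
  as.matrix(instances[, schema, drop = FALSE])
}

#' Mean instance vector of a bag
#'
#' @param bag_instances instance tibble of one bag (>= 1 row).
#' @param schema feature names.
#' @return named numeric vector (element-wise mean).
#' @export
mean_instance <- function(bag_instances, schema = feature_schema()) {
  if (nrow(bag_instances) == 0) stop("bag has no instances")
  colMeans(instance_matrix(bag_instances, schema))
}

# per-bag mean vectors, rows ordered as `pair_ids`
bag_mean_matrix <- function(instances, pair_ids, schema) {
  m <- instance_matrix(instances, schema)
  sums <- rowsum(m, group = instances$pair_id)
  counts <- as.vector(table(instances$pair_id)[rownames(sums)])
  means <- sums / counts
  missing <- setdiff(pair_ids, rownames(means))
  if (length(missing) > 0) stop("bags without instances: ", missing[1])
  means[pair_ids, , drop = FALSE]
}

#' Bag-to-instance similarity (distance) embedding
#'
#' @param bag_means matrix of bag mean-instance vectors (bags x features).
#' @param reference matrix of reference instance vectors
#'   (instances x features).
#' @param metric `"l1"` (absolute distance, default) or `"l2"`.
#' @return non-negative distance matrix, bags x reference instances.
#' @export
miles_embed <- function(bag_means, reference, metric = c("l1", "l2")) {
  metric <- match.arg(metric)
  if (ncol(bag_means) != ncol(reference)) {
    stop("feature dimension mismatch between bags and reference instances")
  }
  n <- nrow(bag_means)
  m <- nrow(reference)
  d <- matrix(0, n, m)
  for (k in seq_len(ncol(bag_means))) {
    diff <- outer(bag_means[, k], reference[, k], `-`)
    d <- d + if (metric == "l1") abs(diff) else diff^2
  }
  if (metric == "l2") d <- sqrt(d)
  d
}

#' Cap the number of bags per SV type
#'
#' Uniformly subsamples bags when their count exceeds `cap` (default
#' 700), preserving the class ratio as closely as possible.
#' Deterministic under `seed`.
#'
#' @param bags bag tibble.
#' @param cap maximum bag count.
#' @param seed integer seed.
#' @return subsampled bag tibble.
#' @export
subsample_bags <- function(bags, cap = 700, seed = 1) {
  if (nrow(bags) <= cap) return(bags)
  with_seed(seed, {
    pos <- which(bags$label == "positive")
    neg <- which(bags$label == "negative")
    n_pos <- min(length(pos), round(cap * length(pos) / nrow(bags)))
    n_neg <- cap - n_pos
    keep <- sort(c(safe_sample(pos, n_pos), safe_sample(neg, n_neg)))
    bags[keep, , drop = FALSE]
  })
}

#' Train a MILES random-forest model for one SV type
#'
#' Normalizes the training instances ([normalize_features()]), stores
#' them as the embedding reference, embeds the bags and fits a random
#' forest (100 trees, sqrt-features per split, impurity importance).
#'
#' @param bags labelled bag tibble (one SV type; >= 2 bags per class).
#' @param instances raw (un-normalized) instance tibble covering the
#'   bags' pairs.
#' @param schema feature names.
#' @param metric embedding metric, `"l1"` or `"l2"`.
#' @param num_trees,mtry random-forest hyperparameters; `mtry = NULL`
#'   uses the square root of the embedding dimension.
#' @param seed integer seed (forest growth is deterministic under it).
#' @return a `tadmil_model` bundle: forest, reference instances,
#'   normalization statistics, schema, and slots for CV predictions and
#'   operating point.
#' @export
train_model <- function(bags, instances, schema = feature_schema(),
                        metric = "l1", num_trees = 100, mtry = NULL,
                        seed = 1) {
  classes <- table(factor(bags$label, c("negative", "positive")))
  if (any(classes < 2)) {
    stop("need at least 2 bags per class; got ",
         paste(classes, collapse = "/"))
  }
  inst <- instances[instances$pair_id %in% bags$pair_id, , drop = FALSE]
  schema <- intersect(schema, names(inst))
  mins <- vapply(schema, function(f) min(inst[[f]]), 0)
  maxs <- vapply(schema, function(f) max(inst[[f]]), 0)
  norm <- normalize_with(inst, mins, maxs, schema)
  reference <- instance_matrix(norm, schema)
  bag_means <- bag_mean_matrix(norm, bags$pair_id, schema)
  emb <- miles_embed(bag_means, reference, metric)
  df <- as.data.frame(emb)
  names(df) <- paste0("ref", seq_len(ncol(df)))
  df$.label <- factor(bags$label, c("negative", "positive"))
  forest <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = num_trees,
    mtry = mtry %||% max(1, floor(sqrt(ncol(emb)))),
    probability = TRUE, importance = "impurity",
    seed = seed, num.threads = 1
  )
  structure(list(
    sv_type = if (length(unique(bags$sv_type)) == 1) bags$sv_type[1] else NA,
    forest = forest,
    schema = schema, metric = metric,
    mins = mins, maxs = maxs,
    reference = reference,
    reference_meta = norm[, intersect(
      c("pair_id", "patient", "sv_id", "gene_id", "element_kind",
        "chrom", "start", "end", "direction"), names(norm))],
    train_bags = bags,
    operating_point = NA_real_,
    cv_predictions = NULL,
    seed = seed
  ), class = "tadmil_model")
}

normalize_with <- function(df, mins, maxs, schema) {
  for (f in schema) {
    rng <- maxs[f] - mins[f]
    df[[f]] <- if (rng == 0) rep(0, nrow(df)) else
      pmin(1, pmax(0, (df[[f]] - mins[f]) / rng))
  }
  df
}

#' Predict pathogenicity probabilities for bags
#'
#' New bags are normalized with the bundle's training statistics,
#' embedded against its reference instances, and scored by the forest.
#' When the bundle carries an operating point, `call` marks
#' probabilities at or above it.
#'
#' @param object a `tadmil_model`.
#' @param bags bag tibble (only `pair_id` is required).
#' @param instances raw instance tibble covering the bags.
#' @param ... unused.
#' @return tibble `pair_id`, `prob`, `call`.
#' @export
predict.tadmil_model <- function(object, bags, instances, ...) {
  if (nrow(bags) == 0) {
    return(tibble::tibble(pair_id = character(), prob = double(),
                          call = logical()))
  }
  if (!all(object$schema %in% names(instances))) {
    stop("instance columns do not match the model schema")
  }
  inst <- instances[instances$pair_id %in% bags$pair_id, , drop = FALSE]
  norm <- normalize_with(inst, object$mins, object$maxs, object$schema)
  bag_means <- bag_mean_matrix(norm, bags$pair_id, object$schema)
  emb <- miles_embed(bag_means, object$reference, object$metric)
  df <- as.data.frame(emb)
  names(df) <- paste0("ref", seq_len(ncol(df)))
  prob <- predict(object$forest, data = df,
                  num.threads = 1)$predictions[, "positive"]
  tibble::tibble(
    pair_id = bags$pair_id, prob = as.numeric(prob),
    call = if (is.na(object$operating_point)) NA else
      as.numeric(prob) >= object$operating_point
  )
}

#' Leave-one-patient-out cross-validation
#'
#' For every patient, a model is trained on all other patients' bags
#' (embedding reference and normalization statistics from the training
#' instances only) and the held-out patient's bags are scored. Pooled
#' predictions over all folds are returned. Folds whose training set
#' lacks a class are skipped with a warning.
#'
#' @param bags labelled bag tibble of one SV type (>= 2 patients).
#' @param instances raw instance tibble.
#' @param schema,metric,num_trees,seed as in [train_model()].
#' @return tibble `pair_id`, `patient`, `sv_type`, `truth`, `prob`.
#' @export
leave_one_patient_out_cv <- function(bags, instances,
                                     schema = feature_schema(),
                                     metric = "l1", num_trees = 100,
                                     seed = 1) {
  patients <- sort(unique(bags$patient))
  if (length(patients) < 2) stop("need at least 2 patients")
  preds <- purrr::map(patients, function(p) {
    train_bags <- bags[bags$patient != p, , drop = FALSE]
    test_bags <- bags[bags$patient == p, , drop = FALSE]
    if (length(unique(train_bags$label)) < 2 ||
        min(table(train_bags$label)) < 2) {
      warning("fold for patient ", p, " skipped: single-class training set")
      return(NULL)
    }
    model <- train_model(train_bags, instances, schema, metric, num_trees,
                         seed = child_seed(seed, match(p, patients)))
    scored <- predict(model, test_bags, instances)
    tibble::tibble(
      pair_id = test_bags$pair_id, patient = p,
      sv_type = test_bags$sv_type,
      truth = test_bags$label, prob = scored$prob
    )
  })
  dplyr::bind_rows(preds)
}

#' Rank-based AUC of pooled CV predictions
#'
#' Mann-Whitney formulation: probability that a random positive ranks
#' above a random negative, ties counting one half.
#'
#' @param truth class labels (`"positive"`/`"negative"` or logical).
#' @param prob predicted scores.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(truth, prob) {
  pos <- if (is.logical(truth)) truth else truth == "positive"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("AUC undefined: single-class input")
  r <- rank(prob)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Operating point: maximal recall at a precision floor
#'
#' Sweeps the candidate thresholds (the distinct predicted scores; a
#' call is `prob >= threshold`) and returns the threshold with the
#' highest recall among those reaching `min_precision`. Among
#' equal-recall thresholds the one with the higher precision wins (on a
#' perfectly separated score set this lands just below the lowest
#' positive score), and remaining ties break toward the lower
#' threshold.
#'
#' @param truth,prob pooled CV labels and scores.
#' @param min_precision precision floor (default 0.5).
#' @return list `threshold`, `precision`, `recall`; `threshold` is `NA`
#'   (with a warning) when no threshold reaches the floor.
#' @export
select_operating_point <- function(truth, prob, min_precision = 0.5) {
  pos <- if (is.logical(truth)) truth else truth == "positive"
  thresholds <- sort(unique(prob))
  stats <- purrr::map(thresholds, function(t) {
    call <- prob >= t
    tp <- sum(call & pos)
    list(threshold = t,
         precision = if (sum(call) == 0) NA_real_ else tp / sum(call),
         recall = tp / sum(pos))
  })
  stats <- purrr::keep(stats, ~ !is.na(.x$precision) &&
                         .x$precision >= min_precision)
  if (length(stats) == 0) {
    warning("no threshold reaches precision ", min_precision)
    return(list(threshold = NA_real_, precision = NA_real_,
                recall = NA_real_))
  }
  recalls <- purrr::map_dbl(stats, "recall")
  precisions <- purrr::map_dbl(stats, "precision")
  at_max <- which(recalls == max(recalls))
  # thresholds are ascending, so the first index also breaks exact ties
  # toward the lower threshold
  best <- at_max[which(precisions[at_max] == max(precisions[at_max]))[1]]
  stats[[best]]
}

#' Per-instance feature importance of the trained forest
#'
#' Maps the forest's impurity importance on the embedding columns back
#' to the reference instances and normalizes to sum to one.
#'
#' @param model a `tadmil_model`.
#' @return reference-instance metadata tibble with an `importance`
#'   column, sorted decreasing.
#' @export
rf_instance_importance <- function(model) {
  imp <- ranger::importance(model$forest)
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- model$reference_meta
  out$importance <- as.numeric(imp)
  dplyr::arrange(out, dplyr::desc(.data$importance))
}

#' @method tidy tadmil_model
#' @export
tidy.tadmil_model <- function(x, ...) rf_instance_importance(x)

#' @method glance tadmil_model
#' @export
glance.tadmil_model <- function(x, ...) {
  cv_auc <- if (!is.null(x$cv_predictions)) {
    compute_auc(x$cv_predictions$truth, x$cv_predictions$prob)
  } else NA_real_
  tibble::tibble(
    sv_type = x$sv_type,
    n_bags = nrow(x$train_bags),
    n_positive = sum(x$train_bags$label == "positive"),
    n_reference_instances = nrow(x$reference),
    num_trees = x$forest$num.trees,
    cv_auc = cv_auc,
    operating_point = x$operating_point
  )
}

#' @export
print.tadmil_model <- function(x, ...) {
  cat("<tadmil_model>", x$sv_type %||% "", "\n")
  cat("  bags:", nrow(x$train_bags),
      "(", sum(x$train_bags$label == "positive"), "positive )\n")
  cat("  reference instances:", nrow(x$reference), "\n")
  cat("  operating point:", format(x$operating_point), "\n")
  invisible(x)
}
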