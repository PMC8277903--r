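#' Instance feature schema
#'
#' Ordered feature names describing one gained or lost regulatory
#' element: gain/loss indicators, binary overlap with histone marks,
#' chromHMM states, open-chromatin/TF tracks and CpG islands, peak
#' strengths, element-kind one-hot, and the total number of elements the
#' parent SV disrupts. The default (`"current"`) state set excludes the
#' low-variance chromHMM enhancer/repeat states; `"legacy"` retains
#' them (the feature set of the previous model generation).
#'
#' @param chromhmm_state_set `"current"` (default, 29 features) or
#'   `"legacy"`.
#' @param include_ctcf_strength keep the CTCF peak-strength feature
#'   (default TRUE).
#' @return character vector of feature names, in fixed order.
#' @export
feature_schema <- function(chromhmm_state_set = c("current", "legacy"),
                           include_ctcf_strength = TRUE) {
  chromhmm_state_set <- match.arg(chromhmm_state_set)
  chromhmm <- c("chromhmm_ctcf", "chromhmm_ctcf_enhancer",
                "chromhmm_ctcf_promoter",
                if (chromhmm_state_set == "legacy") "chromhmm_enhancer",
                "chromhmm_promoter", "chromhmm_poised_promoter",
                "chromhmm_heterochromatin", "chromhmm_repressed",
                if (chromhmm_state_set == "legacy") "chromhmm_repeat",
                "chromhmm_transcribed")
  c("gain", "loss",
    "h3k4me3", "h3k27me3", "h3k27ac", "h3k4me1",
    chromhmm,
    "dnase", "rnapol2", "ctcf_peak", "tfbs", "cpg",
    "h3k4me3_strength", "h3k27me3_strength", "h3k27ac_strength",
    "h3k4me1_strength", "rnapol2_strength",
    if (include_ctcf_strength) "ctcf_strength",
    "is_eqtl", "is_enhancer", "is_super_enhancer", "instance_count")
}

# chromHMM state label -> schema feature name
CHROMHMM_STATE_MAP <- c(
  "CTCF" = "chromhmm_ctcf",
  "CTCF+Enhancer" = "chromhmm_ctcf_enhancer",
  "CTCF+Promoter" = "chromhmm_ctcf_promoter",
  "Enhancer" = "chromhmm_enhancer",
  "Promoter" = "chromhmm_promoter",
  "Poised_Promoter" = "chromhmm_poised_promoter",
  "Heterochromatin" = "chromhmm_heterochromatin",
  "Repressed" = "chromhmm_repressed",
  "Repeat" = "chromhmm_repeat",
  "Transcribed" = "chromhmm_transcribed"
)

#' Encode gain/loss records as instance feature vectors
#'
#' Builds, for every record of [build_sv_gene_pairs()], the fixed-length
#' feature vector of [feature_schema()]: binary >= 1 bp overlap with each
#' annotation track, maximum peak intensity among overlapping peaks for
#' the strength features, element-kind one-hot, gain/loss indicator, and
#' the parent SV's total record count (`instance_count`). Values are raw
#' (not yet min-max normalized; see [normalize_features()]).
#'
#' @param records record tibble from [build_sv_gene_pairs()].
#' @param tracks named list of track tibbles; recognised names:
#'   `h3k4me3`, `h3k27me3`, `h3k27ac`, `h3k4me1`, `dnase`, `rnapol2`,
#'   `ctcf`, `tfbs`, `cpg`, `chromhmm`. Missing tracks yield all-zero
#'   features for their columns.
#' @param schema feature-name vector, default [feature_schema()].
#' @return tibble: record metadata columns followed by one numeric
#'   column per schema feature.
#' @export
encode_instances <- function(records, tracks, schema = feature_schema()) {
  bad <- setdiff(unique(records$element_kind),
                 c("eqtl", "enhancer", "super_enhancer"))
  if (length(bad) > 0) stop("unknown element kind: ", bad[1])
  n <- nrow(records)
  feats <- matrix(0, nrow = n, ncol = length(schema),
                  dimnames = list(NULL, schema))
  if (n == 0) {
    return(dplyr::bind_cols(records, tibble::as_tibble(feats)))
  }
  el <- records[, c("chrom", "start", "end")]

  feats[, "gain"] <- as.numeric(records$direction == "gain")
  feats[, "loss"] <- as.numeric(records$direction == "loss")
  feats[, "is_eqtl"] <- as.numeric(records$element_kind == "eqtl")
  feats[, "is_enhancer"] <- as.numeric(records$element_kind == "enhancer")
  feats[, "is_super_enhancer"] <-
    as.numeric(records$element_kind == "super_enhancer")

  binary_map <- c(h3k4me3 = "h3k4me3", h3k27me3 = "h3k27me3",
                  h3k27ac = "h3k27ac", h3k4me1 = "h3k4me1",
                  dnase = "dnase", rnapol2 = "rnapol2", ctcf = "ctcf_peak",
                  tfbs = "tfbs", cpg = "cpg")
  strength_map <- c(h3k4me3 = "h3k4me3_strength", h3k27me3 = "h3k27me3_strength",
                    h3k27ac = "h3k27ac_strength", h3k4me1 = "h3k4me1_strength",
                    rnapol2 = "rnapol2_strength", ctcf = "ctcf_strength")

  for (tn in names(binary_map)) {
    track <- tracks[[tn]]
    if (is.null(track) || nrow(track) == 0) next
    hits <- overlap_pairs(el, track)
    feat <- binary_map[[tn]]
    if (feat %in% schema) {
      feats[unique(hits$x_idx), feat] <- 1
    }
    sfeat <- strength_map[tn]
    if (!is.na(sfeat) && sfeat %in% schema && !is.null(track[["signal"]]) &&
        nrow(hits) > 0) {
      mx <- tapply(track$signal[hits$y_idx], hits$x_idx,
                   function(v) if (all(is.na(v))) 0 else max(v, na.rm = TRUE))
      feats[as.integer(names(mx)), sfeat] <- as.numeric(mx)
    }
  }

  chromhmm <- tracks$chromhmm
  if (!is.null(chromhmm) && nrow(chromhmm) > 0) {
    hits <- overlap_pairs(el, chromhmm)
    if (nrow(hits) > 0) {
      feat <- CHROMHMM_STATE_MAP[chromhmm$state[hits$y_idx]]
      ok <- !is.na(feat) & feat %in% schema
      feats[cbind(hits$x_idx[ok], match(feat[ok], schema))] <- 1
    }
  }

  sv_counts <- records |>
    dplyr::count(.data$patient, .data$sv_id, name = "n_records")
  counts <- dplyr::left_join(records[, c("patient", "sv_id")], sv_counts,
                             by = c("patient", "sv_id"))
  feats[, "instance_count"] <- counts$n_records

  dplyr::bind_cols(records, tibble::as_tibble(feats))
}

#' Min-max normalize instance features
#'
#' Scales every schema feature to `[0, 1]` using the minimum and maximum
#' observed in the training instances only (no leakage from held-out
#' data); values of the apply set outside the training range are clipped
#' to `[0, 1]`. Constant features map to 0.
#'
#' @param train instance tibble used to fit the statistics.
#' @param apply optional second instance tibble transformed with the
#'   training statistics (default: none).
#' @param schema feature names to normalize.
#' @return the normalized training tibble; when `apply` is supplied, a
#'   list with elements `train` and `apply`.
#' @export
normalize_features <- function(train, apply = NULL, schema = feature_schema()) {
  stopifnot(nrow(train) > 0)
  schema <- intersect(schema, names(train))
  mins <- vapply(schema, function(f) min(train[[f]], na.rm = TRUE), 0)
  maxs <- vapply(schema, function(f) max(train[[f]], na.rm = TRUE), 0)
  scale_one <- function(df) {
    for (f in schema) {
      rng <- maxs[f] - mins[f]
      df[[f]] <- if (rng == 0) rep(0, nrow(df)) else
        pmin(1, pmax(0, (df[[f]] - mins[f]) / rng))
    }
    df
  }
  if (is.null(apply)) scale_one(train) else
    list(train = scale_one(train), apply = scale_one(apply))
}

#' Drop features with near-zero variance
#'
#' Computes, per feature, the natural-log variance across all instances
#' and drops features below the threshold (default `log(var) < -10`),
#' the criterion used to prune uninformative annotation columns.
#'
#' @param instances instance tibble.
#' @param log_var_threshold drop features with `log(variance)` strictly
#'   below this (default -10; `-Inf` disables dropping).
#' @param schema candidate feature names.
#' @return list with `schema` (retained names), `dropped`, and
#'   `log_variance` (named numeric vector).
#' @export
select_features_by_variance <- function(instances, log_var_threshold = -10,
                                        schema = feature_schema()) {
  schema <- intersect(schema, names(instances))
  stopifnot(nrow(instances) >= 2)
  v <- vapply(schema, function(f) var(instances[[f]]), 0)
  logv <- suppressWarnings(log(v))
  logv[v == 0] <- -Inf
  drop <- logv < log_var_threshold
  list(schema = schema[!drop], dropped = schema[drop],
       log_variance = setNames(logv, schema))
}
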