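#' Expression z-score of a gene in a focal patient
#'
#' The z-score compares the focal patient's expression with the
#' reference panel of patients carrying no disruption of the gene
#' (no coding SNV, out-of-range copy number, coding SV overlap, or
#' non-coding SV-gene pair): `z = (x - mean(ref)) / sd(ref)`, sample
#' standard deviation (n - 1).
#'
#' @param gene gene id.
#' @param patient focal patient id.
#' @param expression wide expression tibble ([read_expression()]).
#' @param mutation_index flag tibble ([build_mutation_index()]), or NULL.
#' @param pairs record tibble ([build_sv_gene_pairs()]) used to exclude
#'   patients with a non-coding SV on the gene, or NULL.
#' @param min_reference minimum reference-panel size (default 5).
#' @return list with `z` and `n_reference`; `z` is `NA` when the gene is
#'   unexpressed in the focal patient, the panel is too small, or the
#'   panel standard deviation is zero.
#' @export
expression_zscore <- function(gene, patient, expression, mutation_index = NULL,
                              pairs = NULL, min_reference = 5) {
  row <- expression[expression$gene_id == gene, , drop = FALSE]
  if (nrow(row) != 1) return(list(z = NA_real_, n_reference = 0L))
  all_pat <- setdiff(names(expression), "gene_id")
  x <- if (patient %in% names(row)) as.numeric(row[[patient]]) else NA_real_
  if (is.na(x)) return(list(z = NA_real_, n_reference = 0L))
  excluded <- patient
  if (!is.null(mutation_index)) {
    excluded <- c(excluded,
                  mutation_index$patient[mutation_index$gene_id == gene])
  }
  if (!is.null(pairs)) {
    excluded <- c(excluded, pairs$patient[pairs$gene_id == gene])
  }
  ref_pat <- setdiff(all_pat, excluded)
  ref <- as.numeric(row[1, ref_pat, drop = TRUE])
  ref <- ref[!is.na(ref)]
  if (length(ref) < min_reference) {
    return(list(z = NA_real_, n_reference = length(ref)))
  }
  s <- sd(ref)
  if (is.na(s) || s == 0) {
    return(list(z = NA_real_, n_reference = length(ref)))
  }
  list(z = (x - mean(ref)) / s, n_reference = length(ref))
}

#' Label SV-gene pairs from patient-matched expression
#'
#' Every pair becomes a labelled bag: positive when the expression
#' z-score against the undisrupted reference panel exceeds the threshold
#' in magnitude (`z > z_threshold` or `z < -z_threshold`, strict),
#' negative otherwise. Pairs whose gene lacks expression in the focal
#' patient, has a degenerate reference panel (sd 0) or fewer than
#' `min_reference` reference patients are excluded with a log entry.
#'
#' @param pairs record tibble from [build_sv_gene_pairs()].
#' @param expression wide expression tibble.
#' @param mutation_index flag tibble, or NULL.
#' @param z_threshold label threshold on |z| (default 1.5).
#' @param min_reference minimum reference-panel size (default 5).
#' @return bag tibble: `pair_id`, `patient`, `sv_id`, `sv_type`,
#'   `gene_id`, `z`, `n_reference`, `label` (`"positive"`/`"negative"`).
#' @export
assign_labels <- function(pairs, expression, mutation_index = NULL,
                          z_threshold = 1.5, min_reference = 5) {
  bags <- dplyr::distinct(
    pairs[, c("pair_id", "patient", "sv_id", "sv_type", "gene_id")]
  )
  zs <- purrr::map(seq_len(nrow(bags)), function(i) {
    expression_zscore(bags$gene_id[i], bags$patient[i], expression,
                      mutation_index, pairs, min_reference)
  })
  bags$z <- purrr::map_dbl(zs, "z")
  bags$n_reference <- purrr::map_int(zs, ~ as.integer(.x$n_reference))
  excluded <- is.na(bags$z)
  if (any(excluded)) {
    message(sum(excluded),
            " pair(s) excluded from labeling (missing expression, ",
            "small or degenerate reference panel)")
  }
  bags <- bags[!excluded, , drop = FALSE]
  bags$label <- ifelse(abs(bags$z) > z_threshold, "positive", "negative")
  bags
}

#' Balance classes by subsampling negative bags
#'
#' Within each SV type, negatives are uniformly subsampled without
#' replacement down to the number of positives (no upsampling in the
#' opposite direction). Deterministic under `seed`.
#'
#' @param bags bag tibble from [assign_labels()].
#' @param seed integer seed.
#' @return balanced bag tibble.
#' @export
balance_classes <- function(bags, seed = 1) {
  with_seed(seed, {
    out <- purrr::map(split(bags, bags$sv_type), function(b) {
      pos <- b[b$label == "positive", , drop = FALSE]
      neg <- b[b$label == "negative", , drop = FALSE]
      if (nrow(pos) == 0) {
        warning("no positive bags for SV type ", b$sv_type[1],
                "; type skipped")
        return(NULL)
      }
      if (nrow(neg) > nrow(pos)) {
        neg <- neg[sort(sample(nrow(neg), nrow(pos))), , drop = FALSE]
      }
      dplyr::bind_rows(pos, neg)
    })
    out <- dplyr::bind_rows(out)
    if (nrow(out) == 0) return(bags[0, , drop = FALSE])
    dplyr::arrange(out, .data$patient, .data$sv_id, .data$gene_id)
  })
}
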