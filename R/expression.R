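#' Read a normalized expression matrix
#'
#' Expects a TSV whose first column is the gene id and whose remaining
#' columns are patients, holding normalized (e.g. TMM) expression values.
#' Empty cells are read as missing; the gene is then excluded for that
#' patient downstream.
#'
#' @param path TSV path.
#' @return wide tibble: `gene_id` plus one numeric column per patient.
#' @export
read_expression <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  names(out)[1] <- "gene_id"
  out <- dplyr::mutate(out, dplyr::across(-"gene_id", as.numeric))
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene id in expression matrix: ",
         out$gene_id[duplicated(out$gene_id)][1])
  }
  out
}

#' Read a gene-level copy-number table
#'
#' Same layout as the expression matrix: `gene_id` column plus one column
#' of copy numbers per patient.
#'
#' @param path TSV path.
#' @return wide tibble: `gene_id` plus one numeric column per patient.
#' @export
read_cnv_table <- function(path) read_expression(path)

#' Pivot a gene-by-patient wide table to long form
#'
#' @param wide tibble from [read_expression()] or [read_cnv_table()].
#' @param value_name name for the value column.
#' @return long tibble `gene_id`, `patient`, `<value_name>`.
#' @export
matrix_long <- function(wide, value_name = "value") {
  tidyr::pivot_longer(wide, -"gene_id",
                      names_to = "patient", values_to = value_name)
}

#' Read a gene annotation BED
#'
#' BED with columns chrom, start, end, gene id and optionally strand in
#' column 5 or 6 (BED6 score is ignored).
#'
#' @param path BED path.
#' @return tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    stop("gene BED line ", which(nf < 4)[1], " needs >= 4 columns")
  }
  strand <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    cand <- f[f %in% c("+", "-")]
    if (length(cand) > 0) cand[1] else "+"
  }, "")
  out <- tibble::tibble(
    gene_id = vapply(fields, `[[`, "", 4),
    chrom = norm_chrom(vapply(fields, `[[`, "", 1)),
    start = as.numeric(vapply(fields, `[[`, "", 2)),
    end = as.numeric(vapply(fields, `[[`, "", 3)),
    strand = strand
  )
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene_id in gene annotation")
  }
  out
}

#' Build the per-patient mutation index
#'
#' Flags, per patient and gene, the coding disruptions used to filter
#' SV-gene pairs and to choose expression reference panels:
#' * `coding_snv` — at least one SNV of moderate or high impact overlaps
#'   the gene body (>= 1 bp);
#' * `cnv_out_of_range` — gene copy number below `2 - delta` or above
#'   `2 + delta` (default bounds 1.7 and 2.3);
#' * `coding_sv` — an SV's breakpoint-to-breakpoint span overlaps the
#'   gene body (>= 1 bp; translocation breakpoints count as 1-bp ends).
#'
#' Patients present in one input but not another are treated as having no
#' mutation of the missing kind, with a warning.
#'
#' @param snvs tibble of SNV calls (`patient`, `chrom`, `pos`, `impact`),
#'   e.g. [read_snv_calls()] rows bound over patients.
#' @param cnvs wide copy-number tibble from [read_cnv_table()], or NULL.
#' @param svs SV tibble, or NULL.
#' @param genes gene tibble from [read_genes()].
#' @param cnv_delta half-width of the copy-number window around 2.
#' @return long flag tibble: `patient`, `gene_id`, `flag` (one of
#'   `"coding_snv"`, `"cnv_out_of_range"`, `"coding_sv"`), `sv_id`
#'   (the flagging SV for `coding_sv`, otherwise `NA`).
#' @export
build_mutation_index <- function(snvs, cnvs, svs, genes, cnv_delta = 0.3) {
  pat_sets <- list(
    snv = if (is.null(snvs)) character() else unique(snvs$patient),
    cnv = if (is.null(cnvs)) character() else setdiff(names(cnvs), "gene_id"),
    sv = if (is.null(svs)) character() else unique(svs$patient)
  )
  all_pat <- unique(unlist(pat_sets))
  for (nm in names(pat_sets)) {
    miss <- setdiff(all_pat, pat_sets[[nm]])
    if (length(miss) > 0 && length(pat_sets[[nm]]) > 0) {
      warning("patient(s) without ", nm, " data treated as unmutated: ",
              paste(miss, collapse = ", "))
    }
  }
  out <- list()

  if (!is.null(snvs) && nrow(snvs) > 0) {
    coding <- snvs[tolower(snvs$impact) %in% c("moderate", "high"), ]
    if (nrow(coding) > 0) {
      snv_iv <- tibble::tibble(chrom = coding$chrom, start = coding$pos,
                               end = coding$pos + 1)
      hits <- overlap_pairs(snv_iv, genes)
      out$snv <- tibble::tibble(
        patient = coding$patient[hits$x_idx],
        gene_id = genes$gene_id[hits$y_idx],
        flag = "coding_snv", sv_id = NA_character_
      )
    }
  }

  if (!is.null(cnvs) && nrow(cnvs) > 0) {
    cn <- matrix_long(cnvs, "copy_number")
    bad <- cn[!is.na(cn$copy_number) &
                (cn$copy_number < 2 - cnv_delta |
                   cn$copy_number > 2 + cnv_delta), ]
    out$cnv <- tibble::tibble(
      patient = bad$patient, gene_id = bad$gene_id,
      flag = "cnv_out_of_range", sv_id = NA_character_
    )
  }

  if (!is.null(svs) && nrow(svs) > 0) {
    spans <- sv_spans(svs)
    hits <- overlap_pairs(spans, genes)
    out$sv <- tibble::tibble(
      patient = spans$patient[hits$x_idx],
      gene_id = genes$gene_id[hits$y_idx],
      flag = "coding_sv", sv_id = spans$sv_id[hits$x_idx]
    )
  }

  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(patient = character(), gene_id = character(),
                          flag = character(), sv_id = character())
  }
  dplyr::distinct(dplyr::arrange(res, .data$patient, .data$gene_id, .data$flag))
}

# breakpoint-to-breakpoint spans used for the coding-SV overlap test
sv_spans <- function(svs) {
  intra <- svs[svs$sv_type != "TRA", ]
  tra <- svs[svs$sv_type == "TRA", ]
  dplyr::bind_rows(
    tibble::tibble(sv_id = intra$sv_id, patient = intra$patient,
                   chrom = intra$chrom1, start = intra$pos1, end = intra$pos2),
    tibble::tibble(sv_id = tra$sv_id, patient = tra$patient,
                   chrom = tra$chrom1, start = tra$pos1, end = tra$pos1 + 1),
    tibble::tibble(sv_id = tra$sv_id, patient = tra$patient,
                   chrom = tra$chrom2, start = tra$pos2, end = tra$pos2 + 1)
  )
}
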