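#' Simulation configuration
#'
#' Returns the default configuration of the synthetic-cohort generator.
#' The genome is a sparse regulatory landscape: domains tile each
#' chromosome; every domain carries one gene; a minority of domains
#' carry regulatory elements, a biased subset of which are "active"
#' (enhancer co-located with an h3k27ac and a DNase peak of high
#' signal). A configurable fraction of boundary-disrupting SVs is
#' planted as pathogenic: the SV is constructed so that a target gene
#' gains an active enhancer across a boundary, and the target gene's
#' expression in that patient is shifted by `effect_size` standard
#' deviations.
#'
#' @param ... overrides of the default fields.
#' @return named list of simulation parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chromosomes = 4,
    chrom_length = 1e6,
    n_domains = 25,            # per chromosome
    gene_length = 2000,
    enhancer_length = 1000,
    eqtl_length = 200,
    se_length = 5000,
    element_domain_fraction = 0.6,   # domains carrying elements
    enhancers_per_domain = 2,
    se_domain_fraction = 0.1,
    co_location_bias = 0.3,    # P(enhancer gets h3k27ac + DNase peaks)
    active_signal_range = c(5, 10),
    background_signal_range = c(0.5, 3),
    n_background_peaks = 15,   # per peak kind and chromosome
    chromhmm_tile = 5000,
    n_patients = 40,
    svs_per_type = c(DEL = 5, DUP = 5, INV = 5, TRA = 5),
    planted_fraction = 0.3,
    effect_size = 4,
    noise_sd = 1,
    baseline_range = c(6, 12),
    snvs_per_patient = 2,
    cnv_outliers_per_patient = 2,
    seed = 1
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

runif_int <- function(n, lo, hi) {
  # integer positions in [lo, hi], inclusive; requires lo <= hi
  lo + floor(runif(n) * (hi - lo + 1))
}

#' Simulate the reference genome bundle
#'
#' Generates domains, genes, regulatory elements and annotation tracks
#' according to [sim_config()]. Deterministic under `config$seed`.
#'
#' @param config list from [sim_config()].
#' @return list with `domains`, `genes`, `eqtl`, `enhancer`,
#'   `super_enhancer`, `tracks` (named list of peak/chromHMM tibbles)
#'   and `active_enhancers` (subset of `enhancer` rows with a
#'   `domain_idx` column).
#' @export
simulate_reference <- function(config = sim_config()) {
  cfg <- config
  dom_w <- floor(cfg$chrom_length / cfg$n_domains)
  if (dom_w < 10 * cfg$gene_length) {
    stop("infeasible packing: domains too small for the configured genes")
  }
  with_seed(child_seed(cfg$seed, 1), {
    chroms <- as.character(seq_len(cfg$n_chromosomes))
    domains <- purrr::map(chroms, function(ch) {
      tibble::tibble(chrom = ch,
                     start = (seq_len(cfg$n_domains) - 1) * dom_w,
                     end = seq_len(cfg$n_domains) * dom_w)
    }) |> dplyr::bind_rows()
    domains$domain_idx <- seq_len(nrow(domains))

    # one gene per domain, in the left half away from the edges
    g_lo <- domains$start + round(0.15 * dom_w)
    g_hi <- domains$start + round(0.45 * dom_w) - cfg$gene_length
    g_start <- runif_int(nrow(domains), g_lo, g_hi)
    genes <- tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(nrow(domains))),
      chrom = domains$chrom,
      start = g_start, end = g_start + cfg$gene_length,
      strand = sample(c("+", "-"), nrow(domains), replace = TRUE),
      domain_idx = domains$domain_idx
    )

    # elements live in the right half of a minority of domains
    n_el_dom <- max(1, round(cfg$element_domain_fraction * nrow(domains)))
    el_dom <- sort(safe_sample(seq_len(nrow(domains)), n_el_dom))
    el_pos <- function(dom_rows, len) {
      lo <- domains$start[dom_rows] + round(0.5 * dom_w)
      hi <- domains$start[dom_rows] + round(0.85 * dom_w) - len
      s <- runif_int(length(dom_rows), lo, hi)
      tibble::tibble(chrom = domains$chrom[dom_rows], start = s,
                     end = s + len, domain_idx = dom_rows)
    }
    enh_dom_rows <- rep(el_dom, cfg$enhancers_per_domain)
    enhancer <- el_pos(enh_dom_rows, cfg$enhancer_length)
    # eQTLs tag their domain's enhancer (placed alongside it), so that
    # a hijacked active enhancer carries a coherent eQTL signal
    eq_start <- pmax(domains$start[enh_dom_rows] + 1,
                     enhancer$start + runif_int(nrow(enhancer), -400, 400))
    eqtl <- tibble::tibble(chrom = enhancer$chrom, start = eq_start,
                           end = eq_start + cfg$eqtl_length,
                           domain_idx = enh_dom_rows)
    eqtl$p <- runif(nrow(eqtl), 0, 0.1)
    n_se_dom <- max(1, round(cfg$se_domain_fraction * nrow(domains)))
    super_enhancer <- el_pos(sort(safe_sample(el_dom, min(n_se_dom, length(el_dom)))),
                             cfg$se_length)

    active <- runif(nrow(enhancer)) < cfg$co_location_bias
    sig <- function(n, range) runif(n, range[1], range[2])
    h3k27ac <- tibble::tibble(
      chrom = enhancer$chrom[active],
      start = enhancer$start[active] - 100,
      end = enhancer$end[active] + 100,
      signal = sig(sum(active), cfg$active_signal_range)
    )
    dnase <- dplyr::mutate(h3k27ac, signal = sig(sum(active),
                                                 cfg$active_signal_range))
    # active eQTLs share the hot domains so planted gains look coherent
    eqtl_active <- eqtl$domain_idx %in% enhancer$domain_idx[active]

    bg_peaks <- function() {
      purrr::map(chroms, function(ch) {
        s <- runif_int(cfg$n_background_peaks, 0,
                       cfg$chrom_length - 2000)
        tibble::tibble(chrom = ch, start = s, end = s + runif_int(
          cfg$n_background_peaks, 500, 2000),
          signal = sig(cfg$n_background_peaks, cfg$background_signal_range))
      }) |> dplyr::bind_rows()
    }
    tracks <- list(
      h3k4me3 = bg_peaks(), h3k27me3 = bg_peaks(), h3k4me1 = bg_peaks(),
      rnapol2 = bg_peaks(), ctcf = bg_peaks(), tfbs = bg_peaks(),
      cpg = bg_peaks(),
      h3k27ac = dplyr::bind_rows(h3k27ac, bg_peaks()),
      dnase = dplyr::bind_rows(dnase, bg_peaks())
    )
    states <- names(CHROMHMM_STATE_MAP)
    n_tiles <- floor(cfg$chrom_length / cfg$chromhmm_tile)
    tracks$chromhmm <- purrr::map(chroms, function(ch) {
      tibble::tibble(
        chrom = ch,
        start = (seq_len(n_tiles) - 1) * cfg$chromhmm_tile,
        end = seq_len(n_tiles) * cfg$chromhmm_tile,
        state = sample(states, n_tiles, replace = TRUE)
      )
    }) |> dplyr::bind_rows()
    tracks <- purrr::imap(tracks, function(t, nm) {
      set_track_kind(dplyr::arrange(t, .data$chrom, .data$start),
                     if (nm == "ctcf") "ctcf" else nm)
    })

    list(
      domains = set_track_kind(domains, "tad"),
      genes = genes,
      eqtl = set_track_kind(dplyr::mutate(eqtl, active = eqtl_active), "eqtl"),
      enhancer = set_track_kind(dplyr::mutate(enhancer, active = active),
                                "enhancer"),
      super_enhancer = set_track_kind(super_enhancer, "super_enhancer"),
      tracks = tracks,
      active_enhancers = dplyr::mutate(enhancer[active, , drop = FALSE])
    )
  })
}

# candidate planted layouts: an active enhancer with a gene in the
# left-adjacent domain on the same chromosome (intra-chromosomal SVs),
# or any gene on another chromosome (translocations)
planting_sites <- function(genome) {
  enh <- genome$active_enhancers
  doms <- genome$domains
  genes <- genome$genes
  site_row <- function(i, gene, gene_dom) {
    d <- enh$domain_idx[i]
    tibble::tibble(enh_idx = i, gene_dom_idx = doms$domain_idx[gene_dom],
                   enh_dom_idx = d, gene_id = gene$gene_id,
                   gene_chrom = gene$chrom, gene_end = gene$end,
                   gene_start = gene$start,
                   gene_dom_start = doms$start[gene_dom],
                   gene_dom_end = doms$end[gene_dom],
                   enh_chrom = enh$chrom[i], enh_start = enh$start[i],
                   enh_end = enh$end[i],
                   enh_dom_start = doms$start[doms$domain_idx == d],
                   enh_dom_end = doms$end[doms$domain_idx == d])
  }
  sites <- purrr::map(seq_len(nrow(enh)), function(i) {
    d <- enh$domain_idx[i]
    # intra-chromosomal: target gene in the left-adjacent domain
    left <- which(doms$domain_idx == d - 1 & doms$chrom == enh$chrom[i])
    intra <- NULL
    if (length(left) == 1) {
      gene <- genes[genes$domain_idx == doms$domain_idx[left], ]
      if (nrow(gene) > 0) intra <- site_row(i, gene[1, ], left)
    }
    # translocations: target genes on other chromosomes
    cross_genes <- genes[genes$chrom != enh$chrom[i], ]
    cross <- purrr::map(seq_len(nrow(cross_genes)), function(j) {
      g <- cross_genes[j, ]
      site_row(i, g, which(doms$domain_idx == g$domain_idx))
    })
    dplyr::bind_rows(c(list(intra), cross))
  })
  dplyr::bind_rows(sites)
}

plant_sv <- function(type, site, genome, sv_id, patient) {
  # geometry chosen so the target gene gains the active enhancer
  with_pos <- function(chrom1, pos1, orient1, chrom2, pos2, orient2) {
    tibble::tibble(sv_id = sv_id, patient = patient, sv_type = type,
                   chrom1 = chrom1, pos1 = pos1, orient1 = orient1,
                   chrom2 = chrom2, pos2 = pos2, orient2 = orient2)
  }
  switch(type,
    DEL = with_pos(site$gene_chrom,
                   runif_int(1, site$gene_end + 1, site$gene_dom_end - 1), "+",
                   site$enh_chrom,
                   runif_int(1, site$enh_dom_start + 1, site$enh_start - 1), "-"),
    DUP = with_pos(site$gene_chrom,
                   runif_int(1, site$gene_dom_start + 1, site$gene_start - 1), "-",
                   site$enh_chrom,
                   runif_int(1, site$enh_end + 1, site$enh_dom_end - 1), "+"),
    INV = with_pos(site$gene_chrom,
                   runif_int(1, site$gene_end + 1, site$gene_dom_end - 1), NA,
                   site$enh_chrom,
                   runif_int(1, site$enh_end + 1, site$enh_dom_end - 1), NA),
    TRA = with_pos(site$gene_chrom,
                   runif_int(1, site$gene_end + 1, site$gene_dom_end - 1), "+",
                   site$enh_chrom,
                   runif_int(1, site$enh_dom_start + 1, site$enh_start - 1), "-")
  )
}

#' Simulate a patient cohort over a reference genome
#'
#' Draws per-patient SVs with the configured type mix; a
#' `planted_fraction` of them are planted pathogenic events whose
#' target gene gains an active enhancer and whose expression in the
#' focal patient is shifted by `effect_size * noise_sd`. Also emits
#' random coding SNVs and copy-number outliers (never on a patient's
#' planted genes), the expression matrix, and the planted truth table.
#'
#' @param genome bundle from [simulate_reference()].
#' @param config list from [sim_config()] (use the same one).
#' @return list with `svs`, `snvs`, `cnvs`, `expression`, `truth`.
#' @export
simulate_cohort <- function(genome, config = sim_config()) {
  cfg <- config
  sites <- planting_sites(genome)
  if (nrow(sites) == 0) stop("no feasible planting sites in this genome")
  doms <- genome$domains
  genes <- genome$genes
  patients <- sprintf("p%02d", seq_len(cfg$n_patients))

  # elements carrying the active-enhancer signature, as the pipeline
  # sees them (p-filtered, binned): any element overlapping a strong
  # h3k27ac window drives the expression response when rewired
  prep <- prepare_tracks(genome)
  strong <- prep$tracks$h3k27ac[
    !is.na(prep$tracks$h3k27ac$signal) &
      prep$tracks$h3k27ac$signal >= cfg$active_signal_range[1], ,
    drop = FALSE]
  active_el <- prep$elements[overlaps_any(prep$elements, strong), ,
                             drop = FALSE]

  with_seed(child_seed(cfg$seed, 2), {
    all_svs <- list(); all_truth <- list(); all_snvs <- list()
    cnv_cols <- list()
    baseline <- runif(nrow(genes), cfg$baseline_range[1],
                      cfg$baseline_range[2])
    expr <- matrix(rnorm(nrow(genes) * length(patients),
                         mean = baseline, sd = cfg$noise_sd),
                   nrow = nrow(genes), dimnames = list(genes$gene_id,
                                                       patients))

    for (p in patients) {
      k <- 0
      planted_genes <- character()
      svs <- list(); truth <- list()
      used_doms <- integer()  # one SV per domain and patient: somatic
                              # SVs are sparse at genome scale, and
                              # disjoint placement keeps each gene's
                              # expression attributable to one SV
      for (type in names(cfg$svs_per_type)) {
        for (j in seq_len(cfg$svs_per_type[[type]])) {
          k <- k + 1
          sv_id <- sprintf("%s_sv%02d", p, k)
          sv <- NULL
          if (runif(1) < cfg$planted_fraction) {
            ok <- if (type == "TRA") sites$gene_chrom != sites$enh_chrom
                  else sites$gene_chrom == sites$enh_chrom
            ok <- ok & !sites$gene_id %in% planted_genes &
              !sites$gene_dom_idx %in% used_doms &
              !sites$enh_dom_idx %in% used_doms
            if (any(ok)) {
              site <- sites[safe_sample(which(ok), 1), ]
              sv <- plant_sv(type, site, genome, sv_id, p)
              truth[[k]] <- tibble::tibble(patient = p, sv_id = sv_id,
                                           gene_id = site$gene_id)
              planted_genes <- c(planted_genes, site$gene_id)
              used_doms <- c(used_doms, site$gene_dom_idx,
                             site$enh_dom_idx)
            }
          }
          if (is.null(sv)) {
            sv <- random_sv(type, doms, used_doms, sv_id, p)
            used_doms <- c(used_doms, attr(sv, "doms"))
            attr(sv, "doms") <- NULL
          }
          svs[[k]] <- sv
        }
      }
      svs <- dplyr::bind_rows(svs)
      all_svs[[p]] <- svs
      all_truth[[p]] <- dplyr::bind_rows(truth)

      # expression response: a gene gaining an active-enhancer element
      # through a boundary-disrupting SV is up-shifted, a gene losing
      # one is down-shifted (planted targets gain one by construction)
      resp <- suppressMessages(
        build_sv_gene_pairs(svs, doms, genes, active_el, NULL)
      )
      if (nrow(resp) > 0) {
        gained <- unique(resp$gene_id[resp$direction == "gain"])
        lost <- setdiff(unique(resp$gene_id[resp$direction == "loss"]),
                        gained)
        expr[gained, p] <- expr[gained, p] +
          cfg$effect_size * cfg$noise_sd
        expr[lost, p] <- expr[lost, p] - cfg$effect_size * cfg$noise_sd
      }

      # coding SNVs and CNV outliers on non-planted genes
      eligible <- setdiff(genes$gene_id, planted_genes)
      hit <- safe_sample(eligible, min(cfg$snvs_per_patient, length(eligible)))
      gi <- match(hit, genes$gene_id)
      all_snvs[[p]] <- tibble::tibble(
        patient = p, chrom = genes$chrom[gi],
        pos = runif_int(length(gi), genes$start[gi], genes$end[gi] - 1),
        impact = sample(c("high", "moderate", "low"), length(gi),
                        replace = TRUE)
      )
      cn <- rep(2, nrow(genes))
      out_genes <- safe_sample(eligible, min(cfg$cnv_outliers_per_patient,
                                             length(eligible)))
      cn[match(out_genes, genes$gene_id)] <-
        sample(c(1.2, 1.5, 3, 3.5), length(out_genes), replace = TRUE)
      cnv_cols[[p]] <- cn
    }

    cnvs <- dplyr::bind_cols(
      tibble::tibble(gene_id = genes$gene_id),
      tibble::as_tibble(cnv_cols)
    )
    expression <- dplyr::bind_cols(
      tibble::tibble(gene_id = genes$gene_id),
      tibble::as_tibble(as.data.frame(expr))
    )
    truth <- dplyr::bind_rows(all_truth)
    if (nrow(truth) == 0) {
      truth <- tibble::tibble(patient = character(), sv_id = character(),
                              gene_id = character())
    }
    list(
      svs = dplyr::bind_rows(all_svs),
      snvs = dplyr::bind_rows(all_snvs),
      cnvs = cnvs,
      expression = expression,
      truth = truth
    )
  })
}

# a non-planted SV; intra-chromosomal SVs span a random adjacent domain
# pair, translocations join two random domains on different chromosomes;
# domains already used by the patient's earlier SVs are avoided
random_sv <- function(type, doms, used_doms, sv_id, patient) {
  if (type == "TRA") {
      free <- setdiff(seq_len(nrow(doms)), used_doms)
      if (length(free) < 2) free <- seq_len(nrow(doms))
      d1 <- safe_sample(free, 1)
      other <- setdiff(free[doms$chrom[free] != doms$chrom[d1]], d1)
      if (length(other) == 0) other <- setdiff(free, d1)
      d2 <- safe_sample(other, 1)
      sv <- tibble::tibble(
        sv_id = sv_id, patient = patient, sv_type = "TRA",
        chrom1 = doms$chrom[d1],
        pos1 = runif_int(1, doms$start[d1] + 1, doms$end[d1] - 1),
        orient1 = sample(c("+", "-"), 1),
        chrom2 = doms$chrom[d2],
        pos2 = runif_int(1, doms$start[d2] + 1, doms$end[d2] - 1),
        orient2 = sample(c("+", "-"), 1)
    )
  } else {
    # adjacent domain pair on a random chromosome
    cand <- which(doms$chrom == sample(unique(doms$chrom), 1))
    cand <- cand[-length(cand)]
    open_pairs <- cand[!(cand %in% used_doms) & !((cand + 1) %in% used_doms)]
    if (length(open_pairs) == 0) open_pairs <- cand
    d1 <- safe_sample(open_pairs, 1)
    d2 <- d1 + 1
    sv <- tibble::tibble(
      sv_id = sv_id, patient = patient, sv_type = type,
      chrom1 = doms$chrom[d1],
      pos1 = runif_int(1, doms$start[d1] + 1, doms$end[d1] - 1),
      orient1 = dplyr::case_match(type, "DEL" ~ "+", "DUP" ~ "-",
                                  .default = NA),
      chrom2 = doms$chrom[d2],
      pos2 = runif_int(1, doms$start[d2] + 1, doms$end[d2] - 1),
      orient2 = dplyr::case_match(type, "DEL" ~ "-", "DUP" ~ "+",
                                  .default = NA)
    )
  }
  attr(sv, "doms") <- c(d1, d2)
  sv
}

#' Write the genome bundle as BED files
#'
#' @param genome bundle from [simulate_reference()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(genome$domains[, c("chrom", "start", "end")],
            file.path(dir, "tads.bed"))
  gene_bed <- tibble::tibble(chrom = genome$genes$chrom,
                             start = genome$genes$start,
                             end = genome$genes$end,
                             name = genome$genes$gene_id,
                             signal = NA_real_)
  readr::write_lines(sprintf("%s\t%d\t%d\t%s\t0\t%s", gene_bed$chrom,
                             as.integer(gene_bed$start),
                             as.integer(gene_bed$end), gene_bed$name,
                             genome$genes$strand),
                     file.path(dir, "genes.bed"))
  write_bed(genome$eqtl[, c("chrom", "start", "end", "p")],
            file.path(dir, "eqtls.bed"))
  write_bed(genome$enhancer[, c("chrom", "start", "end")],
            file.path(dir, "enhancers.bed"))
  write_bed(genome$super_enhancer[, c("chrom", "start", "end")],
            file.path(dir, "super_enhancers.bed"))
  for (nm in names(genome$tracks)) {
    write_bed(genome$tracks[[nm]], file.path(dir, paste0(nm, ".bed")))
  }
  invisible(dir)
}

#' Write the cohort as standard-format files
#'
#' SVs in the TSV dialect, SNVs as one VCF per patient (IMPACT INFO
#' token), copy numbers and expression as gene-by-patient TSVs, and the
#' planted truth table.
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "snv"), recursive = TRUE, showWarnings = FALSE)
  write_sv_tsv(cohort$svs, file.path(dir, "svs.tsv"))
  for (p in unique(cohort$snvs$patient)) {
    write_snv_vcf(cohort$snvs[cohort$snvs$patient == p, ],
                  file.path(dir, "snv", paste0(p, ".vcf")))
  }
  readr::write_tsv(cohort$cnvs, file.path(dir, "cnv.tsv"))
  readr::write_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
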