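#' Derivative-domain rewiring of SV-gene regulatory contacts
#'
#' For each boundary-disrupting SV the derivative chromosome around the
#' breakpoints is modeled as an ordered list of retained / duplicated /
#' reflected source segments. Domain structure on the derivative is
#' reconstructed by mapping the original domains through the segments:
#' a domain boundary survives only where the two flanking basepairs are
#' still source-adjacent in the derivative, while novel junctions fuse
#' the flanking domains. A gene gains a regulatory element when the two
#' share a derivative domain but shared none before the SV, and loses it
#' in the converse case. Gains and losses are computed for the two
#' domains containing the SV endpoints.
#'
#' @name rewiring
NULL

# index of the domain containing base `base` (0-based) on `chrom`, or NA
dom_of_base <- function(chrom, base, domains) {
  hit <- which(norm_chrom(domains$chrom) == norm_chrom(chrom) &
                 domains$start <= base & base < domains$end)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

# Derivative segment layout for one SV, or NULL when the SV does not
# disrupt a boundary (both breakpoints inside domains is required).
# Segments: src_chrom, src_start, src_end, strand (+1 forward, -1
# reflected), dst_start (cumulative derivative coordinate).
sv_geometry <- function(sv, domains) {
  if (sv$sv_type %in% c("DEL", "DUP", "INV")) {
    d1 <- dom_of_base(sv$chrom1, sv$pos1, domains)
    d2 <- dom_of_base(sv$chrom1, sv$pos2 - 1, domains)
    if (is.na(d1) || is.na(d2) || d1 == d2) return(NULL)
    w0 <- domains$start[d1]
    w1 <- domains$end[d2]
    ch <- norm_chrom(sv$chrom1)
    segs <- switch(sv$sv_type,
      DEL = list(c(w0, sv$pos1, 1), c(sv$pos2, w1, 1)),
      DUP = list(c(w0, sv$pos2, 1), c(sv$pos1, sv$pos2, 1), c(sv$pos2, w1, 1)),
      INV = list(c(w0, sv$pos1, 1), c(sv$pos1, sv$pos2, -1), c(sv$pos2, w1, 1))
    )
    segs <- purrr::map(segs, ~ tibble::tibble(
      src_chrom = ch, src_start = .x[1], src_end = .x[2], strand = .x[3]))
  } else {
    base1 <- if (sv$orient1 == "+") sv$pos1 - 1 else sv$pos1
    base2 <- if (sv$orient2 == "+") sv$pos2 - 1 else sv$pos2
    d1 <- dom_of_base(sv$chrom1, base1, domains)
    d2 <- dom_of_base(sv$chrom2, base2, domains)
    if (is.na(d1) || is.na(d2)) return(NULL)
    ret <- function(chrom, pos, orient, dom) {
      if (orient == "+") c(domains$start[dom], pos) else c(pos, domains$end[dom])
    }
    r1 <- ret(sv$chrom1, sv$pos1, sv$orient1, d1)
    r2 <- ret(sv$chrom2, sv$pos2, sv$orient2, d2)
    seg1 <- tibble::tibble(src_chrom = norm_chrom(sv$chrom1),
                           src_start = r1[1], src_end = r1[2], strand = 1)
    seg2 <- tibble::tibble(src_chrom = norm_chrom(sv$chrom2),
                           src_start = r2[1], src_end = r2[2], strand = 1)
    # head ends at its breakpoint, tail starts at its breakpoint;
    # a retained-left piece used as tail (or retained-right as head) is
    # reflected so the junction sits between them
    key <- paste0(sv$orient1, sv$orient2)
    segs <- switch(key,
      "+-" = list(seg1, seg2),
      "++" = list(seg1, dplyr::mutate(seg2, strand = -1)),
      "-+" = list(seg2, seg1),
      "--" = list(dplyr::mutate(seg2, strand = -1), seg1)
    )
  }
  segs <- dplyr::bind_rows(segs)
  segs <- segs[segs$src_end > segs$src_start, , drop = FALSE]
  if (nrow(segs) == 0) return(NULL)
  len <- segs$src_end - segs$src_start
  segs$dst_start <- cumsum(c(0, len[-length(len)]))
  window <- if (sv$sv_type == "TRA") sort(unique(c(d1, d2))) else d1:d2
  list(segments = segs, endpoint_domains = sort(unique(c(d1, d2))),
       window_domains = window)
}

#' Select SVs that disrupt a domain boundary
#'
#' Keeps SVs whose breakpoints both fall inside (>= 1 bp overlap) a
#' domain and whose span or junction crosses at least one boundary:
#' intra-chromosomal SVs must start and end in different domains;
#' translocation junctions are always novel. SVs with a breakpoint
#' outside all domains, and intra-domain SVs, are excluded.
#'
#' @param svs SV tibble (see [sv_calls]).
#' @param domains domain track tibble (TADs or CTCF-loop domains).
#' @return the selected subset of `svs`.
#' @export
select_boundary_disrupting_svs <- function(svs, domains) {
  domains <- dplyr::arrange(domains, .data$chrom, .data$start)
  keep <- vapply(seq_len(nrow(svs)), function(i) {
    !is.null(sv_geometry(svs[i, ], domains))
  }, logical(1))
  if (any(!keep)) {
    message(sum(!keep), " SV(s) excluded: breakpoint outside domains or ",
            "no boundary crossed")
  }
  svs[keep, , drop = FALSE]
}

# map features (chrom/start/end tibble) through the segment list;
# features split by segment edges map to several derivative pieces
map_features <- function(feat, segments) {
  if (nrow(feat) == 0) {
    return(tibble::tibble(feat_idx = integer(), dst_start = double(),
                          dst_end = double()))
  }
  fc <- norm_chrom(feat$chrom)
  out <- purrr::map(seq_len(nrow(segments)), function(si) {
    s <- segments[si, ]
    a <- pmax(feat$start, s$src_start)
    b <- pmin(feat$end, s$src_end)
    sel <- which(fc == s$src_chrom & a < b)
    if (length(sel) == 0) return(NULL)
    a <- a[sel]; b <- b[sel]
    if (s$strand == 1) {
      tibble::tibble(feat_idx = sel,
                     dst_start = s$dst_start + (a - s$src_start),
                     dst_end = s$dst_start + (b - s$src_start))
    } else {
      tibble::tibble(feat_idx = sel,
                     dst_start = s$dst_start + (s$src_end - b),
                     dst_end = s$dst_start + (s$src_end - a))
    }
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(feat_idx = integer(), dst_start = double(),
                          dst_end = double())
  }
  out
}

# Reconstruct domain intervals on the derivative chromosome. Domain
# coverage is mapped piecewise; adjacent pieces merge unless they are
# source-adjacent across a preserved boundary (split) or separated by a
# non-domain region (split). Novel junctions fuse.
derivative_domains <- function(segments, domains) {
  dc <- norm_chrom(domains$chrom)
  pieces <- purrr::map(seq_len(nrow(segments)), function(si) {
    s <- segments[si, ]
    a <- pmax(domains$start, s$src_start)
    b <- pmin(domains$end, s$src_end)
    sel <- which(dc == s$src_chrom & a < b)
    if (length(sel) == 0) return(NULL)
    a <- a[sel]; b <- b[sel]
    if (s$strand == 1) {
      ds <- s$dst_start + (a - s$src_start)
      de <- s$dst_start + (b - s$src_start)
    } else {
      ds <- s$dst_start + (s$src_end - b)
      de <- s$dst_start + (s$src_end - a)
    }
    tibble::tibble(dom_id = sel, src_a = a, src_b = b,
                   strand = s$strand, chrom = s$src_chrom,
                   dst_start = ds, dst_end = de)
  })
  pieces <- dplyr::bind_rows(pieces)
  if (nrow(pieces) == 0) {
    return(tibble::tibble(der_dom = integer(), start = double(),
                          end = double()))
  }
  pieces <- dplyr::arrange(pieces, .data$dst_start)
  der <- integer(nrow(pieces))
  cur <- 1L
  der[1] <- cur
  for (i in seq_len(nrow(pieces))[-1]) {
    prev <- pieces[i - 1, ]
    p <- pieces[i, ]
    new_dom <- if (p$dst_start > prev$dst_end) {
      TRUE  # non-domain (boundary) region between
    } else {
      src_adj <- prev$chrom == p$chrom && prev$strand == p$strand &&
        ((p$strand == 1 && p$src_a == prev$src_b) ||
           (p$strand == -1 && p$src_b == prev$src_a))
      src_adj && p$dom_id != prev$dom_id  # preserved boundary
    }
    if (new_dom) cur <- cur + 1L
    der[i] <- cur
  }
  pieces$der <- der
  pieces |>
    dplyr::group_by(der_dom = .data$der) |>
    dplyr::summarise(start = min(.data$dst_start), end = max(.data$dst_end),
                     .groups = "drop")
}

# contact pairs (g_idx, e_idx) given per-feature domain memberships
contact_pairs <- function(g_mem, e_mem) {
  dplyr::distinct(dplyr::inner_join(
    g_mem, e_mem, by = "dom", relationship = "many-to-many"
  )[, c("g_idx", "e_idx")])
}

#' Gains and losses of regulatory elements caused by one SV
#'
#' Core rewiring operator: compares which (gene, element) pairs share a
#' domain before and after the SV, on the derivative-domain
#' reconstruction described in [rewiring]. Genes and elements overlapped
#' by a deletion's deleted span are not counted; genes absent from the
#' modeled derivative (e.g. on the lost side of a translocation) emit no
#' records.
#'
#' @param sv a single-row SV tibble.
#' @param domains domain track tibble.
#' @param genes gene tibble ([read_genes()]).
#' @param elements element tibble with `chrom`, `start`, `end`,
#'   `element_kind` in `eqtl`, `enhancer`, `super_enhancer`
#'   (see [element_table()]).
#' @return tibble of gain/loss records: `gene_id`, `element_kind`,
#'   `chrom`, `start`, `end`, `direction` (`"gain"`/`"loss"`).
#' @export
rewire_sv <- function(sv, domains, genes, elements) {
  stopifnot(nrow(sv) == 1)
  domains <- dplyr::arrange(domains, .data$chrom, .data$start)
  geom <- sv_geometry(sv, domains)
  if (is.null(geom)) return(empty_records())
  epd <- domains[geom$endpoint_domains, , drop = FALSE]

  g <- genes[overlaps_any(genes, epd), , drop = FALSE]
  e <- elements[overlaps_any(elements, epd), , drop = FALSE]
  if (sv$sv_type == "DEL") {
    span <- tibble::tibble(chrom = sv$chrom1, start = sv$pos1, end = sv$pos2)
    g <- g[!overlaps_any(g, span), , drop = FALSE]
    e <- e[!overlaps_any(e, span), , drop = FALSE]
  }
  if (nrow(g) == 0 || nrow(e) == 0) return(empty_records())

  gb <- overlap_pairs(g, domains) |> dplyr::rename(g_idx = "x_idx", dom = "y_idx")
  eb <- overlap_pairs(e, domains) |> dplyr::rename(e_idx = "x_idx", dom = "y_idx")
  before <- contact_pairs(gb, eb)

  dd <- derivative_domains(geom$segments, domains)
  dd_iv <- tibble::tibble(chrom = "der", start = dd$start, end = dd$end)
  gm <- map_features(g, geom$segments)
  em <- map_features(e, geom$segments)
  gm_iv <- tibble::tibble(chrom = "der", start = gm$dst_start, end = gm$dst_end)
  em_iv <- tibble::tibble(chrom = "der", start = em$dst_start, end = em$dst_end)
  ga <- overlap_pairs(gm_iv, dd_iv) |>
    dplyr::transmute(g_idx = gm$feat_idx[.data$x_idx], dom = .data$y_idx)
  ea <- overlap_pairs(em_iv, dd_iv) |>
    dplyr::transmute(e_idx = em$feat_idx[.data$x_idx], dom = .data$y_idx)
  after <- contact_pairs(ga, ea)
  # contacts through domains outside the modeled window are untouched
  out_contacts <- contact_pairs(
    gb[!gb$dom %in% geom$window_domains, , drop = FALSE],
    eb[!eb$dom %in% geom$window_domains, , drop = FALSE]
  )
  after <- dplyr::distinct(dplyr::bind_rows(after, out_contacts))

  gains <- dplyr::anti_join(after, before, by = c("g_idx", "e_idx"))
  losses <- dplyr::anti_join(before, after, by = c("g_idx", "e_idx"))
  losses <- losses[losses$g_idx %in% unique(gm$feat_idx), , drop = FALSE]

  rec <- function(idx, direction) {
    if (nrow(idx) == 0) return(NULL)
    tibble::tibble(
      gene_id = g$gene_id[idx$g_idx],
      element_kind = e$element_kind[idx$e_idx],
      chrom = norm_chrom(e$chrom[idx$e_idx]),
      start = e$start[idx$e_idx],
      end = e$end[idx$e_idx],
      direction = direction
    )
  }
  out <- dplyr::bind_rows(rec(gains, "gain"), rec(losses, "loss"))
  if (is.null(out) || nrow(out) == 0) return(empty_records())
  dplyr::arrange(out, .data$gene_id, .data$chrom, .data$start,
                 .data$element_kind, .data$direction)
}

empty_records <- function() {
  tibble::tibble(gene_id = character(), element_kind = character(),
                 chrom = character(), start = double(), end = double(),
                 direction = character())
}

check_type <- function(sv, type) {
  if (sv$sv_type != type) stop("expected a ", type, " record")
  invisible(sv)
}

#' @rdname rewire_sv
#' @export
rewire_deletion <- function(sv, domains, genes, elements) {
  rewire_sv(check_type(sv, "DEL"), domains, genes, elements)
}

#' @rdname rewire_sv
#' @export
rewire_duplication <- function(sv, domains, genes, elements) {
  rewire_sv(check_type(sv, "DUP"), domains, genes, elements)
}

#' @rdname rewire_sv
#' @export
rewire_inversion <- function(sv, domains, genes, elements) {
  rewire_sv(check_type(sv, "INV"), domains, genes, elements)
}

#' @rdname rewire_sv
#' @export
rewire_translocation <- function(sv, domains, genes, elements) {
  if (is.na(sv$orient1) || is.na(sv$orient2)) {
    stop("translocation requires both orientations")
  }
  rewire_sv(check_type(sv, "TRA"), domains, genes, elements)
}

#' Combine element tracks into one element table
#'
#' @param eqtl,enhancer,super_enhancer track tibbles (eQTLs already
#'   p-filtered and binned as desired).
#' @return tibble `chrom`, `start`, `end`, `element_kind`.
#' @export
element_table <- function(eqtl = NULL, enhancer = NULL, super_enhancer = NULL) {
  pick <- function(track, kind) {
    if (is.null(track) || nrow(track) == 0) return(NULL)
    tibble::tibble(chrom = norm_chrom(track$chrom), start = track$start,
                   end = track$end, element_kind = kind)
  }
  out <- dplyr::bind_rows(pick(eqtl, "eqtl"), pick(enhancer, "enhancer"),
                          pick(super_enhancer, "super_enhancer"))
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = double(),
                          end = double(), element_kind = character())
  }
  out
}

#' Build filtered SV-gene pairs with their gain/loss records
#'
#' Runs the rewiring operator over all boundary-disrupting SVs and
#' removes pairs whose gene carries a coding mutation in the same
#' patient (coding SNV, out-of-range copy number, or overlap by an SV
#' span). The disrupting SV itself is exempt from the coding-SV overlap
#' filter when it is a duplication or inversion, which may overlap the
#' affected gene.
#'
#' @param svs SV tibble.
#' @param domains domain track tibble.
#' @param genes gene tibble.
#' @param elements element tibble ([element_table()]).
#' @param mutation_index flag tibble from [build_mutation_index()], or
#'   NULL to skip mutation filtering.
#' @return record tibble: one row per gain/loss record with `pair_id`,
#'   `patient`, `sv_id`, `sv_type`, `gene_id`, `element_kind`, `chrom`,
#'   `start`, `end`, `direction`, sorted by (patient, sv_id, gene_id).
#' @export
build_sv_gene_pairs <- function(svs, domains, genes, elements,
                                mutation_index = NULL) {
  svs <- select_boundary_disrupting_svs(svs, domains)
  recs <- purrr::map(seq_len(nrow(svs)), function(i) {
    r <- rewire_sv(svs[i, ], domains, genes, elements)
    if (nrow(r) == 0) return(NULL)
    dplyr::mutate(r,
                  patient = svs$patient[i], sv_id = svs$sv_id[i],
                  sv_type = svs$sv_type[i], .before = 1)
  })
  recs <- dplyr::bind_rows(recs)
  if (nrow(recs) == 0) return(empty_pair_records())

  if (!is.null(mutation_index) && nrow(mutation_index) > 0) {
    flags <- dplyr::inner_join(
      dplyr::distinct(recs[, c("patient", "sv_id", "sv_type", "gene_id")]),
      mutation_index, by = c("patient", "gene_id"),
      relationship = "many-to-many"
    )
    # self-overlap exemption for non-coding duplications and inversions
    flags <- flags[!(flags$flag == "coding_sv" &
                       !is.na(flags$sv_id.y) &
                       flags$sv_id.y == flags$sv_id.x &
                       flags$sv_type %in% c("DUP", "INV")), , drop = FALSE]
    drop <- dplyr::distinct(tibble::tibble(
      patient = flags$patient, sv_id = flags$sv_id.x, gene_id = flags$gene_id
    ))
    recs <- dplyr::anti_join(recs, drop, by = c("patient", "sv_id", "gene_id"))
  }
  if (nrow(recs) == 0) return(empty_pair_records())
  recs$pair_id <- paste(recs$patient, recs$sv_id, recs$gene_id, sep = "|")
  dplyr::arrange(
    recs[, c("pair_id", "patient", "sv_id", "sv_type", "gene_id",
             "element_kind", "chrom", "start", "end", "direction")],
    .data$patient, .data$sv_id, .data$gene_id,
    .data$chrom, .data$start, .data$element_kind, .data$direction
  )
}

empty_pair_records <- function() {
  tibble::tibble(pair_id = character(), patient = character(),
                 sv_id = character(), sv_type = character(),
                 gene_id = character(), element_kind = character(),
                 chrom = character(), start = double(), end = double(),
                 direction = character())
}

#' Export SV-gene pairs as a summary TSV
#'
#' One row per pair: patient, sv_id, sv_type, gene_id, n_gains,
#' n_losses and the semicolon-joined element list
#' (`kind:chrom:start-end:direction`).
#'
#' @param pairs record tibble from [build_sv_gene_pairs()].
#' @param path output path.
#' @return the summary tibble, invisibly.
#' @export
export_pairs <- function(pairs, path) {
  summary <- pairs |>
    dplyr::group_by(.data$pair_id, .data$patient, .data$sv_id,
                    .data$sv_type, .data$gene_id) |>
    dplyr::summarise(
      n_gains = sum(.data$direction == "gain"),
      n_losses = sum(.data$direction == "loss"),
      elements = paste(sprintf("%s:%s:%d-%d:%s", .data$element_kind,
                               .data$chrom, as.integer(.data$start),
                               as.integer(.data$end), .data$direction),
                       collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$patient, .data$sv_id, .data$gene_id)
  readr::write_tsv(summary[, -1], path)
  invisible(summary)
}
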