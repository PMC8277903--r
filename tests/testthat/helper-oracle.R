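# Independent per-basepair enumerator for SV rewiring, used as the
# oracle against the package's interval-arithmetic implementation.
#
# The derivative chromosome is materialized base by base as (source
# chromosome, source position) records. Derivative domains are maximal
# runs of domain-covered bases, split where two bases that were adjacent
# in the source (in reading order) straddle an original domain boundary,
# and fused across novel junctions. A gene and an element are "in
# contact" when any basepair of one shares a (derivative) domain with
# any basepair of the other. Gains/losses are contact set differences,
# restricted to genes/elements overlapping the SV's endpoint domains.

# per-base vectors for one chromosome window
bp_range <- function(a, b) if (b > a) seq(a, b - 1) else integer(0)

# derivative base list for an SV, given domains; returns list of
# tibbles with src_chrom, src_pos in derivative order, or NULL when the
# SV is not boundary-disrupting under the same endpoint rules
oracle_derivative <- function(sv, domains) {
  dom_at <- function(ch, p) {
    h <- which(domains$chrom == ch & domains$start <= p & p < domains$end)
    if (length(h) == 0) NA_integer_ else h[1]
  }
  if (sv$sv_type %in% c("DEL", "DUP", "INV")) {
    d1 <- dom_at(sv$chrom1, sv$pos1)
    d2 <- dom_at(sv$chrom1, sv$pos2 - 1)
    if (is.na(d1) || is.na(d2) || d1 == d2) return(NULL)
    w0 <- domains$start[d1]; w1 <- domains$end[d2]
    ch <- sv$chrom1
    src <- switch(sv$sv_type,
      DEL = c(bp_range(w0, sv$pos1), bp_range(sv$pos2, w1)),
      DUP = c(bp_range(w0, sv$pos2), bp_range(sv$pos1, sv$pos2),
              bp_range(sv$pos2, w1)),
      INV = c(bp_range(w0, sv$pos1), rev(bp_range(sv$pos1, sv$pos2)),
              bp_range(sv$pos2, w1))
    )
    list(src_chrom = rep(ch, length(src)), src_pos = src,
         endpoint = c(d1, d2), window = d1:d2)
  } else {
    base1 <- if (sv$orient1 == "+") sv$pos1 - 1 else sv$pos1
    base2 <- if (sv$orient2 == "+") sv$pos2 - 1 else sv$pos2
    d1 <- dom_at(sv$chrom1, base1)
    d2 <- dom_at(sv$chrom2, base2)
    if (is.na(d1) || is.na(d2)) return(NULL)
    ret1 <- if (sv$orient1 == "+") bp_range(domains$start[d1], sv$pos1) else
      bp_range(sv$pos1, domains$end[d1])
    ret2 <- if (sv$orient2 == "+") bp_range(domains$start[d2], sv$pos2) else
      bp_range(sv$pos2, domains$end[d2])
    key <- paste0(sv$orient1, sv$orient2)
    parts <- switch(key,
      "+-" = list(c1 = ret1, c2 = ret2),
      "++" = list(c1 = ret1, c2 = rev(ret2)),
      "-+" = list(c1 = ret2, c2 = ret1),
      "--" = list(c1 = rev(ret2), c2 = ret1)
    )
    chrom_of <- switch(key,
      "+-" = c(sv$chrom1, sv$chrom2), "++" = c(sv$chrom1, sv$chrom2),
      "-+" = c(sv$chrom2, sv$chrom1), "--" = c(sv$chrom2, sv$chrom1)
    )
    list(src_chrom = c(rep(chrom_of[1], length(parts$c1)),
                       rep(chrom_of[2], length(parts$c2))),
         src_pos = c(parts$c1, parts$c2),
         endpoint = sort(unique(c(d1, d2))), window = sort(unique(c(d1, d2))))
  }
}

# assign derivative domain ids to the base list
oracle_domains <- function(der, domains) {
  n <- length(der$src_pos)
  dom <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    h <- which(domains$chrom == der$src_chrom[i] &
                 domains$start <= der$src_pos[i] &
                 der$src_pos[i] < domains$end)
    if (length(h) > 0) dom[i] <- h[1]
  }
  der_dom <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (is.na(dom[i])) next
    new_run <- i == 1 || is.na(dom[i - 1])
    if (!new_run) {
      adj <- der$src_chrom[i] == der$src_chrom[i - 1] &&
        abs(der$src_pos[i] - der$src_pos[i - 1]) == 1
      if (adj && dom[i] != dom[i - 1]) new_run <- TRUE  # preserved boundary
    }
    if (new_run) cur <- cur + 1L
    der_dom[i] <- cur
  }
  der_dom
}

# brute-force gain/loss records for one SV
oracle_rewire <- function(sv, domains, genes, elements) {
  empty <- tibble::tibble(gene_id = character(), element_kind = character(),
                          chrom = character(), start = double(),
                          end = double(), direction = character())
  der <- oracle_derivative(sv, domains)
  if (is.null(der)) return(empty)
  der_dom <- oracle_domains(der, domains)
  epd <- domains[der$endpoint, , drop = FALSE]

  feat_bases <- function(f) bp_range(f$start, f$end)
  overlaps_epd <- function(f) {
    any(epd$chrom == f$chrom & f$start < epd$end & epd$start < f$end)
  }
  in_del_span <- function(f) {
    sv$sv_type == "DEL" && f$chrom == sv$chrom1 &&
      f$start < sv$pos2 && sv$pos1 < f$end
  }
  orig_doms <- function(f) {
    unique(which(domains$chrom == f$chrom & f$start < domains$end &
                   domains$start < f$end))
  }
  der_doms_of <- function(f) {
    hit <- der$src_chrom == f$chrom & der$src_pos >= f$start &
      der$src_pos < f$end
    unique(der_dom[hit & !is.na(der_dom)])
  }

  recs <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    if (!overlaps_epd(g) || in_del_span(g)) next
    g_before <- orig_doms(g)
    g_after <- der_doms_of(g)
    g_exists <- any(der$src_chrom == g$chrom & der$src_pos >= g$start &
                      der$src_pos < g$end)
    for (ei in seq_len(nrow(elements))) {
      e <- elements[ei, ]
      if (!overlaps_epd(e) || in_del_span(e)) next
      e_before <- orig_doms(e)
      before <- length(intersect(g_before, e_before)) > 0
      # unchanged contacts through domains outside the modeled window
      shared_out <- setdiff(intersect(g_before, e_before), der$window)
      after <- length(intersect(g_after, der_doms_of(e))) > 0 ||
        length(shared_out) > 0
      if (after && !before) {
        recs[[length(recs) + 1]] <- tibble::tibble(
          gene_id = g$gene_id, element_kind = e$element_kind,
          chrom = e$chrom, start = e$start, end = e$end,
          direction = "gain")
      } else if (before && !after && g_exists) {
        recs[[length(recs) + 1]] <- tibble::tibble(
          gene_id = g$gene_id, element_kind = e$element_kind,
          chrom = e$chrom, start = e$start, end = e$end,
          direction = "loss")
      }
    }
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, gene_id, chrom, start, element_kind, direction)
}

# random two-chromosome toy genome for oracle-equivalence tests:
# chromosomes <= 5 kb each, <= 6 domains (gaps between some domains)
random_toy_genome <- function() {
  one_chrom <- function(ch) {
    n_dom <- sample(2:6, 1)
    dom_w <- sample(4:8, 1) * 100
    gap <- sample(c(0, 0, 50), 1)  # occasionally leave boundary gaps
    starts <- (seq_len(n_dom) - 1) * (dom_w + gap)
    tibble::tibble(chrom = ch, start = starts, end = starts + dom_w)
  }
  domains <- dplyr::bind_rows(one_chrom("1"), one_chrom("2"))
  lens <- sapply(c("1", "2"), function(ch) {
    max(domains$end[domains$chrom == ch])
  })
  place <- function(n, len_range, prefix, kinds = FALSE) {
    ch <- sample(c("1", "2"), n, replace = TRUE)
    s <- vapply(ch, function(c) sample(0:(lens[[c]] - 130), 1), 0)
    w <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    out <- tibble::tibble(chrom = ch, start = s, end = s + w)
    if (kinds) {
      out$element_kind <- sample(c("eqtl", "enhancer", "super_enhancer"),
                                 n, replace = TRUE)
    } else {
      out <- dplyr::mutate(out,
                           gene_id = sprintf("%s%d", prefix, dplyr::row_number()),
                           .before = 1)
    }
    out
  }
  list(domains = domains,
       genes = place(sample(2:5, 1), c(50, 120), "g"),
       elements = place(sample(2:6, 1), c(30, 80), "e", kinds = TRUE),
       lens = lens)
}

random_toy_sv <- function(g, type = NULL) {
  type <- type %||% sample(c("DEL", "DUP", "INV", "TRA"), 1)
  if (type == "TRA") {
    tibble::tibble(sv_id = "sv", patient = "p", sv_type = "TRA",
                   chrom1 = "1", pos1 = sample(1:(g$lens[["1"]] - 2), 1),
                   orient1 = sample(c("+", "-"), 1),
                   chrom2 = "2", pos2 = sample(1:(g$lens[["2"]] - 2), 1),
                   orient2 = sample(c("+", "-"), 1))
  } else {
    ch <- sample(c("1", "2"), 1)
    L <- g$lens[[ch]]
    p <- sort(sample(1:(L - 1), 2))
    while (p[2] - p[1] < 2) p <- sort(sample(1:(L - 1), 2))
    tibble::tibble(sv_id = "sv", patient = "p", sv_type = type,
                   chrom1 = ch, pos1 = p[1],
                   orient1 = dplyr::case_match(type, "DEL" ~ "+",
                                               "DUP" ~ "-", .default = NA),
                   chrom2 = ch, pos2 = p[2],
                   orient2 = dplyr::case_match(type, "DEL" ~ "-",
                                               "DUP" ~ "+", .default = NA))
  }
}

# SV whose span is guaranteed to cross a boundary: breakpoints drawn
# from two distinct domains of one chromosome (or two chromosomes for
# translocations)
boundary_biased_sv <- function(g, type = NULL) {
  type <- type %||% sample(c("DEL", "DUP", "INV", "TRA"), 1)
  if (type == "TRA") return(random_toy_sv(g, "TRA"))
  ch <- sample(c("1", "2"), 1)
  doms <- g$domains[g$domains$chrom == ch, ]
  picks <- sort(safe_sample_local(seq_len(nrow(doms)), 2))
  p1 <- sample(doms$start[picks[1]]:(doms$end[picks[1]] - 1), 1)
  p2 <- sample((doms$start[picks[2]] + 1):doms$end[picks[2]], 1)
  tibble::tibble(sv_id = "sv", patient = "p", sv_type = type,
                 chrom1 = ch, pos1 = p1,
                 orient1 = dplyr::case_match(type, "DEL" ~ "+",
                                             "DUP" ~ "-", .default = NA),
                 chrom2 = ch, pos2 = p2,
                 orient2 = dplyr::case_match(type, "DEL" ~ "-",
                                             "DUP" ~ "+", .default = NA))
}

safe_sample_local <- function(x, n) x[sample.int(length(x), n)]
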