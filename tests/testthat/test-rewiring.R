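test_that("boundary-disruption selection keeps only domain-crossing SVs", {
  g <- two_domain_genome()
  crossing <- make_sv("DEL", 90, 110)
  inside <- make_sv("DEL", 10, 20, sv_id = "sv2")
  tra <- make_sv("TRA", 50, 50, chrom2 = "2", orient1 = "+", orient2 = "-",
                 sv_id = "sv3")
  doms <- dplyr::bind_rows(g$domains,
                           tibble::tibble(chrom = "2", start = 0, end = 100))
  sel <- suppressMessages(
    select_boundary_disrupting_svs(dplyr::bind_rows(crossing, inside, tra),
                                   doms))
  expect_setequal(sel$sv_id, c("sv1", "sv3"))

  outside <- make_sv("DEL", 250, 400, sv_id = "sv4")
  expect_equal(nrow(suppressMessages(
    select_boundary_disrupting_svs(outside, doms))), 0)
})

test_that("deletions bridge flanking genes and elements, excluding the span", {
  g <- two_domain_genome()
  sv <- make_sv("DEL", 90, 110)
  recs <- rewire_deletion(sv, g$domains, g$genes, g$elements)
  expect_equal(recs$direction, "gain")
  expect_equal(recs$gene_id, "g1")
  expect_equal(recs$start, 150)

  # element overlapped by the deleted span is not counted
  el <- dplyr::bind_rows(g$elements,
                         tibble::tibble(chrom = "1", start = 95, end = 105,
                                        element_kind = "enhancer"))
  recs <- rewire_deletion(sv, g$domains, g$genes, el)
  expect_false(any(recs$start == 95))

  # gene inside the span emits nothing
  gin <- tibble::tibble(gene_id = "gdel", chrom = "1", start = 95, end = 99,
                        strand = "+")
  recs <- rewire_deletion(sv, g$domains, gin, g$elements)
  expect_equal(nrow(recs), 0)
})

test_that("duplications pair genes and elements inside the new domain", {
  g <- two_domain_genome()
  sv <- make_sv("DUP", 50, 150)
  genes <- tibble::tibble(gene_id = c("gin", "gout"), chrom = "1",
                          start = c(60, 10), end = c(70, 20), strand = "+")
  el <- tibble::tibble(chrom = "1", start = 110, end = 120,
                       element_kind = "enhancer")
  recs <- rewire_duplication(sv, g$domains, genes, el)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$gene_id, "gin")     # overlapped by the DUP
  expect_equal(recs$direction, "gain")  # gout, not overlapped, gets nothing

  # a 1 bp overlap with the duplication counts
  el_edge <- tibble::tibble(chrom = "1", start = 149, end = 200,
                            element_kind = "enhancer")
  recs <- rewire_duplication(sv, g$domains, genes, el_edge)
  expect_true("gin" %in% recs$gene_id[recs$direction == "gain"])
})

test_that("inversions move elements between the flanking domains", {
  g <- two_domain_genome()
  sv <- make_sv("INV", 50, 150)
  # enhancer inside the inversion reflects into the left domain
  el <- tibble::tibble(chrom = "1", start = 110, end = 140,
                       element_kind = "enhancer")
  recs <- rewire_inversion(sv, g$domains, g$genes, el)
  expect_equal(recs$direction, "gain")
  expect_equal(recs$gene_id, "g1")

  # gene inside the inversion exits the left domain and loses its elements
  gin <- tibble::tibble(gene_id = "gin", chrom = "1", start = 60, end = 70,
                        strand = "+")
  el2 <- tibble::tibble(chrom = "1", start = 10, end = 40,
                        element_kind = "enhancer")
  recs <- rewire_inversion(sv, g$domains, gin, el2)
  expect_equal(recs$direction, "loss")

  # fully intra-domain inversion: nothing (not boundary-disrupting)
  recs <- rewire_inversion(make_sv("INV", 10, 40), g$domains, g$genes,
                           g$elements)
  expect_equal(nrow(recs), 0)
})

test_that("translocations join the retained segments per orientation", {
  doms <- tibble::tibble(chrom = c("1", "2"), start = 0, end = 100)
  genes <- tibble::tibble(gene_id = "g1", chrom = "1", start = 10, end = 20,
                          strand = "+")
  sv <- make_sv("TRA", 50, 40, chrom2 = "2", orient1 = "+", orient2 = "-")
  el <- tibble::tibble(chrom = c("2", "1"), start = c(60, 60),
                       end = c(70, 70), element_kind = c("enhancer", "eqtl"))
  recs <- rewire_translocation(sv, doms, genes, el)
  gained <- recs[recs$direction == "gain", ]
  lost <- recs[recs$direction == "loss", ]
  expect_equal(gained$chrom, "2")   # retained chr2 side introduced
  expect_equal(lost$chrom, "1")     # lost chr1 segment removed

  # symmetry: a gene on the retained chr2 side gains the chr1 element
  genes2 <- tibble::tibble(gene_id = "g2", chrom = "2", start = 80, end = 90,
                           strand = "+")
  el2 <- tibble::tibble(chrom = "1", start = 30, end = 40,
                        element_kind = "eqtl")
  recs <- rewire_translocation(sv, doms, genes2, el2)
  expect_equal(recs$direction, "gain")

  expect_error(
    rewire_translocation(make_sv("TRA", 50, 40, chrom2 = "2"), doms,
                         genes, el),
    "orientation")
})

test_that("each rewiring operator matches the per-basepair enumerator", {
  set.seed(101)
  nonempty <- 0
  for (i in 1:40) {
    g <- random_toy_genome()
    for (sv in list(random_toy_sv(g), boundary_biased_sv(g))) {
      imp <- rewire_sv(sv, g$domains, g$genes, g$elements)
      ora <- oracle_rewire(sv, g$domains, g$genes, g$elements)
      expect_equal(as.data.frame(imp), as.data.frame(ora))
      if (nrow(ora) > 0) nonempty <- nonempty + 1
    }
  }
  expect_gt(nonempty, 10)
})

test_that("deletions produce only gains and records are never duplicated", {
  set.seed(202)
  for (i in 1:40) {
    g <- random_toy_genome()
    sv <- random_toy_sv(g, type = sample(c("DEL", "DUP", "INV", "TRA"), 1))
    recs <- rewire_sv(sv, g$domains, g$genes, g$elements)
    if (sv$sv_type == "DEL") expect_true(all(recs$direction == "gain"))
    # an element is never both gained and lost for the same gene
    key <- paste(recs$gene_id, recs$chrom, recs$start, recs$end)
    expect_true(all(table(key) <= 1) ||
                  !any(duplicated(recs[, c("gene_id", "chrom", "start",
                                           "end")])))
  }
})

test_that("a single whole-chromosome domain yields no pairs", {
  doms <- tibble::tibble(chrom = c("1", "2"), start = 0, end = 10000)
  genes <- tibble::tibble(gene_id = "g1", chrom = "1", start = 100, end = 200,
                          strand = "+")
  el <- tibble::tibble(chrom = "1", start = 5000, end = 5100,
                       element_kind = "enhancer")
  for (type in c("DEL", "DUP", "INV")) {
    sv <- make_sv(type, 1000, 9000)
    expect_equal(nrow(rewire_sv(sv, doms, genes, el)), 0)
  }
})

test_that("rewiring output is invariant to input ordering", {
  set.seed(303)
  for (i in 1:10) {
    g <- random_toy_genome()
    sv <- random_toy_sv(g)
    a <- rewire_sv(sv, g$domains, g$genes, g$elements)
    perm_g <- g$genes[sample(nrow(g$genes)), ]
    perm_e <- g$elements[sample(nrow(g$elements)), ]
    b <- rewire_sv(sv, g$domains, perm_g, perm_e)
    expect_equal(as.data.frame(a), as.data.frame(b))
  }
})

test_that("pair construction applies the coding filters and exceptions", {
  doms <- tibble::tibble(chrom = "1", start = c(0, 100, 200),
                         end = c(100, 200, 300))
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "1",
                          start = c(10, 110), end = c(20, 120),
                          strand = "+")
  el <- tibble::tibble(chrom = "1", start = c(150, 50, 250),
                       end = c(160, 60, 260), element_kind = "enhancer")
  svs <- dplyr::bind_rows(
    make_sv("DEL", 90, 110, sv_id = "svA"),
    make_sv("INV", 105, 250, sv_id = "svB")  # overlaps gB itself
  )
  # no mutations: both genes pair
  pairs <- suppressMessages(build_sv_gene_pairs(svs, doms, genes, el, NULL))
  expect_true(all(c("gA", "gB") %in% pairs$gene_id))
  # the INV overlapping its own gene is kept (DUP/INV exception)
  expect_true("gB" %in% pairs$gene_id[pairs$sv_id == "svB"])

  # a high-impact coding SNV in gA drops gA's pairs
  idx <- build_mutation_index(
    tibble::tibble(patient = "p1", chrom = "1", pos = 15, impact = "high"),
    NULL, svs, genes)
  pairs <- suppressMessages(build_sv_gene_pairs(svs, doms, genes, el, idx))
  expect_false("gA" %in% pairs$gene_id)
  expect_true("gB" %in% pairs$gene_id[pairs$sv_id == "svB"])

  # copy number 2.5 drops the gene
  idx2 <- build_mutation_index(NULL, tibble::tibble(gene_id = "gB", p1 = 2.5),
                               svs, genes)
  pairs <- suppressMessages(build_sv_gene_pairs(svs, doms, genes, el, idx2))
  expect_false("gB" %in% pairs$gene_id)
})

test_that("pair export writes the documented summary columns", {
  g <- two_domain_genome()
  svs <- make_sv("DEL", 90, 110)
  pairs <- suppressMessages(
    build_sv_gene_pairs(svs, g$domains, g$genes, g$elements, NULL))
  path <- withr::local_tempfile(fileext = ".tsv")
  summary <- export_pairs(pairs, path)
  expect_equal(summary$n_gains, 1)
  expect_equal(summary$n_losses, 0)
  expect_match(summary$elements, "enhancer:1:150-160:gain")
  expect_equal(names(readr::read_tsv(path, show_col_types = FALSE)),
               c("patient", "sv_id", "sv_type", "gene_id", "n_gains",
                 "n_losses", "elements"))
})
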