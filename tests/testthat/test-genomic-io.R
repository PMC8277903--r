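test_that("read_bed keeps BED coordinates and maps the score column", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr2\t50\t60"), path)
  track <- read_bed(path, kind = "enhancer")
  expect_equal(track$chrom, c("1", "2"))  # chr prefix stripped
  expect_equal(track$start, c(0, 50))
  expect_equal(track$end, c(100, 60))

  writeLines("1\t10\t20\tpeak1\t37.5", path)
  track <- read_bed(path, kind = "h3k27ac")
  expect_equal(track$signal, 37.5)
  expect_equal(track$name, "peak1")

  writeLines("1\t10\t20\te1\t0.04", path)
  eqtl <- read_bed(path, kind = "eqtl")
  expect_equal(eqtl$p, 0.04)
  expect_null(eqtl[["signal"]])
})

test_that("read_bed rejects malformed input, naming the line", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t0\t100", "1\t100\t100"), path)
  expect_error(read_bed(path), "line 2")
  writeLines("1\t5", path)
  expect_error(read_bed(path), "line 1")
  writeLines("1\tx\t100", path)
  expect_error(read_bed(path), "line 1")
})

test_that("canonical BED round-trips byte-identically", {
  path <- withr::local_tempfile(fileext = ".bed")
  out <- withr::local_tempfile(fileext = ".bed")
  for (content in list(c("1\t0\t100", "2\t5\t250000"),
                       c("1\t0\t100\tA\t1.5", "1\t200\t300\tB\t37.5"))) {
    writeLines(content, path)
    write_bed(read_bed(path, kind = "h3k4me3"), out)
    expect_identical(readLines(out), content)
  }
})

test_that("overlap queries agree with a brute-force scan", {
  brute <- function(x, y) {
    hits <- list()
    for (i in seq_len(nrow(x))) for (j in seq_len(nrow(y))) {
      if (norm_chrom(x$chrom[i]) == norm_chrom(y$chrom[j]) &&
          x$start[i] < y$end[j] && y$start[j] < x$end[i]) {
        hits[[length(hits) + 1]] <- c(i, j)
      }
    }
    m <- do.call(rbind, hits)
    if (is.null(m)) tibble::tibble(x_idx = integer(), y_idx = integer())
    else tibble::tibble(x_idx = m[, 1], y_idx = m[, 2]) |>
      dplyr::arrange(x_idx, y_idx)
  }
  set.seed(7)
  for (rep in 1:5) {
    rand_track <- function(n) {
      s <- sample(0:500, n, replace = TRUE)
      tibble::tibble(chrom = sample(c("1", "2", "chr1"), n, replace = TRUE),
                     start = s, end = s + sample(1:40, n, replace = TRUE))
    }
    x <- rand_track(sample(50:500, 1))
    y <- rand_track(sample(50:500, 1))
    expect_equal(overlap_pairs(x, y), brute(x, y))
  }
})

test_that("SV TSV dialect reads back identically", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p1\tDEL\tchr1\t100\t+\tchr1\t200\t-", path)
  svs <- read_sv_calls(path, "tsv")
  expect_equal(svs$sv_type, "DEL")
  expect_equal(svs$pos1, 100)
  expect_equal(svs$pos2, 200)
  expect_equal(svs$chrom1, "1")

  svs2 <- tibble::tibble(
    sv_id = c("a", "b"), patient = "p1", sv_type = c("DEL", "TRA"),
    chrom1 = "1", pos1 = c(100, 5000), orient1 = c("+", "-"),
    chrom2 = c("1", "2"), pos2 = c(200, 700), orient2 = c("-", "+")
  )
  out <- withr::local_tempfile(fileext = ".tsv")
  write_sv_tsv(svs2, out)
  expect_equal(as.data.frame(read_sv_calls(out, "tsv")),
               as.data.frame(svs2))
})

test_that("VCF SV dialect converts coordinates and pairs BND mates", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"m\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t101\tdel1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=200",
    "chr1\t51\tbnd_a\tN\tN[chr2:41[\t.\tPASS\tSVTYPE=BND;MATEID=bnd_b",
    "chr2\t41\tbnd_b\tN\t]chr1:51]N\t.\tPASS\tSVTYPE=BND;MATEID=bnd_a"
  ), path)
  svs <- read_sv_calls(path, "vcf_bnd", patient = "p1")
  del <- svs[svs$sv_type == "DEL", ]
  expect_equal(del$pos1, 100)  # VCF POS 101 -> 0-based 100
  expect_equal(del$pos2, 200)
  tra <- svs[svs$sv_type == "TRA", ]
  expect_equal(nrow(tra), 1)   # two BND lines -> one junction
  expect_equal(tra$orient1, "+")
  expect_equal(tra$orient2, "-")
  expect_equal(tra$pos1, 50)
})

test_that("SV VCF writer round-trips through the reader", {
  svs <- tibble::tibble(
    sv_id = c("s1", "s2", "s3"), patient = "p7",
    sv_type = c("DUP", "INV", "TRA"),
    chrom1 = c("1", "2", "1"), pos1 = c(100, 500, 321),
    orient1 = c("-", NA, "-"),
    chrom2 = c("1", "2", "3"), pos2 = c(900, 800, 77),
    orient2 = c("+", NA, "+")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(svs, path)
  back <- read_sv_calls(path, "vcf_bnd", patient = "p7")
  back$sv_id <- sub("_a$", "", back$sv_id)
  expect_equal(as.data.frame(back[order(back$sv_id), ]),
               as.data.frame(svs), ignore_attr = TRUE)
})

test_that("unmatched BND mates are dropped with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t51\tlone\tN\tN[2:41[\t.\tPASS\tSVTYPE=BND"
  ), path)
  expect_warning(svs <- read_sv_calls(path, "vcf_bnd", patient = "p"),
                 "unmatched")
  expect_equal(nrow(svs), 0)
})

test_that("expression matrix reader handles shape, gaps and duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tp1\tp2\tp3", "gA\t1\t2\t3", "gB\t4\t\t6"), path)
  ex <- read_expression(path)
  expect_equal(dim(ex), c(2, 4))
  expect_true(is.na(ex$p2[2]))

  writeLines(c("gene_id\tp1", "gA\t1", "gA\t2"), path)
  expect_error(read_expression(path), "duplicate gene id")
})

test_that("mutation index applies the copy-number and impact rules", {
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "1",
                          start = c(0, 1000), end = c(500, 1500),
                          strand = "+")
  cnvs <- tibble::tibble(gene_id = c("gA", "gB"),
                         p1 = c(2.0, 1.69), p2 = c(2.3, 2.31))
  snvs <- tibble::tibble(patient = c("p1", "p1"), chrom = "1",
                         pos = c(100, 1100), impact = c("low", "high"))
  svs <- make_sv("DEL", 1400, 2000, patient = "p2")
  idx <- suppressWarnings(build_mutation_index(snvs, cnvs, svs, genes))

  cn <- idx[idx$flag == "cnv_out_of_range", ]
  # 2.0 and 2.3 are inside [1.7, 2.3]; 1.69 and 2.31 are outside
  expect_equal(nrow(cn), 2)
  expect_setequal(paste(cn$patient, cn$gene_id),
                  c("p1 gB", "p2 gB"))

  sn <- idx[idx$flag == "coding_snv", ]
  # the low-impact SNV in gA does not flag; the high-impact one does
  expect_equal(paste(sn$patient, sn$gene_id), "p1 gB")

  sv <- idx[idx$flag == "coding_sv", ]
  expect_equal(paste(sv$patient, sv$gene_id), "p2 gB")
  expect_equal(sv$sv_id, "sv1")
})

test_that("patients missing from one input are treated as unmutated", {
  genes <- tibble::tibble(gene_id = "gA", chrom = "1", start = 0, end = 500,
                          strand = "+")
  snvs <- tibble::tibble(patient = "p1", chrom = "1", pos = 10,
                         impact = "high")
  svs <- make_sv("DEL", 10, 600, patient = "p2")
  w <- capture_warnings(idx <- build_mutation_index(snvs, NULL, svs, genes))
  expect_match(w, "unmutated", all = FALSE)
  expect_setequal(idx$flag, c("coding_snv", "coding_sv"))
})
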