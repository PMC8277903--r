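#' Structural variant calls
#'
#' Somatic SVs are tibbles with columns `sv_id`, `patient`, `sv_type`
#' (`DEL`, `DUP`, `INV`, `TRA`), `chrom1`, `pos1`, `orient1`, `chrom2`,
#' `pos2`, `orient2`. Positions are 0-based breakpoint coordinates;
#' intra-chromosomal SVs satisfy `pos1 < pos2` and span `[pos1, pos2)`.
#' An orientation of `"+"` means the retained segment lies to the left of
#' the breakpoint (it ends at the breakpoint); `"-"` means it lies to the
#' right.
#'
#' @name sv_calls
NULL

SV_TYPES <- c("DEL", "DUP", "INV", "TRA")

sv_tsv_cols <- c("patient", "sv_type", "chrom1", "pos1", "orient1",
                 "chrom2", "pos2", "orient2")

validate_svs <- function(svs) {
  intra <- svs$sv_type %in% c("DEL", "DUP", "INV")
  if (any(intra & norm_chrom(svs$chrom1) != norm_chrom(svs$chrom2))) {
    stop("DEL/DUP/INV must have chrom1 == chrom2")
  }
  if (any(intra & !(svs$pos1 < svs$pos2))) {
    stop("DEL/DUP/INV must have pos1 < pos2")
  }
  tra <- svs$sv_type == "TRA"
  if (any(tra & (is.na(svs$orient1) | is.na(svs$orient2)))) {
    stop("TRA records require both orientations")
  }
  svs
}

#' Read structural variant calls
#'
#' Two dialects are supported. `"tsv"` is a plain table with columns
#' `patient, sv_type, chrom1, pos1, orient1, chrom2, pos2, orient2`
#' (0-based positions, optional header and optional leading `sv_id`
#' column). `"vcf_bnd"` is VCF 4.2: `SVTYPE=DEL/DUP/INV` records with an
#' `END` INFO field, and translocations as breakend (BND) mate pairs,
#' which are merged into single `TRA` records; 1-based VCF positions are
#' converted to the internal 0-based convention on read.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf_bnd"`.
#' @param patient patient identifier for VCF input (one VCF per patient);
#'   defaults to the file name without extension.
#' @return an SV tibble (see [sv_calls]).
#' @export
read_sv_calls <- function(path, dialect = c("tsv", "vcf_bnd"), patient = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") read_sv_tsv(path) else read_sv_vcf(path, patient)
}

read_sv_tsv <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  has_header <- length(lines) > 0 && grepl("^(sv_id\t)?patient\t", lines[1])
  if (has_header) lines <- lines[-1]
  if (length(lines) == 0) return(empty_svs())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  has_id <- all(nf == 9)
  if (!all(nf == if (has_id) 9 else 8)) {
    stop("malformed SV TSV line ", which(nf != nf[1])[1], " in ", path)
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  off <- if (has_id) 1L else 0L
  svs <- tibble::tibble(
    sv_id = if (has_id) get(1) else sprintf("sv%04d", seq_along(fields)),
    patient = get(off + 1),
    sv_type = get(off + 2),
    chrom1 = norm_chrom(get(off + 3)),
    pos1 = as.numeric(get(off + 4)),
    orient1 = dplyr::na_if(dplyr::na_if(get(off + 5), "."), "NA"),
    chrom2 = norm_chrom(get(off + 6)),
    pos2 = as.numeric(get(off + 7)),
    orient2 = dplyr::na_if(dplyr::na_if(get(off + 8), "."), "NA")
  )
  bad <- !svs$sv_type %in% SV_TYPES
  if (any(bad)) {
    message("dropping ", sum(bad), " SV(s) with unknown type")
    svs <- svs[!bad, , drop = FALSE]
  }
  validate_svs(svs)
}

# Bracket notation of a BND ALT encodes which side of each breakpoint is
# retained in the derivative junction:
#   t[p[  local +, mate -     t]p]  local +, mate +
#   ]p]t  local -, mate +     [p[t  local -, mate -
parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec("(\\[|\\])(.+?):([0-9]+)(\\[|\\])", alt,
                               perl = TRUE))[[1]]
  if (length(m) == 0) return(NULL)
  bracket <- m[2]
  local_orient <- if (grepl("^(\\[|\\])", alt, perl = TRUE)) "-" else "+"
  mate_orient <- if (bracket == "]") "+" else "-"
  list(
    mate_chrom = norm_chrom(m[3]),
    mate_pos = as.numeric(m[4]),
    local_orient = local_orient,
    mate_orient = mate_orient
  )
}

read_sv_vcf <- function(path, patient = NULL) {
  if (is.null(patient)) patient <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) return(empty_svs())
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  svtype <- vcfR::extract.info(vcf, element = "SVTYPE")
  endpos <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "END")))
  mateid <- vcfR::extract.info(vcf, element = "MATEID")
  pos <- as.numeric(fix$POS)
  chrom <- norm_chrom(fix$CHROM)

  simple <- which(svtype %in% c("DEL", "DUP", "INV"))
  out <- list()
  if (length(simple) > 0) {
    out$simple <- tibble::tibble(
      sv_id = fix$ID[simple],
      patient = patient,
      sv_type = svtype[simple],
      chrom1 = chrom[simple],
      pos1 = pos[simple] - 1,          # VCF 1-based -> 0-based
      orient1 = dplyr::case_match(svtype[simple],
                                  "DEL" ~ "+", "DUP" ~ "-", "INV" ~ NA),
      chrom2 = chrom[simple],
      pos2 = endpos[simple],           # 1-based inclusive END == half-open end
      orient2 = dplyr::case_match(svtype[simple],
                                  "DEL" ~ "-", "DUP" ~ "+", "INV" ~ NA)
    )
  }

  bnd <- which(svtype == "BND")
  if (length(bnd) > 0) {
    parsed <- purrr::map(fix$ALT[bnd], parse_bnd_alt)
    ok <- !purrr::map_lgl(parsed, is.null)
    if (any(!ok)) warning("dropping ", sum(!ok), " unparseable BND record(s)")
    bnd <- bnd[ok]
    parsed <- parsed[ok]
    used <- rep(FALSE, length(bnd))
    tras <- list()
    for (i in seq_along(bnd)) {
      if (used[i]) next
      pi <- parsed[[i]]
      # prefer MATEID pairing, fall back on reciprocal coordinates
      j <- NA_integer_
      if (!is.na(mateid[bnd[i]])) {
        j <- match(mateid[bnd[i]], fix$ID[bnd])
      }
      if (is.na(j)) {
        cand <- which(!used & seq_along(bnd) != i &
                        chrom[bnd] == pi$mate_chrom &
                        pos[bnd] == pi$mate_pos)
        j <- if (length(cand) > 0) cand[1] else NA_integer_
      }
      if (is.na(j) || used[j]) {
        warning("unmatched BND mate for ", fix$ID[bnd[i]], "; record dropped")
        used[i] <- TRUE
        next
      }
      used[c(i, j)] <- TRUE
      tras[[length(tras) + 1]] <- tibble::tibble(
        sv_id = fix$ID[bnd[i]],
        patient = patient,
        sv_type = "TRA",
        chrom1 = chrom[bnd[i]],
        pos1 = pos[bnd[i]] - 1,
        orient1 = pi$local_orient,
        chrom2 = chrom[bnd[j]],
        pos2 = pos[bnd[j]] - 1,
        orient2 = parsed[[j]]$local_orient
      )
    }
    out$tra <- dplyr::bind_rows(tras)
  }

  unknown <- which(!is.na(svtype) & !svtype %in% c("DEL", "DUP", "INV", "BND"))
  if (length(unknown) > 0) {
    message("dropping ", length(unknown), " SV(s) with unknown SVTYPE")
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_svs())
  validate_svs(res)
}

empty_svs <- function() {
  tibble::tibble(
    sv_id = character(), patient = character(), sv_type = character(),
    chrom1 = character(), pos1 = double(), orient1 = character(),
    chrom2 = character(), pos2 = double(), orient2 = character()
  )
}

#' Write structural variants in the TSV dialect
#'
#' @param svs an SV tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_tsv <- function(svs, path) {
  out <- svs[, c("sv_id", sv_tsv_cols)]
  out$orient1[is.na(out$orient1)] <- "."
  out$orient2[is.na(out$orient2)] <- "."
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write structural variants as a VCF (SVTYPE + BND notation)
#'
#' DEL/DUP/INV are written as symbolic-ALT records with an `END` INFO
#' field; TRA records become two BND mate lines with bracket ALTs and
#' `MATEID`. Coordinates are converted back to 1-based VCF positions.
#'
#' @param svs an SV tibble for a single patient.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character()
  for (i in seq_len(nrow(svs))) {
    s <- svs[i, ]
    if (s$sv_type %in% c("DEL", "DUP", "INV")) {
      body <- c(body, sprintf(
        "%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d",
        s$chrom1, s$pos1 + 1, s$sv_id, s$sv_type, s$sv_type, s$pos2
      ))
    } else {
      ida <- paste0(s$sv_id, "_a")
      idb <- paste0(s$sv_id, "_b")
      alt_for <- function(local_orient, mate_chrom, mate_pos, mate_orient) {
        mate <- sprintf("%s:%d", mate_chrom, mate_pos + 1)
        bra <- if (mate_orient == "+") "]" else "["
        piece <- paste0(bra, mate, bra)
        if (local_orient == "+") paste0("N", piece) else paste0(piece, "N")
      }
      body <- c(body,
        sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\tSVTYPE=BND;MATEID=%s",
                s$chrom1, s$pos1 + 1, ida,
                alt_for(s$orient1, s$chrom2, s$pos2, s$orient2), idb),
        sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\tSVTYPE=BND;MATEID=%s",
                s$chrom2, s$pos2 + 1, idb,
                alt_for(s$orient2, s$chrom1, s$pos1, s$orient1), ida)
      )
    }
  }
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read coding SNV calls from a VCF with an IMPACT INFO token
#'
#' @param path VCF path (one per patient).
#' @param patient patient identifier; defaults to the file name.
#' @return tibble with `patient`, `chrom`, `pos` (0-based), `impact`
#'   (lower-cased, e.g. `"high"`, `"moderate"`, `"low"`).
#' @export
read_snv_calls <- function(path, patient = NULL) {
  if (is.null(patient)) patient <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) {
    return(tibble::tibble(patient = character(), chrom = character(),
                          pos = double(), impact = character()))
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  impact <- vcfR::extract.info(vcf, element = "IMPACT")
  tibble::tibble(
    patient = patient,
    chrom = norm_chrom(fix$CHROM),
    pos = as.numeric(fix$POS) - 1,
    impact = tolower(impact)
  )
}

#' Write coding SNV calls as a VCF with IMPACT annotation
#'
#' @param snvs tibble with `chrom`, `pos` (0-based), `impact`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Predicted impact\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t%s\tN\tA\t.\tPASS\tIMPACT=%s",
                  snvs$chrom, snvs$pos + 1,
                  sprintf("snv%04d", seq_len(nrow(snvs))),
                  toupper(snvs$impact))
  readr::write_lines(c(header, body), path)
  invisible(path)
}
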