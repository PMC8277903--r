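#' Annotation tracks
#'
#' Regulatory annotation is carried as plain tibbles of genomic intervals in
#' 0-based half-open (BED-native) coordinates: columns `chrom`, `start`,
#' `end`, and optionally `name`, `signal` (non-negative peak intensity),
#' `state` (chromHMM state label) or `p` (eQTL association p-value). The
#' track kind is stored in the `"kind"` attribute.
#'
#' @name tracks
NULL

TRACK_KINDS <- c(
  "tad", "ctcf_loop", "eqtl", "enhancer", "super_enhancer",
  "h3k4me3", "h3k27me3", "h3k27ac", "h3k4me1",
  "dnase", "rnapol2", "ctcf", "tfbs", "cpg", "chromhmm", "gene"
)

#' Normalise chromosome names
#'
#' Strips an optional `"chr"` prefix so that chromosome names compare by
#' exact string equality across all inputs.
#'
#' @param x character vector of chromosome names.
#' @return character vector without the `"chr"` prefix.
#' @export
norm_chrom <- function(x) sub("^chr", "", as.character(x))

track_kind <- function(track) attr(track, "kind") %||% NA_character_

set_track_kind <- function(track, kind) {
  attr(track, "kind") <- kind
  track
}

#' Read a BED-like annotation track
#'
#' Reads BED3/BED4/BED5 into an interval tibble. Coordinates are kept
#' exactly as in the file (0-based half-open). The 4th column becomes
#' `name` (for `kind = "chromhmm"` it becomes the `state` label) and the
#' 5th column becomes `signal`, except for `kind = "eqtl"` where it is the
#' association p-value column `p`.
#'
#' @param path path to a tab-separated BED file without header.
#' @param kind track kind, one of `"tad"`, `"ctcf_loop"`, `"eqtl"`,
#'   `"enhancer"`, `"super_enhancer"`, `"h3k4me3"`, `"h3k27me3"`,
#'   `"h3k27ac"`, `"h3k4me1"`, `"dnase"`, `"rnapol2"`, `"ctcf"`, `"tfbs"`,
#'   `"cpg"`, `"chromhmm"`.
#' @return a track tibble (see [tracks]).
#' @export
read_bed <- function(path, kind = "tad") {
  kind <- match.arg(kind, TRACK_KINDS)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble::tibble(
      chrom = character(), start = double(), end = double()
    )
    return(set_track_kind(out, kind))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], " in ", path,
         ": fewer than 3 columns")
  }
  chrom <- norm_chrom(vapply(fields, `[[`, "", 1))
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], " in ", path,
         ": non-numeric coordinates")
  }
  bad <- which(!(start < end) | start < 0)
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], " in ", path,
         ": requires 0 <= start < end")
  }
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (any(nf >= 4)) {
    col4 <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""), NA)
    if (kind == "chromhmm") out$state <- col4 else out$name <- col4
  }
  if (any(nf >= 5)) {
    col5 <- suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, "")
    ))
    if (kind == "eqtl") out$p <- col5 else out$signal <- col5
  }
  if (!is.null(out[["signal"]]) && any(!is.na(out[["signal"]]) & out[["signal"]] < 0)) {
    stop("negative signal values in ", path)
  }
  set_track_kind(out, kind)
}

#' Write a track tibble as BED
#'
#' Inverse of [read_bed()]: columns are written back in BED order
#' (chrom, start, end, name/state, signal/p), omitting optional columns
#' that are absent. Canonical chr-less 3/5-column tracks round-trip
#' byte-identically.
#'
#' @param track a track tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  fmt_num <- function(x) {
    ifelse(x == round(x),
           format(x, scientific = FALSE, trim = TRUE),
           as.character(x))
  }
  cols <- list(track$chrom, fmt_num(track$start), fmt_num(track$end))
  name_col <- track[["state"]] %||% track[["name"]]
  score_col <- track[["p"]] %||% track[["signal"]]
  if (!is.null(score_col) && is.null(name_col)) name_col <- rep(".", nrow(track))
  if (!is.null(name_col)) cols <- c(cols, list(name_col))
  if (!is.null(score_col)) cols <- c(cols, list(as.character(score_col)))
  lines <- do.call(paste, c(cols, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Find overlapping interval pairs between two tibbles
#'
#' Reports every pair of rows sharing at least 1 bp, half-open semantics,
#' matching chromosomes by exact (chr-stripped) name.
#'
#' @param x,y tibbles with `chrom`, `start`, `end`.
#' @return tibble with columns `x_idx`, `y_idx` (row indices into x and y).
#' @export
overlap_pairs <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) {
    return(tibble::tibble(x_idx = integer(), y_idx = integer()))
  }
  xc <- norm_chrom(x$chrom)
  yc <- norm_chrom(y$chrom)
  out <- vector("list", 0)
  for (ch in intersect(unique(xc), unique(yc))) {
    xi <- which(xc == ch)
    yi <- which(yc == ch)
    # half-open [s, e) -> closed 1-based [s + 1, e]
    xr <- IRanges::IRanges(start = x$start[xi] + 1, end = x$end[xi])
    yr <- IRanges::IRanges(start = y$start[yi] + 1, end = y$end[yi])
    hits <- IRanges::findOverlaps(xr, yr, minoverlap = 1L)
    out[[length(out) + 1]] <- tibble::tibble(
      x_idx = xi[S4Vectors::queryHits(hits)],
      y_idx = yi[S4Vectors::subjectHits(hits)]
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(x_idx = integer(), y_idx = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$x_idx, .data$y_idx)
}

#' @rdname overlap_pairs
#' @return `overlaps_any()`: logical vector, one entry per row of `x`.
#' @export
overlaps_any <- function(x, y) {
  hits <- overlap_pairs(x, y)
  seq_len(nrow(x)) %in% hits$x_idx
}

#' Bin a track into fixed-width windows
#'
#' Replaces intervals by the genome-aligned fixed-width bins they touch;
#' a bin's signal is the maximum signal of the intervals contributing to
#' it. Applied to eQTLs, histone marks and TF binding sites to bound the
#' instance count (default 1 kb windows).
#'
#' @param track a track tibble.
#' @param width bin width in bp (default 1000).
#' @return a binned track tibble of the same kind.
#' @export
bin_track <- function(track, width = 1000) {
  stopifnot(width > 0)
  if (nrow(track) == 0) {
    out <- tibble::tibble(chrom = character(), start = double(), end = double(),
                          signal = double())
    return(set_track_kind(out, track_kind(track)))
  }
  sig <- track[["signal"]] %||% rep(NA_real_, nrow(track))
  first_bin <- floor(track$start / width)
  last_bin <- floor((track$end - 1) / width)
  n_bins <- last_bin - first_bin + 1
  expanded <- tibble::tibble(
    chrom = rep(track$chrom, n_bins),
    bin = unlist(purrr::map2(first_bin, last_bin, seq)),
    signal = rep(sig, n_bins)
  )
  out <- expanded |>
    dplyr::group_by(.data$chrom, .data$bin) |>
    dplyr::summarise(
      signal = if (all(is.na(.data$signal))) NA_real_ else
        max(.data$signal, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::transmute(
      chrom = .data$chrom,
      start = .data$bin * width,
      end = (.data$bin + 1) * width,
      signal = .data$signal
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
  set_track_kind(out, track_kind(track))
}

#' Filter eQTLs by association p-value
#'
#' Keeps eQTL records with `p <= p_threshold` (inclusive). Records without
#' a p-value are dropped with a warning.
#'
#' @param track an eQTL track tibble with a `p` column.
#' @param p_threshold retain records with p at or below this value
#'   (default 0.05; the stringent genome-wide setting 5e-8 is also valid).
#' @return filtered track tibble.
#' @export
filter_eqtls <- function(track, p_threshold = 0.05) {
  if (is.null(track[["p"]])) stop("eQTL track has no p-value column")
  missing_p <- is.na(track$p)
  if (any(missing_p)) {
    warning(sum(missing_p), " eQTL record(s) without p-value dropped")
  }
  out <- track[!missing_p & track$p <= p_threshold, , drop = FALSE]
  set_track_kind(out, track_kind(track))
}
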