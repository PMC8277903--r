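# small in-code fixtures shared across test files

two_domain_genome <- function() {
  list(
    domains = tibble::tibble(chrom = "1", start = c(0, 100), end = c(100, 200)),
    genes = tibble::tibble(gene_id = "g1", chrom = "1", start = 10, end = 20,
                           strand = "+"),
    elements = tibble::tibble(chrom = "1", start = 150, end = 160,
                              element_kind = "enhancer")
  )
}

make_sv <- function(type, pos1, pos2, chrom1 = "1", chrom2 = chrom1,
                    orient1 = NA, orient2 = NA, patient = "p1",
                    sv_id = "sv1") {
  if (is.na(orient1) && type %in% c("DEL", "DUP")) {
    orient1 <- if (type == "DEL") "+" else "-"
    orient2 <- if (type == "DEL") "-" else "+"
  }
  tibble::tibble(sv_id = sv_id, patient = patient, sv_type = type,
                 chrom1 = chrom1, pos1 = pos1, orient1 = orient1,
                 chrom2 = chrom2, pos2 = pos2, orient2 = orient2)
}

# tiny deterministic instance tibble: n instances with given feature
# values for a handful of schema columns, zeros elsewhere
toy_instances <- function(pair_ids, ...) {
  over <- tibble::tibble(...)
  schema <- feature_schema()
  n <- length(pair_ids)
  base <- tibble::as_tibble(matrix(0, n, length(schema),
                                   dimnames = list(NULL, schema)))
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  dplyr::bind_cols(
    tibble::tibble(pair_id = pair_ids,
                   patient = sub("\\|.*", "", pair_ids),
                   sv_id = "sv", gene_id = "g",
                   element_kind = "enhancer", chrom = "1",
                   start = seq_len(n) * 10, end = seq_len(n) * 10 + 5,
                   direction = "gain"),
    base
  )
}

# brute-force AUC over all (positive, negative) score pairs
auc_bruteforce <- function(truth, prob) {
  pos <- prob[truth == "positive"]
  neg <- prob[truth != "positive"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# linearly separable MIL fixture: positive bags carry strong
# h3k27ac/DNase instances, negative bags are quiet
separable_bags <- function(n_per_class = 12, n_patients = 6, seed = 1) {
  set.seed(seed)
  ids <- sprintf("p%d|sv%02d|g", rep(seq_len(n_patients),
                                     length.out = 2 * n_per_class),
                 seq_len(2 * n_per_class))
  label <- rep(c("positive", "negative"), each = n_per_class)
  inst <- toy_instances(
    rep(ids, each = 2),
    h3k27ac_strength = ifelse(rep(label, each = 2) == "positive",
                              runif(4 * n_per_class, 6, 10),
                              runif(4 * n_per_class, 0, 2)),
    dnase = rep(ifelse(label == "positive", 1, 0), each = 2)
  )
  bags <- tibble::tibble(
    pair_id = ids, patient = sub("\\|.*", "", ids), sv_id = "sv",
    sv_type = "DEL", gene_id = "g", z = 0, n_reference = 10L, label = label
  )
  list(bags = bags, instances = inst)
}
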