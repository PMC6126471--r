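# Worked examples from the two published tables of equal- and unequal-mix
# barnyard experiments. Expected multiplet frequencies (3 decimals) were
# verified by independent closed-form evaluation before being frozen here.
table_fixture <- data.frame(
  table   = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
  n_type1 = c(2005, 2050, 2500, 2050, 3050, 3550, 3850, 3950),
  n_type2 = c(2005, 2050, 2500, 2050, 1050,  550,  250,  150),
  n_mixed = c(  10,  100, 1000,  100,  100,  100,  100,  100),
  m_3dp   = c(0.005, 0.049, 0.425, 0.049, 0.065, 0.110, 0.245, 0.459),
  # "twice cross celltype freq" is only tabulated for the equal-mix table
  twice_cross_3dp = c(0.005, 0.050, 0.500, NA, NA, NA, NA, NA))

# Independent oracle: M from truncated Poisson pmf summation, never from the
# closed form under test.
oracle_multiplet_frequency <- function(mu, k_max = 60L) {
  sum(stats::dpois(2:k_max, mu)) / sum(stats::dpois(1:k_max, mu))
}

random_valid_counts <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    n1 <- sample(20:5000, 1)
    n2 <- sample(20:5000, 1)
    n12 <- sample(seq_len(min(n1, n2) - 1L), 1)
    droplet_counts(n1, n2, n12)
  })
}

# Writes a cellranger-style triplet with raw text so the reader's parsing of
# 1-based MatrixMarket coordinates is exercised independently of writeMM.
write_raw_triplet <- function(dir, n_features, n_barcodes, entries,
                              feature_ids, barcode_ids = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(dir, "matrix.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", n_features, n_barcodes, nrow(entries)),
               if (nrow(entries) > 0)
                 sprintf("%d %d %d", entries[, 1], entries[, 2], entries[, 3])),
             mtx)
  writeLines(paste(feature_ids, feature_ids, sep = "\t"),
             file.path(dir, "features.tsv"))
  if (is.null(barcode_ids)) barcode_ids <- paste0("BC", seq_len(n_barcodes))
  writeLines(barcode_ids, file.path(dir, "barcodes.tsv"))
  file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
}
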