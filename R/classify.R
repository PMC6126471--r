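#' Read a cellranger-style mixed-species gene-barcode matrix
#'
#' Reads the standard triplet — a MatrixMarket coordinate `.mtx` of UMI
#' counts (features x barcodes) plus features and barcodes TSV sidecars,
#' optionally gzipped — and assigns each feature to one of the two species by
#' its identifier prefix (e.g. genome-build prefixes such as `"GRCh38_"` and
#' `"mm10_"`). Prefixes are matched literally and case-sensitively; a feature
#' matching neither (or both) prefixes is an error naming the offenders.
#'
#' @param mtx Path to the MatrixMarket counts file.
#' @param features Path to the features TSV (feature id in column 1).
#' @param barcodes Path to the barcodes TSV (one barcode per line).
#' @param species_prefixes Character vector of length 2: the type-1 and
#'   type-2 feature-id prefixes, in that order.
#' @return An object of class `species_matrix`: sparse counts
#'   (`Matrix::dgCMatrix`, features x barcodes), `barcodes`, `features`, and
#'   the per-feature `species` factor with levels `type1`, `type2`.
#' @export
read_species_matrix <- function(mtx, features, barcodes, species_prefixes) {
  if (length(species_prefixes) != 2L || !is.character(species_prefixes) ||
      anyNA(species_prefixes) || any(!nzchar(species_prefixes)))
    stop_validation("species_prefixes must be two non-empty strings")
  m <- as(Matrix::readMM(mtx), "CsparseMatrix")
  read_column <- function(path, col = 1L) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    as.character(df[[col]])
  }
  feature_ids <- if (nrow(m) > 0) read_column(features) else character(0)
  barcode_ids <- if (ncol(m) > 0) read_column(barcodes) else character(0)
  if (length(feature_ids) != nrow(m))
    stop_validation(sprintf(
      "features file has %d entries but matrix header declares %d rows",
      length(feature_ids), nrow(m)))
  if (length(barcode_ids) != ncol(m))
    stop_validation(sprintf(
      "barcodes file has %d entries but matrix header declares %d columns",
      length(barcode_ids), ncol(m)))
  if (any(m@x < 0) || any(m@x != round(m@x)))
    stop_validation("matrix entries must be non-negative integer UMI counts")
  is1 <- startsWith(feature_ids, species_prefixes[1])
  is2 <- startsWith(feature_ids, species_prefixes[2])
  bad <- feature_ids[(is1 & is2) | (!is1 & !is2)]
  if (length(bad) > 0)
    stop_validation(paste0(
      "feature ids not matching exactly one species prefix: ",
      paste(utils::head(bad, 10), collapse = ", "),
      if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10) else ""))
  structure(
    list(counts = m, barcodes = barcode_ids, features = feature_ids,
         species = factor(ifelse(is1, "type1", "type2"),
                          levels = c("type1", "type2")),
         species_prefixes = species_prefixes),
    class = "species_matrix")
}

new_species_matrix <- function(counts, barcodes, features, species) {
  structure(list(counts = counts, barcodes = barcodes, features = features,
                 species = factor(species, levels = c("type1", "type2")),
                 species_prefixes = c("type1_", "type2_")),
            class = "species_matrix")
}

#' @export
print.species_matrix <- function(x, ...) {
  cat(sprintf("Mixed-species UMI matrix: %d features (%d type1 / %d type2) x %d barcodes, %d non-zero entries\n",
              nrow(x$counts), sum(x$species == "type1"),
              sum(x$species == "type2"), ncol(x$counts),
              length(x$counts@x)))
  invisible(x)
}

#' Call each barcode's species from UMI purity
#'
#' Per barcode, UMIs are summed per species. Barcodes with total UMIs below
#' `min_umi` are `background`. Above the floor, a barcode is `mixed` when the
#' minor species holds at least `minor_fraction` of the UMIs (the boundary is
#' inclusive, so an exact 50/50 split is mixed); otherwise it is called as the
#' majority species. The summary follows the inclusive counting convention of
#' [droplet_counts()]: `n_type1` counts calls in {type1, mixed}, `n_type2`
#' counts {type2, mixed}, `n_mixed` counts {mixed}.
#'
#' The rule is deliberately simple and transparent — a purity threshold over
#' raw UMI shares. It does not model ambient RNA, so on real data the
#' defaults (`min_umi = 100`, `minor_fraction = 0.1`) should be reviewed
#' against the barcode-rank and cross-species contamination profiles.
#'
#' @param mat A [read_species_matrix()] result (or equivalent).
#' @param min_umi Minimum total UMIs for a barcode to be considered a cell.
#' @param minor_fraction Minor-species UMI share at or above which a barcode
#'   is called mixed; must lie strictly between 0 and 0.5.
#' @return An object of class `cell_calls`: a per-barcode data.frame
#'   (`barcode`, `umi_type1`, `umi_type2`, `call`), the `summary`
#'   [droplet_counts()] over non-background barcodes, and the parameters.
#' @export
call_cells <- function(mat, min_umi = 100L, minor_fraction = 0.1) {
  stopifnot(inherits(mat, "species_matrix"))
  if (!is.numeric(min_umi) || min_umi < 1)
    stop_validation("min_umi must be >= 1")
  if (!is.numeric(minor_fraction) || minor_fraction <= 0 ||
      minor_fraction >= 0.5)
    stop_validation("minor_fraction must be strictly between 0 and 0.5")
  umi1 <- Matrix::colSums(mat$counts[mat$species == "type1", , drop = FALSE])
  umi2 <- Matrix::colSums(mat$counts[mat$species == "type2", , drop = FALSE])
  total <- umi1 + umi2
  minor_share <- ifelse(total > 0, pmin(umi1, umi2) / total, 0)
  call <- rep("background", length(total))
  cell <- total >= min_umi
  call[cell & minor_share >= minor_fraction] <- "mixed"
  call[cell & minor_share < minor_fraction & umi1 > umi2] <- "type1"
  call[cell & minor_share < minor_fraction & umi2 > umi1] <- "type2"
  calls <- data.frame(barcode = mat$barcodes, umi_type1 = umi1,
                      umi_type2 = umi2,
                      call = factor(call, levels = c("type1", "type2",
                                                     "mixed", "background")),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(
    list(calls = calls,
         summary = droplet_counts(
           n_type1 = sum(call %in% c("type1", "mixed")),
           n_type2 = sum(call %in% c("type2", "mixed")),
           n_mixed = sum(call == "mixed")),
         min_umi = min_umi, minor_fraction = minor_fraction),
    class = "cell_calls")
}

#' @export
print.cell_calls <- function(x, ...) {
  cat(sprintf("Species calls over %d barcodes (min_umi = %g, minor_fraction = %g)\n",
              nrow(x$calls), x$min_umi, x$minor_fraction))
  print(table(x$calls$call))
  print(x$summary)
  invisible(x)
}

#' Generate a synthetic mixed-species UMI matrix from simulated droplets
#'
#' Turns the per-droplet cell counts of a [simulate_droplets()] run (with
#' `keep_droplets = TRUE`) into a cellranger-style sparse UMI matrix: each
#' non-empty droplet becomes one barcode, and each species' UMI count is drawn
#' as `Poisson(depth * cells_of_that_species)`. With `depth` far above the
#' classifier's `min_umi` and `noise = 0`, purity calls cannot flip and the
#' classifier summary reproduces the simulator's droplet counts exactly.
#'
#' @param sim A `simulation_result` carrying `droplets`.
#' @param depth Mean UMIs sequenced per cell.
#' @param n_features_per_species Features per species to spread counts over.
#' @param noise Mean cross-species ambient UMIs added per barcode (Poisson);
#'   0 for a clean matrix. Synthetic stand-in for ambient contamination only.
#' @param seed Integer RNG seed.
#' @return A `species_matrix` (synthetic), barcodes named `cell_<i>`.
#' @export
simulate_species_matrix <- function(sim, depth = 2000, n_features_per_species = 10L,
                                    noise = 0, seed = 20180903L) {
  stopifnot(inherits(sim, "simulation_result"))
  if (is.null(sim$droplets))
    stop_validation("simulate_droplets must be run with keep_droplets = TRUE")
  set.seed(as.integer(seed %% .Machine$integer.max))
  c1 <- sim$droplets$c1; c2 <- sim$droplets$c2
  nonempty <- which(c1 + c2 > 0)
  n_bc <- length(nonempty)
  umi1 <- stats::rpois(n_bc, depth * c1[nonempty] + noise)
  umi2 <- stats::rpois(n_bc, depth * c2[nonempty] + noise)
  nf <- as.integer(n_features_per_species)
  features <- c(paste0("type1_gene", seq_len(nf)),
                paste0("type2_gene", seq_len(nf)))
  species <- rep(c("type1", "type2"), each = nf)
  spread <- function(totals, offset) {
    ## multinomial spread of each barcode's species total across its features
    ij <- lapply(seq_along(totals), function(j) {
      if (totals[j] == 0) return(NULL)
      x <- as.vector(stats::rmultinom(1, totals[j], rep(1, nf)))
      keep <- x > 0
      cbind(i = offset + which(keep), j = j, x = x[keep])
    })
    do.call(rbind, ij)
  }
  trip <- rbind(spread(umi1, 0L), spread(umi2, nf))
  counts <- Matrix::sparseMatrix(
    i = if (is.null(trip)) integer(0) else trip[, "i"],
    j = if (is.null(trip)) integer(0) else trip[, "j"],
    x = if (is.null(trip)) numeric(0) else trip[, "x"],
    dims = c(2L * nf, n_bc))
  new_species_matrix(counts, barcodes = paste0("cell_", seq_len(n_bc)),
                     features = features, species = species)
}

#' Write a species matrix as a cellranger-style triplet
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` into `dir`.
#' Used by tests and the CLI to round-trip synthetic matrices through the
#' on-disk format the classifier reads.
#'
#' @param mat A `species_matrix`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_species_matrix <- function(mat, dir) {
  stopifnot(inherits(mat, "species_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(mat$counts, paths[1])
  utils::write.table(data.frame(id = mat$features, name = mat$features),
                     paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(mat$barcodes, paths[3])
  invisible(paths)
}
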