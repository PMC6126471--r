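#' Observed droplet counts from a two-species mixing experiment
#'
#' Container for the three experimental observables of a barnyard experiment:
#' the number of partitions (droplets, wells, or well combinations) containing
#' at least one cell of type 1 (`n_type1`, N1), at least one of type 2
#' (`n_type2`, N2), and at least one of *both* (`n_mixed`, N1,2).
#'
#' @section Counting convention:
#' `n_type1` and `n_type2` each **include** the mixed droplets: a droplet with
#' both a human and a mouse cell is counted in all three of N1, N2 and N1,2.
#' The number of non-empty droplets is therefore `n_type1 + n_type2 - n_mixed`.
#' This is the convention used by cellranger-style "estimated number of cell
#' partitions" summaries; [call_cells()] and [simulate_droplets()] both emit it.
#'
#' @param n_type1 Droplets containing >= 1 cell of type 1 (includes mixed).
#' @param n_type2 Droplets containing >= 1 cell of type 2 (includes mixed).
#' @param n_mixed Droplets containing >= 1 cell of each type.
#'
#' @details Counts are usually integers, but non-negative reals are accepted
#'   (with a notice) because upstream pipelines may report estimated,
#'   fractional partition counts.
#'
#' @return An object of class `droplet_counts`: a list with fields `n_type1`,
#'   `n_type2`, `n_mixed` and the derived `n_nonempty`.
#' @examples
#' droplet_counts(2050, 2050, 100)
#' @seealso [estimate_from_counts()], [infer_rates()]
#' @export
droplet_counts <- function(n_type1, n_type2, n_mixed) {
  for (nm in c("n_type1", "n_type2", "n_mixed")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_validation(sprintf("%s must be a single finite number, got %s",
                              nm, deparse(v)))
    if (v < 0)
      stop_validation(sprintf("%s must be non-negative, got %g", nm, v))
  }
  n_type1 <- as.numeric(n_type1)
  n_type2 <- as.numeric(n_type2)
  n_mixed <- as.numeric(n_mixed)
  if (any(c(n_type1, n_type2, n_mixed) != round(c(n_type1, n_type2, n_mixed))))
    message("note: non-integer droplet counts supplied; treating as ",
            "estimated (fractional) partition counts")
  if (n_mixed > n_type1 || n_mixed > n_type2)
    stop_validation(sprintf(
      "n_mixed (%g) cannot exceed n_type1 (%g) or n_type2 (%g): mixed droplets are included in both per-type counts",
      n_mixed, n_type1, n_type2))
  structure(
    list(n_type1 = n_type1, n_type2 = n_type2, n_mixed = n_mixed,
         n_nonempty = n_type1 + n_type2 - n_mixed),
    class = "droplet_counts")
}

#' @export
print.droplet_counts <- function(x, ...) {
  cat("Droplet counts (inclusive convention)\n")
  cat(sprintf("  N1 (>=1 type-1 cell): %g\n", x$n_type1))
  cat(sprintf("  N2 (>=1 type-2 cell): %g\n", x$n_type2))
  cat(sprintf("  N1,2 (both types):    %g\n", x$n_mixed))
  cat(sprintf("  non-empty:            %g\n", x$n_nonempty))
  invisible(x)
}

#' Poisson droplet-loading parameters
#'
#' The loading model: each droplet independently receives `c1 ~ Poisson(mu1)`
#' cells of type 1 and `c2 ~ Poisson(mu2)` cells of type 2, out of
#' `n_droplets` total droplets (empty and non-empty). When inferred from
#' observed counts, `n_droplets` is generally fractional and is kept
#' real-valued: rounding it perturbs the rates at the fourth decimal.
#'
#' @param mu1,mu2 Mean cells per droplet of each type (>= 0, finite).
#' @param n_droplets Total droplet count, empty + non-empty (> 0); may be
#'   non-integer when inferred. Optional (`NA`) for the pure probability
#'   functions, which only use the rates.
#' @return An object of class `poisson_load`.
#' @examples
#' poisson_load(0.05, 0.05, n_droplets = 42025)
#' @export
poisson_load <- function(mu1, mu2, n_droplets = NA_real_) {
  for (nm in c("mu1", "mu2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop_validation(sprintf("%s must be a single finite number >= 0", nm))
  }
  if (!is.na(n_droplets) &&
      (!is.numeric(n_droplets) || length(n_droplets) != 1L ||
       !is.finite(n_droplets) || n_droplets <= 0))
    stop_validation("n_droplets must be a single finite number > 0 (or NA)")
  structure(list(mu1 = as.numeric(mu1), mu2 = as.numeric(mu2),
                 n_droplets = as.numeric(n_droplets)),
            class = "poisson_load")
}

#' @export
print.poisson_load <- function(x, ...) {
  cat(sprintf("Poisson load: mu1 = %.6g, mu2 = %.6g cells/droplet", x$mu1, x$mu2))
  if (!is.na(x$n_droplets)) cat(sprintf(", N = %.6g droplets", x$n_droplets))
  cat("\n")
  invisible(x)
}
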