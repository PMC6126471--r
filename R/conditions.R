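#' @keywords internal
"_PACKAGE"

## Condition constructors. Two estimation failures are first-class, named
## conditions so callers (and the CLI exit-code mapping) can branch on them;
## everything else is a plain validation error raised at construction.

stop_unidentifiable_total <- function(counts) {
  stop(structure(
    class = c("barnyard_unidentifiable_total", "barnyard_error",
              "error", "condition"),
    list(
      message = paste0(
        "unidentifiable-total: n_mixed (N1,2) is 0, so the total droplet ",
        "count N = N1*N2/N1,2 is unbounded and the multiplet frequency is ",
        "unconstrained. The doublet approximation gives a lower bound of 0; ",
        "the experiment is underpowered to see mixing."),
      call = NULL, counts = counts
    )))
}

stop_inconsistent_counts <- function(counts, which_side) {
  stop(structure(
    class = c("barnyard_inconsistent_counts", "barnyard_error",
              "error", "condition"),
    list(
      message = paste0(
        "inconsistent-counts: n_mixed (N1,2) >= ", which_side,
        ", which implies an infinite loading rate (the inferred total N ",
        "does not exceed the per-type count, so -log((N - N_i)/N) ",
        "diverges). Check that N1 and N2 include mixed droplets and that ",
        "N1,2 counts only droplets with both types."),
      call = NULL, counts = counts
    )))
}

stop_validation <- function(msg) {
  stop(structure(
    class = c("barnyard_validation_error", "barnyard_error",
              "error", "condition"),
    list(message = msg, call = NULL)))
}
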