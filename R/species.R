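#' Define a precursor species and its fragment channels
#'
#' The unit of simulation: one precursor ion population with its m/z, charge
#' state, relative abundance, and the fragment channels it can produce. A
#' singly-charged convention is used for fragments, so every fragment m/z
#' must be below the precursor m/z.
#'
#' @param mz Precursor m/z, Th (positive).
#' @param charge Charge state, positive integer (default 1).
#' @param abundance Relative abundance, dimensionless, >= 0 (default 1).
#' @param fragments Data frame with columns `fragment_mz` (Th, each less
#'   than `mz`) and `branching_ratio` (>= 0, summing to at most 1). The
#'   remainder 1 - sum(branching_ratio) is the fraction of fragmentation
#'   events that fall outside the monitored channels. May be empty.
#' @return Object of class `precursor_species`.
#' @export
#' @examples
#' precursor_species(1000, fragments = data.frame(
#'   fragment_mz = c(400, 650), branching_ratio = c(0.4, 0.5)))
precursor_species <- function(mz, charge = 1L, abundance = 1,
                              fragments = data.frame(
                                fragment_mz = numeric(),
                                branching_ratio = numeric())) {
  stopifnot(length(mz) == 1, mz > 0, charge >= 1, abundance >= 0)
  fragments <- as.data.frame(fragments)
  if (!all(c("fragment_mz", "branching_ratio") %in% names(fragments)))
    stop("fragments needs columns fragment_mz and branching_ratio")
  if (any(fragments$fragment_mz <= 0) || any(fragments$fragment_mz >= mz))
    stop("fragment m/z must be positive and below the precursor m/z")
  if (any(fragments$branching_ratio < 0) ||
      sum(fragments$branching_ratio) > 1 + 1e-12)
    stop("branching ratios must be non-negative and sum to at most 1")
  structure(list(mz = mz, charge = as.integer(charge),
                 abundance = abundance, fragments = fragments),
            class = "precursor_species")
}

#' @export
print.precursor_species <- function(x, ...) {
  cat("<precursor_species> m/z", x$mz, "Th, z =", x$charge,
      ", abundance", x$abundance, ",", nrow(x$fragments), "fragments\n")
  invisible(x)
}
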