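## Spatio-temporally bias-matched target-group background sampling.

#' Build a target-group background sample
#'
#' Draws `n` points i.i.d. with replacement from the empirical distribution of
#' the prepared target-group records over unique `(location, year, month)`
#' triples, each triple weighted by its record multiplicity. The background
#' therefore inherits both the spatial and the temporal sampling bias of the
#' survey effort that produced the presences (the focal species' own records
#' belong in the target group). Covariates are stamped exactly as for
#' presences.
#'
#' @param target_records prepared (filtered, deduplicated) records of all
#'   target-group species, with `row, col, year, month` (or `x, y`).
#' @param cube a [climate_cube()] for covariate stamping, or `NULL` to skip
#'   stamping.
#' @param n number of background points.
#' @param seed integer seed.
#' @param window_lengths,stacks passed to [stamp_covariates()].
#' @return data.frame of `n` background points with covariate columns.
#' @export
build_target_group_background <- function(target_records, cube = NULL,
                                          n = 100000L, seed = 1L,
                                          window_lengths = c(12L, 36L),
                                          stacks = NULL) {
  if (is.null(target_records) || nrow(target_records) == 0L)
    stop("target group is empty")
  keep <- intersect(c("species", "x", "y", "row", "col", "year", "month",
                      "source"),
                    names(target_records))
  triples <- target_records[, keep, drop = FALSE]
  out <- with_seed(seed,
    triples[sample.int(nrow(triples), n, replace = TRUE), , drop = FALSE])
  rownames(out) <- NULL
  if (!is.null(cube))
    out <- stamp_covariates(out, cube, window_lengths, stacks)
  attr(out, "provenance") <- c(attr(out, "provenance"),
                               list(list(step = "target_group_background",
                                         n = n, seed = seed,
                                         source_records = nrow(triples))))
  out
}
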