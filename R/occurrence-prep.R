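## Quality filtering, spatio-temporal deduplication and covariate stamping of
## occurrence records.

## append an event to a record set's provenance log
log_event <- function(records, ...) {
  lg <- attr(records, "provenance")
  if (is.null(lg)) lg <- list()
  attr(records, "provenance") <- c(lg, list(list(...)))
  records
}

#' Provenance log of an occurrence set
#' @param records a record data.frame processed by this module.
#' @return list of logged filter events.
#' @export
provenance <- function(records) attr(records, "provenance")

#' Quality-filter occurrence records
#'
#' Retains records whose date accuracy and location accuracy are within the
#' stated bounds (bounds inclusive: the exclusion rule drops records strictly
#' coarser than the limit) and, optionally, whose year lies in `year_range`.
#' Removal counts are logged per reason.
#'
#' @param records data.frame with at least `year, month, date_acc (months),
#'   loc_acc (km)`.
#' @param max_date_acc maximum date accuracy, months.
#' @param max_loc_acc maximum location accuracy, km.
#' @param year_range optional inclusive `c(first, last)` year filter.
#' @return the retained records, with a provenance log (see [provenance()]).
#' @export
filter_records <- function(records, max_date_acc = 1, max_loc_acc = 10,
                           year_range = NULL) {
  bad_date <- records$date_acc > max_date_acc
  bad_loc <- records$loc_acc > max_loc_acc
  bad_year <- if (is.null(year_range)) rep(FALSE, nrow(records)) else
    records$year < year_range[1L] | records$year > year_range[2L]
  keep <- !(bad_date | bad_loc | bad_year)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no records survive filtering")
  log_event(out, step = "filter_records",
            removed_date_acc = sum(bad_date),
            removed_loc_acc = sum(bad_loc & !bad_date),
            removed_year = sum(bad_year & !bad_date & !bad_loc),
            retained = nrow(out))
}

## pairwise distance in km between records i and the set js
record_dist_km <- function(records, i, js, metric) {
  if (metric == "haversine") {
    geosphere::distHaversine(cbind(records$x[i], records$y[i]),
                             cbind(records$x[js], records$y[js])) / 1000
  } else {
    sqrt((records$x[i] - records$x[js])^2 + (records$y[i] - records$y[js])^2)
  }
}

#' Deduplicate records within a radius per month-year
#'
#' Within each `(species, year, month)` group, records are clustered greedily
#' in input order: each record joins the cluster of the first earlier record
#' within `radius` km (chains therefore merge), otherwise it seeds a new
#' cluster. Each cluster contributes its first-seen record. Seeds are pairwise
#' farther apart than `radius`, so the operation is idempotent.
#'
#' @param records filtered records with coordinate columns `x, y` (km on the
#'   synthetic planar grid, or lon/lat degrees with `metric = "haversine"`).
#' @param radius dedup radius in km.
#' @param metric `"euclidean"` (planar km) or `"haversine"` (great-circle on
#'   lon/lat).
#' @return the deduplicated records, provenance logged.
#' @export
dedupe_records <- function(records, radius = 5,
                           metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  n <- nrow(records)
  if (n == 0L) return(log_event(records, step = "dedupe_records",
                                removed = 0L, retained = 0L))
  sp <- if ("species" %in% names(records)) records$species else ""
  ord <- order(records$year, records$month, seq_len(n))
  recs <- records[ord, , drop = FALSE]
  spo <- sp[ord]
  grp <- paste(spo, recs$year, recs$month)
  keep_global <- logical(n)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    cluster <- integer(length(idx))
    seeds <- integer(0)
    for (k in seq_along(idx)) {
      if (k == 1L) { cluster[k] <- 1L; seeds <- 1L; next }
      dists <- record_dist_km(recs, idx[k], idx[seq_len(k - 1L)], metric)
      hit <- which(dists <= radius)
      if (length(hit)) cluster[k] <- cluster[hit[1L]]
      else { cluster[k] <- max(cluster) + 1L; seeds <- c(seeds, k) }
    }
    keep_global[idx[seeds]] <- TRUE
  }
  out <- recs[keep_global, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(records, "provenance")
  log_event(out, step = "dedupe_records", radius_km = radius,
            removed = n - nrow(out), retained = nrow(out))
}

#' Stamp records with trailing-window covariates
#'
#' Each record gains the eight covariates per window length, taken from the
#' grid cell containing its coordinates, for the window ending immediately
#' before its `(year, month)`. Records whose window extends before the cube's
#' start are excluded with a logged reason. Columns are named
#' `<covariate>_<length>m`, e.g. `prec_wet_q_36m`.
#'
#' @param records records with `x, y` (planar km) or precomputed `row, col`,
#'   plus `year, month`.
#' @param cube a [climate_cube()].
#' @param window_lengths window lengths in months (subset of 12, 36).
#' @param stacks optional named list of precomputed [covariate_stack()]s
#'   (names `"12"`, `"36"`) to avoid recomputation.
#' @return records with covariate columns appended, provenance logged.
#' @export
stamp_covariates <- function(records, cube, window_lengths = c(12L, 36L),
                             stacks = NULL) {
  if (!all(c("row", "col") %in% names(records))) {
    rc <- cell_of_xy(cube, records$x, records$y)
    records$row <- rc[, "row"]; records$col <- rc[, "col"]
  }
  t <- (records$year - cube$start_year) * 12L +
    (records$month - cube$start_month) + 1L
  ok <- t >= max(window_lengths) + 1L & t <= n_months(cube)
  out <- records[ok, , drop = FALSE]
  t <- t[ok]
  for (L in window_lengths) {
    st <- if (!is.null(stacks) && as.character(L) %in% names(stacks))
      stacks[[as.character(L)]] else covariate_stack(cube, L)
    for (v in bioclim_names()) {
      out[[sprintf("%s_%dm", v, L)]] <- st[cbind(t, out$row, out$col,
                                                 match(v, bioclim_names()))]
    }
  }
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(records, "provenance")
  log_event(out, step = "stamp_covariates",
            excluded_window_out_of_range = sum(!ok), retained = nrow(out))
}

#' Stamp records with long-term climatology covariates
#'
#' Covariates are the 30-year-style climatology means of the record's cell
#' (see [climatology_vars()]); all records in the same cell share values.
#'
#' @inheritParams stamp_covariates
#' @param baseline inclusive `c(start_year, end_year)` of the climatology.
#' @return records with the eight climatology covariate columns appended.
#' @export
stamp_climatology <- function(records, cube, baseline) {
  if (!all(c("row", "col") %in% names(records))) {
    rc <- cell_of_xy(cube, records$x, records$y)
    records$row <- rc[, "row"]; records$col <- rc[, "col"]
  }
  cells <- unique(records[, c("row", "col")])
  vals <- t(vapply(seq_len(nrow(cells)), function(i)
    climatology_vars(cube, c(cells$row[i], cells$col[i]), baseline),
    numeric(8L)))
  colnames(vals) <- bioclim_names()
  key <- paste(records$row, records$col)
  m <- match(key, paste(cells$row, cells$col))
  out <- cbind(records, as.data.frame(vals[m, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(records, "provenance")
  log_event(out, step = "stamp_climatology", baseline = baseline)
}
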