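#' Occurrence localities for one species
#'
#' @param species_id character species label.
#' @param points two-column matrix or data.frame of planar (x_km, y_km)
#'   localities.
#' @param deduplicated logical; set by [dedup_localities()].
#' @return an `occurrence_set`: a data.frame with columns `x_km`, `y_km`,
#'   attributes `species_id` and `deduplicated`.
#' @export
occurrence_set <- function(species_id, points, deduplicated = FALSE) {
  pts <- as.data.frame(rbind(points))
  if (ncol(pts) < 2L) stop("`points` needs two coordinate columns", call. = FALSE)
  pts <- pts[, 1:2]
  names(pts) <- c("x_km", "y_km")
  structure(pts, species_id = as.character(species_id),
            deduplicated = isTRUE(deduplicated),
            class = c("occurrence_set", "data.frame"))
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s: %d localities%s\n",
              attr(x, "species_id"), nrow(x),
              if (isTRUE(attr(x, "deduplicated"))) " (deduplicated)" else ""))
  invisible(x)
}

#' Remove coordinate-identical duplicate localities
#'
#' Specimens collected at exactly the same coordinates count once; this
#' mirrors the standard cleaning step applied to herbarium databases before
#' range estimation or niche modeling. The result is order-independent
#' (localities are returned sorted by x then y).
#'
#' @param occ an `occurrence_set`.
#' @return a deduplicated `occurrence_set` (possibly empty).
#' @export
dedup_localities <- function(occ) {
  pts <- unique(as.data.frame(occ)[, c("x_km", "y_km")])
  pts <- pts[order(pts$x_km, pts$y_km), , drop = FALSE]
  rownames(pts) <- NULL
  occurrence_set(attr(occ, "species_id"), pts, deduplicated = TRUE)
}

#' Read/write occurrence CSV files
#'
#' The on-disk format has columns `species`, `x_km`, `y_km` (planar km).
#'
#' @param occs a list of `occurrence_set` objects, or a single one.
#' @param path CSV file path.
#' @return `write_occurrences`: `path` invisibly. `read_occurrences`: a named
#'   list of `occurrence_set` objects, one per species in the file.
#' @export
write_occurrences <- function(occs, path) {
  if (inherits(occs, "occurrence_set")) occs <- list(occs)
  df <- do.call(rbind, lapply(occs, function(o)
    data.frame(species = attr(o, "species_id"),
               x_km = o$x_km, y_km = o$y_km)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("species", "x_km", "y_km") %in% names(df)))
  sp <- split(df, df$species)
  lapply(sp, function(d) occurrence_set(d$species[1L], d[, c("x_km", "y_km")]))
}
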