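#' Environmental raster stack in planar kilometre coordinates
#'
#' An `env_stack` holds one or more co-registered 2-D grids of environmental
#' values (climate-like layers), a shared cell size in km, a planar origin,
#' and a shared nodata mask. All pipeline stages operate on this container;
#' geographic inputs are assumed to have been projected to an equal-area
#' planar CRS before entry.
#'
#' @param layers named list of numeric matrices, all of identical dimension.
#' @param cell_size_km positive cell edge length in km.
#' @param origin numeric length-2, planar (x_km, y_km) of the lower-left
#'   corner of the grid.
#' @param nodata_mask logical matrix of the same dimension as the layers;
#'   `TRUE` marks cells excluded from every computation. Defaults to no
#'   masked cells.
#'
#' @return an object of class `env_stack` with elements `layers`,
#'   `cell_size_km`, `origin`, `nodata_mask`, `nrow`, `ncol`.
#' @export
env_stack <- function(layers, cell_size_km, origin = c(0, 0),
                      nodata_mask = NULL) {
  if (!is.list(layers) || length(layers) < 1L)
    stop("`layers` must be a non-empty list of matrices", call. = FALSE)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- paste0("layer", seq_along(layers))
  dims <- lapply(layers, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("every layer must be a matrix", call. = FALSE)
  d1 <- dims[[1L]]
  if (any(d1 <= 0L)) stop("layer dimensions must be positive", call. = FALSE)
  if (!all(vapply(dims, function(d) identical(d, d1), logical(1))))
    stop("all layers must share the same dimensions", call. = FALSE)
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1L ||
      cell_size_km <= 0)
    stop("`cell_size_km` must be a positive scalar", call. = FALSE)
  if (is.null(nodata_mask)) {
    nodata_mask <- matrix(FALSE, d1[1L], d1[2L])
  }
  stopifnot(is.logical(nodata_mask), identical(dim(nodata_mask), d1))
  if (all(nodata_mask))
    stop("at least one cell must be unmasked", call. = FALSE)
  structure(
    list(layers = layers, cell_size_km = cell_size_km,
         origin = as.numeric(origin[1:2]), nodata_mask = nodata_mask,
         nrow = d1[1L], ncol = d1[2L]),
    class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layer(s), %d x %d cells, %.3g km cells\n",
              length(x$layers), x$nrow, x$ncol, x$cell_size_km))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat(sprintf("  masked cells: %d / %d\n", sum(x$nodata_mask),
              x$nrow * x$ncol))
  invisible(x)
}

n_cells <- function(env) env$nrow * env$ncol

#' Linear indices of unmasked cells
#' @param env an `env_stack`.
#' @return integer vector of column-major cell indices with data.
#' @export
unmasked_cells <- function(env) which(!env$nodata_mask)

#' Planar centre coordinates of grid cells
#'
#' Cells are indexed column-major (R matrix convention); row 1 is the
#' southernmost row so that y increases with row index.
#'
#' @param env an `env_stack`.
#' @param cells integer cell indices (column-major). Default: all cells.
#' @return two-column matrix of (x_km, y_km) cell centres.
#' @export
cell_centers <- function(env, cells = seq_len(n_cells(env))) {
  rc <- arrayInd(cells, c(env$nrow, env$ncol))
  cbind(x_km = env$origin[1L] + (rc[, 2L] - 0.5) * env$cell_size_km,
        y_km = env$origin[2L] + (rc[, 1L] - 0.5) * env$cell_size_km)
}

#' Cell index containing each planar point
#'
#' @param env an `env_stack`.
#' @param xy two-column matrix of (x_km, y_km) points.
#' @return integer vector of column-major cell indices; `NA` for points
#'   outside the grid extent.
#' @export
cell_at <- function(env, xy) {
  xy <- rbind(xy)
  col <- floor((xy[, 1L] - env$origin[1L]) / env$cell_size_km) + 1L
  row <- floor((xy[, 2L] - env$origin[2L]) / env$cell_size_km) + 1L
  # points exactly on the top/right edge belong to the last cell
  col[xy[, 1L] == env$origin[1L] + env$ncol * env$cell_size_km] <- env$ncol
  row[xy[, 2L] == env$origin[2L] + env$nrow * env$cell_size_km] <- env$nrow
  bad <- row < 1L | row > env$nrow | col < 1L | col > env$ncol
  idx <- (col - 1L) * env$nrow + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Layer values as a cells-by-layers matrix
#' @param env an `env_stack`.
#' @param cells cell indices (default all).
#' @return numeric matrix, one column per layer.
#' @export
env_matrix <- function(env, cells = seq_len(n_cells(env))) {
  out <- vapply(env$layers, function(m) m[cells], numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1L,
                                         dimnames = list(NULL, names(env$layers)))
  out
}

# ---- ESRI ASCII grid IO -----------------------------------------------------
# Plain-text single-band grid format; no raster package is required for it.

#' Write one layer as an ESRI ASCII grid
#' @param env an `env_stack`.
#' @param layer layer name or index.
#' @param path output file path.
#' @param nodata_value value written for masked cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(env, layer, path, nodata_value = -9999) {
  m <- env$layers[[layer]]
  m[env$nodata_mask] <- nodata_value
  hdr <- c(sprintf("ncols %d", env$ncol),
           sprintf("nrows %d", env$nrow),
           sprintf("xllcorner %.10g", env$origin[1L]),
           sprintf("yllcorner %.10g", env$origin[2L]),
           sprintf("cellsize %.10g", env$cell_size_km),
           sprintf("NODATA_value %.10g", nodata_value))
  # ASCII grids store the northernmost row first
  body <- apply(m[env$nrow:1L, , drop = FALSE], 1L,
                function(r) paste(formatC(r, format = "g", digits = 10),
                                  collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a set of ESRI ASCII grids into an `env_stack`
#' @param paths named character vector of file paths (names become layer
#'   names; basenames are used when unnamed).
#' @return an `env_stack`; cells equal to any file's NODATA value are masked.
#' @export
read_ascii_stack <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  parse_one <- function(p) {
    lines <- readLines(p)
    hdr <- list()
    i <- 1L
    while (grepl("^[A-Za-z]", lines[i])) {
      kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
      i <- i + 1L
    }
    vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
    m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
    m <- m[hdr$nrows:1L, , drop = FALSE]   # back to south-first rows
    list(m = m, hdr = hdr)
  }
  grids <- lapply(paths, parse_one)
  hdr <- grids[[1L]]$hdr
  layers <- lapply(grids, `[[`, "m")
  mask <- Reduce(`|`, lapply(grids, function(g) {
    nd <- g$hdr$nodata_value
    if (is.null(nd)) matrix(FALSE, nrow(g$m), ncol(g$m)) else g$m == nd
  }))
  layers <- lapply(layers, function(m) { m[mask] <- NA_real_; m })
  env_stack(layers, cell_size_km = hdr$cellsize,
            origin = c(hdr$xllcorner, hdr$yllcorner), nodata_mask = mask)
}
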