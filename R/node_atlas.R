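#' Path to a packaged network node table
#'
#' The package ships the two region-of-interest (ROI) node tables of the
#' bimanual-coordination study as TSV fixtures: network `N1` (21 nodes,
#' regions significantly activated in both the older and the younger group)
#' and network `N2` (12 nodes, regions overactivated in the older group).
#' Coordinates are MNI millimetres at the activation peak, stored as the
#' integers printed in the source tables.
#'
#' @param network_id `"N1"` or `"N2"`.
#' @return Path to the installed TSV file.
#' @examples
#' node_table_path("N1")
#' @export
node_table_path <- function(network_id = c("N1", "N2")) {
  network_id <- match.arg(network_id)
  fn <- paste0(tolower(network_id), "_nodes.tsv")
  path <- system.file("extdata", fn, package = "bimanet", mustWork = TRUE)
  path
}

NODE_TABLE_COLUMNS <- c("network_id", "figure_index", "label", "brodmann",
                        "hemisphere", "x", "y", "z")

#' Load and validate a network node table
#'
#' Reads a tab-separated node table defining the vertices of a functional
#' network: one row per ROI with its anatomical label, Brodmann area,
#' hemisphere, and MNI peak coordinate. Row order is preserved and becomes
#' the graph vertex order for all downstream analyses.
#'
#' Hemisphere is taken from the table's `hemisphere` (Side) column, never
#' inferred from the sign of `x`: near-midline nodes such as the cerebellar
#' vermis at x = -2 / +2 keep their printed left/right assignment.
#'
#' @param path Path to a TSV file with columns
#'   `network_id, figure_index, label, brodmann, hemisphere, x, y, z`.
#' @param network_id Optional expected network id; if supplied it must match
#'   the file's `network_id` column. For the packaged networks `"N1"` and
#'   `"N2"` the known node counts (21 and 12) are enforced.
#' @return A `node_table`: a data frame with the columns above and attribute
#'   `network_id`.
#' @examples
#' n1 <- load_node_table(node_table_path("N1"), "N1")
#' nrow(n1) # 21
#' @export
load_node_table <- function(path, network_id = NULL) {
  if (!file.exists(path)) stop("node table file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  missing_cols <- setdiff(NODE_TABLE_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("node table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[NODE_TABLE_COLUMNS]
  for (col in c("figure_index", "x", "y", "z")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("node table row %d: `%s` is not an integer (value '%s')",
                   bad[1], col, df[[col]][bad[1]]), call. = FALSE)
    }
    df[[col]] <- v
  }
  empt <- which(!nzchar(trimws(df$label)))
  if (length(empt)) {
    stop("node table row ", empt[1], ": empty label", call. = FALSE)
  }
  bad_hemi <- which(!df$hemisphere %in% c("L", "R"))
  if (length(bad_hemi)) {
    stop(sprintf("node table row %d: hemisphere must be 'L' or 'R', got '%s'",
                 bad_hemi[1], df$hemisphere[bad_hemi[1]]), call. = FALSE)
  }
  dup <- duplicated(df$figure_index)
  if (any(dup)) {
    stop("node table row ", which(dup)[1], ": duplicate figure_index ",
         df$figure_index[which(dup)[1]], call. = FALSE)
  }
  ids <- unique(df$network_id)
  if (length(ids) != 1) {
    stop("node table mixes network ids: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(network_id) && !identical(ids, network_id)) {
    stop(sprintf("expected network_id '%s' but file declares '%s'",
                 network_id, ids), call. = FALSE)
  }
  expected_n <- c(N1 = 21L, N2 = 12L)
  if (ids %in% names(expected_n) && nrow(df) != expected_n[[ids]]) {
    stop(sprintf("network %s must have %d nodes, found %d", ids,
                 expected_n[[ids]], nrow(df)), call. = FALSE)
  }
  structure(df, network_id = ids, class = c("node_table", "data.frame"))
}

#' Write a node table back to TSV
#'
#' Emits the table in the same column order and formatting it is read with,
#' so a save/load round trip is byte-identical.
#'
#' @param table A `node_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(table, path) {
  utils::write.table(as.data.frame(table)[NODE_TABLE_COLUMNS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Enumerate interhemispheric node pairs
#'
#' Unordered node-index pairs whose endpoints lie in different hemispheres —
#' the candidate edges of the interhemispheric-connectivity sub-analysis,
#' where only functional connections that "travel" between hemispheres are
#' considered. For a table with `nL` left and `nR` right nodes the result
#' has exactly `nL * nR` rows.
#'
#' @param table A `node_table`.
#' @return Integer matrix with columns `i`, `j` (`i < j`, 1-based vertex
#'   indices in table row order); zero rows when all nodes share one
#'   hemisphere.
#' @examples
#' n1 <- load_node_table(node_table_path("N1"))
#' nrow(interhemispheric_pairs(n1)) # 110
#' @export
interhemispheric_pairs <- function(table) {
  stopifnot(inherits(table, "node_table"))
  hemi <- table$hemisphere
  n <- length(hemi)
  if (n < 2) return(matrix(integer(0), ncol = 2,
                           dimnames = list(NULL, c("i", "j"))))
  idx <- utils::combn(n, 2)
  keep <- hemi[idx[1, ]] != hemi[idx[2, ]]
  out <- t(idx[, keep, drop = FALSE])
  colnames(out) <- c("i", "j")
  out
}

#' Voxel indices of a spherical ROI
#'
#' Rasterizes a sphere of given radius around an MNI-mm centre onto a regular
#' voxel grid, returning 0-based integer voxel indices. A voxel is included
#' when its centre lies within `radius` (inclusive) of the sphere centre;
#' additionally the voxel whose cell contains the centre point is always
#' included, so a degenerate `radius = 0` sphere returns exactly the
#' containing voxel. Voxel `(i, j, k)` has its centre at
#' `origin + c(i, j, k) * voxel_size`.
#'
#' The source analysis used 6 mm spheres; the grid they were rasterized on is
#' not fixed by the method, so voxel size and origin are parameters
#' (functional 2.5 x 2.5 x 2.8 mm vs. anatomical 1 mm grids give different
#' voxel sets for the same sphere).
#'
#' @param center_mni Numeric length-3 centre, mm.
#' @param radius Sphere radius in mm, `>= 0`.
#' @param voxel_size Positive numeric length-3 voxel pitch, mm.
#' @param origin Numeric length-3 coordinate of voxel `(0, 0, 0)`'s centre.
#' @return Integer matrix, one row per voxel, columns `i`, `j`, `k`.
#' @examples
#' nrow(sphere_voxel_indices(c(0, 0, 0), 6, voxel_size = c(2, 2, 2)))
#' @export
sphere_voxel_indices <- function(center_mni, radius,
                                 voxel_size = c(2, 2, 2),
                                 origin = c(0, 0, 0)) {
  stopifnot(length(center_mni) == 3, length(voxel_size) == 3,
            length(origin) == 3, is.numeric(radius), length(radius) == 1)
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive",
                                 call. = FALSE)
  rel <- (center_mni - origin) / voxel_size
  lo <- floor(rel - radius / voxel_size)
  hi <- ceiling(rel + radius / voxel_size)
  grid <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
  centers <- sweep(sweep(grid, 2, voxel_size, `*`), 2, origin, `+`)
  d2 <- rowSums(sweep(centers, 2, center_mni, `-`)^2)
  keep <- d2 <= radius^2 + 1e-9
  out <- grid[keep, , drop = FALSE]
  containing <- round(rel) # voxel whose cell holds the centre point
  if (!any(out[, 1] == containing[1] & out[, 2] == containing[2] &
           out[, 3] == containing[3])) {
    out <- rbind(out, matrix(as.integer(containing), nrow = 1,
                             dimnames = list(NULL, c("i", "j", "k"))))
  }
  out <- out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}
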