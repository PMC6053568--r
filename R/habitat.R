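#' Build a fractal habitat layout
#'
#' Constructs the nested triangular ("fractal") array of habitat patches used
#' for multi-scale analysis. A level-0 cluster is a single patch; a level-l
#' cluster is three level-(l-1) clusters placed at the vertices of an
#' equilateral triangle whose side length is `spacings[l]`. A layout with
#' `levels = 4` therefore has 81 patches and supports aggregation at group
#' sizes 1, 3, 9, 27 and 81.
#'
#' Patch ids are 0-based and ordered lexicographically by hierarchy path, so
#' the level-l group of patch `i` is simply `i %/% 3^l`.
#'
#' @param levels Number of nesting levels (non-negative integer). The layout
#'   has `3^levels` patches.
#' @param spacings Numeric vector of length `levels`: the triangle side
#'   length (metres) used at each level, innermost first. Must be strictly
#'   positive; typically increasing so that clusters are spatially distinct.
#'   The defaults (0.5, 1.5, 4.5, 13.5 m) grow threefold per level; they are
#'   package defaults for a plausible field layout, not measured values, and
#'   should be replaced with real distances when available.
#' @return An object of class `pp_layout`: a list with elements
#'   \describe{
#'     \item{patch_ids}{integer vector `0:(N-1)`}
#'     \item{coords}{`N x 2` matrix of planar positions (metres)}
#'     \item{dist}{`N x N` Euclidean distance matrix (metres)}
#'     \item{hierarchy}{`N x (levels+1)` integer matrix; column `l+1` maps
#'       each patch to its level-`l` group (level 0 is the identity)}
#'     \item{levels, spacings}{the construction parameters}
#'   }
#' @examples
#' lay <- build_fractal_layout(2)
#' nrow(lay$coords) # 9 patches
#' table(scale_partition(lay, 3)) # 3 groups of 3
#' @export
build_fractal_layout <- function(levels,
                                 spacings = default_spacings(levels)) {
  if (length(levels) != 1L || is.na(levels) || levels < 0 ||
      levels != round(levels)) {
    stop("`levels` must be a single non-negative integer")
  }
  levels <- as.integer(levels)
  if (length(spacings) != levels) {
    stop("`spacings` must have length `levels` (one side length per level)")
  }
  if (levels > 0L && any(!is.finite(spacings) | spacings <= 0)) {
    stop("all `spacings` must be strictly positive")
  }

  coords <- matrix(0, nrow = 1L, ncol = 2L)
  if (levels > 0L) {
    for (l in seq_len(levels)) {
      side <- spacings[l]
      r <- side / sqrt(3) # circumradius of the equilateral triangle
      ang <- pi / 2 + c(0, 2, 4) * pi / 3
      verts <- cbind(r * cos(ang), r * sin(ang))
      coords <- do.call(rbind, lapply(1:3, function(v) {
        sweep(coords, 2L, verts[v, ], "+")
      }))
    }
  }
  # the loop stacks the three copies of each level so that later (larger)
  # levels are the slower-varying base-3 digits of the patch index: the
  # level-l group of patch i is simply i %/% 3^l
  n <- nrow(coords)
  hierarchy <- matrix(
    unlist(lapply(0:levels, function(l) (0:(n - 1L)) %/% 3L^l)),
    nrow = n, dimnames = list(NULL, paste0("level", 0:levels))
  )
  storage.mode(hierarchy) <- "integer"

  structure(
    list(
      patch_ids = 0:(n - 1L),
      coords = coords,
      dist = as.matrix(stats::dist(coords)),
      hierarchy = hierarchy,
      levels = levels,
      spacings = spacings
    ),
    class = "pp_layout"
  )
}

#' Default inter-cluster spacings
#'
#' Side lengths growing threefold per level, starting at 0.5 m between
#' neighbouring patches. Placeholder geometry for a fractal field array.
#'
#' @param levels number of levels
#' @return numeric vector of length `levels`
#' @export
default_spacings <- function(levels) {
  if (levels == 0L) return(numeric(0))
  0.5 * 3^(seq_len(levels) - 1L)
}

#' @export
print.pp_layout <- function(x, ...) {
  cat(sprintf(
    "pp_layout: %d patches, %d levels (group sizes %s)\n",
    length(x$patch_ids), x$levels,
    paste(3L^(0:x$levels), collapse = ", ")
  ))
  invisible(x)
}

#' Number of patches in a layout
#' @param layout a `pp_layout`
#' @return integer patch count
#' @export
n_patches <- function(layout) length(layout$patch_ids)

#' Partition patches into groups of a given spatial scale
#'
#' @param layout a `pp_layout`
#' @param scale group size: a power of 3 no larger than the layout
#'   (1, 3, 9, 27, 81, ...)
#' @return integer vector over patches (in `patch_ids` order) giving the
#'   0-based group index of each patch; every group has exactly `scale`
#'   members
#' @export
scale_partition <- function(layout, scale) {
  stopifnot(inherits(layout, "pp_layout"))
  l <- log(scale, base = 3)
  if (length(scale) != 1L || is.na(scale) || abs(l - round(l)) > 1e-9) {
    stop("`scale` must be a power of 3")
  }
  l <- as.integer(round(l))
  if (l > layout$levels) {
    stop(sprintf("scale %d exceeds layout size %d", scale,
                 length(layout$patch_ids)))
  }
  layout$hierarchy[, l + 1L]
}

#' Export a layout as a plain-text table
#'
#' Writes one row per patch: `patch_id, x, y, group_level1..group_levelL`.
#'
#' @param layout a `pp_layout`
#' @param path file path for the CSV
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "pp_layout"))
  df <- data.frame(
    patch_id = layout$patch_ids,
    x = layout$coords[, 1L],
    y = layout$coords[, 2L]
  )
  if (layout$levels > 0L) {
    grp <- layout$hierarchy[, -1L, drop = FALSE]
    colnames(grp) <- paste0("group_level", seq_len(layout$levels))
    df <- cbind(df, grp)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import a layout written by [write_layout()]
#'
#' Rebuilds the distance matrix from the stored coordinates and the
#' hierarchy from the stored group columns.
#'
#' @param path CSV path
#' @return a `pp_layout`
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path)
  need <- c("patch_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("layout file must have columns patch_id, x, y")
  }
  df <- df[order(df$patch_id), , drop = FALSE]
  n <- nrow(df)
  gcols <- grep("^group_level[0-9]+$", names(df), value = TRUE)
  levels <- length(gcols)
  hierarchy <- cbind(
    level0 = as.integer(df$patch_id),
    if (levels > 0L) {
      m <- as.matrix(df[, paste0("group_level", seq_len(levels)),
                        drop = FALSE])
      storage.mode(m) <- "integer"
      colnames(m) <- paste0("level", seq_len(levels))
      m
    }
  )
  coords <- cbind(df$x, df$y)
  structure(
    list(
      patch_ids = as.integer(df$patch_id),
      coords = coords,
      dist = as.matrix(stats::dist(coords)),
      hierarchy = hierarchy,
      levels = levels,
      spacings = rep(NA_real_, levels)
    ),
    class = "pp_layout"
  )
}
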