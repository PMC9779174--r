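#' Region-of-interest (ROI) sets
#'
#' An `roi_set` holds labeled reference regions over one scene: each region
#' has a class (`vegetation` / `non-vegetation`), a role (`train` / `test` /
#' `validation`) and a set of pixel indices. Train ROIs feed the supervised
#' reference classifier, test ROIs score it, and validation ROIs score the
#' index-based masks. Regions of different roles must not overlap.
#'
#' @param regions A list of regions; each is a list with elements `role`,
#'   `class` and `pixels` (1-based linear pixel indices into the scene,
#'   column-major as R stores matrices), and optionally `bbox`
#'   (`c(row, col, height, width)`, 1-based) for rectangular regions.
#' @param dim Scene dimensions `c(height, width)`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(regions, dim) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 2L, all(dim > 0))
  npix <- prod(dim)
  roles <- character(length(regions))
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    if (!all(c("role", "class", "pixels") %in% names(r)))
      stop("each ROI region needs 'role', 'class' and 'pixels'")
    if (!r$role %in% c("train", "test", "validation"))
      stop("unknown ROI role '", r$role, "'")
    if (!r$class %in% c("vegetation", "non-vegetation"))
      stop("unknown ROI class '", r$class, "'")
    if (length(r$pixels) == 0L) stop("empty ROI region")
    if (any(r$pixels < 1L | r$pixels > npix))
      stop("ROI region ", i, " has pixels outside the image bounds")
    roles[i] <- r$role
  }
  # roles must be disjoint pixel sets
  by_role <- split(regions, roles)
  pix <- lapply(by_role, function(rs) unlist(lapply(rs, `[[`, "pixels")))
  for (a in seq_along(pix)) for (b in seq_len(a - 1L)) {
    if (length(intersect(pix[[a]], pix[[b]])) > 0L)
      stop("ROI roles '", names(pix)[a], "' and '", names(pix)[b],
           "' overlap; roles must be disjoint")
  }
  structure(list(regions = regions, dim = dim), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  tab <- roi_counts(x)
  cat(sprintf("<roi_set> %d regions on a %d x %d scene\n",
              length(x$regions), x$dim[1], x$dim[2]))
  print(tab)
  invisible(x)
}

#' @rdname roi_set
#' @export
roi_counts <- function(x) {
  stopifnot(inherits(x, "roi_set"))
  role <- vapply(x$regions, `[[`, "", "role")
  cls <- vapply(x$regions, `[[`, "", "class")
  table(role = factor(role, c("train", "test", "validation")),
        class = factor(cls, c("vegetation", "non-vegetation")))
}

#' Flatten the pixels of one ROI role
#'
#' @param x An [roi_set()].
#' @param role `"train"`, `"test"` or `"validation"`.
#' @return A data frame with columns `pixel` (1-based linear index) and
#'   `class`.
#' @export
roi_pixels <- function(x, role = c("validation", "train", "test")) {
  stopifnot(inherits(x, "roi_set"))
  role <- match.arg(role)
  keep <- vapply(x$regions, function(r) r$role == role, TRUE)
  if (!any(keep)) stop("roi_set has no regions with role '", role, "'")
  regs <- x$regions[keep]
  data.frame(
    pixel = unlist(lapply(regs, `[[`, "pixels")),
    class = rep(vapply(regs, `[[`, "", "class"),
                vapply(regs, function(r) length(r$pixels), 1L))
  )
}

#' Read and write ROI sets
#'
#' Two plain-text ROI carriers round-trip through the in-memory `roi_set`:
#' a rectangle CSV (`role, class, row, col, height, width` with 0-based
#' top-left origin, half-open extents) and a per-role labeled-mask PNG
#' (0 = unassigned, 1 = vegetation, 2 = non-vegetation, written as grey
#' levels 0/128/255).
#'
#' @param x An [roi_set()] of rectangular regions (for writing).
#' @param path CSV file path.
#' @param dim Scene dimensions `c(height, width)` (for reading).
#' @return `write_roi_csv` returns `path` invisibly; `read_roi_csv` an
#'   `roi_set`.
#' @export
write_roi_csv <- function(x, path) {
  stopifnot(inherits(x, "roi_set"))
  bb <- lapply(x$regions, `[[`, "bbox")
  if (any(vapply(bb, is.null, TRUE)))
    stop("write_roi_csv needs rectangular regions (with a bbox)")
  df <- data.frame(
    role = vapply(x$regions, `[[`, "", "role"),
    class = vapply(x$regions, `[[`, "", "class"),
    row = vapply(bb, `[`, 1, 1) - 1L,   # 0-based external convention
    col = vapply(bb, `[`, 1, 2) - 1L,
    height = vapply(bb, `[`, 1, 3),
    width = vapply(bb, `[`, 1, 4)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_csv <- function(path, dim) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  regions <- lapply(seq_len(nrow(df)), function(i) {
    list(role = df$role[i], class = df$class[i],
         pixels = rect_pixels(df$row[i] + 1L, df$col[i] + 1L,
                              df$height[i], df$width[i], dim),
         bbox = c(df$row[i] + 1L, df$col[i] + 1L, df$height[i], df$width[i]))
  })
  roi_set(regions, dim)
}

# linear pixel indices of a 1-based rectangle on an H x W scene
rect_pixels <- function(row, col, height, width, dim) {
  rows <- row:(row + height - 1L)
  cols <- col:(col + width - 1L)
  as.integer(outer(rows, (cols - 1L) * dim[1], `+`))
}

#' @rdname write_roi_csv
#' @param role Which role to write/read as a labeled mask.
#' @export
write_roi_mask_png <- function(x, path, role = "validation") {
  stopifnot(inherits(x, "roi_set"))
  lab <- matrix(0L, x$dim[1], x$dim[2])
  for (r in x$regions) {
    if (r$role != role) next
    lab[r$pixels] <- if (r$class == "vegetation") 1L else 2L
  }
  png::writePNG(matrix(c(0, 128, 255)[lab + 1L] / 255, x$dim[1], x$dim[2]), path)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_mask_png <- function(path, role = "validation") {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  lab <- matrix(0L, nrow(arr), ncol(arr))
  lab[arr > 0.25 & arr < 0.75] <- 1L
  lab[arr >= 0.75] <- 2L
  regions <- list()
  if (any(lab == 1L))
    regions <- c(regions, list(list(role = role, class = "vegetation",
                                    pixels = which(lab == 1L))))
  if (any(lab == 2L))
    regions <- c(regions, list(list(role = role, class = "non-vegetation",
                                    pixels = which(lab == 2L))))
  if (length(regions) == 0L) stop("labeled mask contains no ROI pixels")
  roi_set(regions, dim(arr))
}
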