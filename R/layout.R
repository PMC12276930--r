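#' Insole sensel layout
#'
#' The pressure insole is modelled as 233 sensing cells (sensels) arranged in
#' a foot-shaped mask embedded in a 31 x 11 grid (rows run toe -> heel,
#' columns run medial -> lateral). The layout is a fixed package constant:
#' every simulated or measured frame is a vector of 233 sensel values whose
#' grid positions are given here.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{nrow, ncol}{grid dimensions (31, 11)}
#'     \item{rows, cols}{0-based integer grid coordinates, length 233}
#'     \item{mask}{31 x 11 logical matrix, `TRUE` on the 233 in-mask cells}
#'     \item{index}{31 x 11 integer matrix mapping grid cells to sensel
#'       number (NA off-mask)}
#'   }
#' @examples
#' lay <- sensel_layout()
#' sum(lay$mask)  # 233
#' @export
sensel_layout <- function() {
  if (!is.null(.gf_cache$layout)) return(.gf_cache$layout)
  nr <- 31L; nc <- 11L
  # cells per row, toe (row 0) to heel (row 30); sums to 233
  widths <- c(3L, 5L, 7L, 9L, 9L,
              11L, 11L, 11L, 11L, 11L,
              10L, 9L, 8L, 7L, 7L,
              6L, 6L, 6L, 6L, 6L, 5L,
              7L, 7L, 8L, 8L, 8L,
              8L, 8L, 7L, 5L, 3L)
  stopifnot(length(widths) == nr, sum(widths) == 233L)
  mask <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    w <- widths[r]
    start <- ((nc - w) %/% 2L) + 1L
    mask[r, start:(start + w - 1L)] <- TRUE
  }
  idx <- matrix(NA_integer_, nr, nc)
  # sensel numbering: column-major over the grid, in-mask cells only
  idx[mask] <- seq_len(sum(mask))
  which_in <- which(mask, arr.ind = TRUE)
  ord <- order(idx[mask])
  lay <- list(
    nrow = nr, ncol = nc,
    rows = as.integer(which_in[ord, "row"] - 1L),
    cols = as.integer(which_in[ord, "col"] - 1L),
    mask = mask,
    index = idx
  )
  .gf_cache$layout <- lay
  lay
}

.gf_cache <- new.env(parent = emptyenv())

#' Embed sensel vectors on the full grid
#'
#' Places 233-sensel frames on the 31 x 11 bounding grid (off-mask cells 0).
#'
#' @param frames numeric matrix, n x 233 (or a length-233 vector).
#' @param layout a [sensel_layout()].
#' @return n x 341 matrix; columns are column-major grid cells.
#' @export
embed_frames <- function(frames, layout = sensel_layout()) {
  if (is.null(dim(frames))) frames <- matrix(frames, nrow = 1L)
  assert_that(ncol(frames) == 233L, "expected 233 sensel columns, got %d", ncol(frames))
  out <- matrix(0, nrow(frames), layout$nrow * layout$ncol)
  cell <- layout$rows + 1L + layout$cols * layout$nrow  # column-major index
  out[, cell] <- frames
  out
}

#' Center of pressure of sensel frames
#'
#' Pressure-weighted centroid of each frame in grid coordinates
#' (0-based row, col). Frames with non-positive total pressure return NA.
#'
#' @param frames n x 233 matrix (or length-233 vector) of sensel values.
#' @param layout a [sensel_layout()].
#' @return n x 2 matrix with columns `row`, `col`.
#' @export
cop_from_frames <- function(frames, layout = sensel_layout()) {
  if (is.null(dim(frames))) frames <- matrix(frames, nrow = 1L)
  tot <- rowSums(frames)
  num <- frames %*% cbind(row = layout$rows, col = layout$cols)
  out <- num / tot
  out[tot <= 0, ] <- NA_real_
  out
}
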