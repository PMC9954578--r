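#' Read an IDX image/label file pair
#'
#' Parses the standard big-endian IDX layout used for handwritten-digit
#' benchmarks: images carry magic number 2051 and dimensions n x rows x cols
#' of unsigned bytes; labels carry magic 2049. Pixel bytes are divided by 255
#' so intensities land in \[0, 1\], and each image is flattened row-major.
#'
#' @param images_path Path to the images file (magic 2051).
#' @param labels_path Path to the labels file (magic 2049).
#' @return A list with `x` (n x rows*cols intensity matrix) and `y` (integer
#'   labels), directly usable as a dataset split.
#' @export
read_idx <- function(images_path, labels_path) {
  img_con <- file(images_path, "rb")
  on.exit(close(img_con), add = TRUE)
  magic <- readBin(img_con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2051L)) {
    stop(sprintf("%s: expected image magic 2051 at offset 0, got %s",
                 images_path, magic), call. = FALSE)
  }
  dims <- readBin(img_con, "integer", 3, size = 4, endian = "big")
  n <- dims[1]; rows <- dims[2]; cols <- dims[3]
  px <- readBin(img_con, "integer", n * rows * cols, size = 1, signed = FALSE)
  if (length(px) != n * rows * cols) {
    stop(sprintf("%s: truncated pixel data at offset %d", images_path,
                 16 + length(px)), call. = FALSE)
  }
  lbl_con <- file(labels_path, "rb")
  on.exit(close(lbl_con), add = TRUE)
  lmagic <- readBin(lbl_con, "integer", 1, size = 4, endian = "big")
  if (!identical(lmagic, 2049L)) {
    stop(sprintf("%s: expected label magic 2049 at offset 0, got %s",
                 labels_path, lmagic), call. = FALSE)
  }
  ln <- readBin(lbl_con, "integer", 1, size = 4, endian = "big")
  y <- readBin(lbl_con, "integer", ln, size = 1, signed = FALSE)
  if (length(y) != ln) {
    stop(sprintf("%s: truncated label data at offset %d", labels_path,
                 8 + length(y)), call. = FALSE)
  }
  if (ln != n) {
    stop(sprintf("image count %d does not match label count %d", n, ln),
         call. = FALSE)
  }
  x <- matrix(px / 255, nrow = n, ncol = rows * cols, byrow = TRUE)
  list(x = x, y = as.integer(y))
}

#' Write an IDX image/label file pair
#'
#' Inverse of [read_idx()]; mainly useful for building small fixtures.
#'
#' @param x n x (rows*cols) intensity matrix in \[0, 1\] (rounded to bytes).
#' @param y Integer labels.
#' @param images_path,labels_path Output paths.
#' @param rows,cols Image geometry; `rows * cols` must equal `ncol(x)`.
#' @return The two paths, invisibly.
#' @export
write_idx <- function(x, y, images_path, labels_path, rows, cols) {
  if (rows * cols != ncol(x)) stop("rows * cols must equal ncol(x)", call. = FALSE)
  if (nrow(x) != length(y)) stop("image/label count mismatch", call. = FALSE)
  con <- file(images_path, "wb")
  writeBin(as.integer(c(2051L, nrow(x), rows, cols)), con, size = 4,
           endian = "big")
  writeBin(as.integer(round(t(x) * 255)), con, size = 1)
  close(con)
  con <- file(labels_path, "wb")
  writeBin(as.integer(c(2049L, length(y))), con, size = 4, endian = "big")
  writeBin(as.integer(y), con, size = 1)
  close(con)
  invisible(c(images_path, labels_path))
}

#' Save / load a trained network as plain text
#'
#' Weights go to a JSON document with named per-layer entries, alongside the
#' layer sizes and LIF parameters, so a saved network reloads bit-for-bit to
#' full double precision.
#'
#' @param net A [network_config].
#' @param path Output file.
#' @return `save_network` returns `path` invisibly; `load_network` returns
#'   the [network_config].
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "network_config"))
  obj <- list(layer_sizes = net$layer_sizes,
              lif = unclass(net$lif),
              weights = stats::setNames(net$weights,
                                        paste0("W", seq_along(net$weights))))
  # I(17) significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::fromJSON(path)
  lif <- do.call(lif_params, as.list(obj$lif))
  weights <- lapply(seq_along(obj$weights), function(l) {
    as.matrix(obj$weights[[paste0("W", l)]])
  })
  network_config(as.integer(obj$layer_sizes), weights, lif)
}

#' Write / read a per-epoch metrics table
#'
#' One row per epoch with columns `epoch`, `train_loss`, `train_acc`,
#' `test_acc`, tab-separated.
#'
#' @param record The `record` data.frame from [train_snn()].
#' @param path Output file.
#' @return `write_metrics` returns `path` invisibly; `read_metrics` the
#'   data.frame.
#' @export
write_metrics <- function(record, path) {
  utils::write.table(record, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
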