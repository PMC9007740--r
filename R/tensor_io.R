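#' Save encoded tensors to HDF5
#'
#' Writes the tensor of a `confidence_maps`, `part_affinity_fields` or
#' `class_maps` object as an HDF5 dataset together with its grid metadata
#' (image size, output stride, sigma), so encoded targets can be exchanged
#' with training pipelines in other languages.
#'
#' @param x an encoded tensor object.
#' @param path output HDF5 path.
#' @param name dataset name within the file (default "tensor").
#' @return `path`, invisibly.
#' @export
save_tensors <- function(x, path, name = "tensor") {
  kind <- class(x)[1]
  if (!kind %in% c("confidence_maps", "part_affinity_fields", "class_maps")) {
    stop("unsupported tensor object: ", kind)
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(x$tensor, path, name)
  meta <- list(kind = kind,
               image_height = x$grid$height, image_width = x$grid$width,
               output_stride = x$grid$stride, sigma_base = x$grid$sigma_base)
  if (!is.null(x$node_names)) meta$node_names <- x$node_names
  if (!is.null(x$edges) && nrow(x$edges)) meta$edges <- unname(x$edges - 1L)
  if (!is.null(x$paf_sigma)) meta$paf_sigma <- x$paf_sigma
  if (!is.null(x$radius)) meta$radius <- x$radius
  rhdf5::h5write(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                               digits = NA)),
                 path, paste0(name, "_meta"))
  invisible(path)
}

#' Load encoded tensors from HDF5
#'
#' Inverse of [save_tensors()].
#'
#' @param path HDF5 file written by [save_tensors()].
#' @param name dataset name within the file.
#' @return the reconstructed tensor object.
#' @export
load_tensors <- function(path, name = "tensor") {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  tensor <- rhdf5::h5read(path, name)
  meta <- jsonlite::fromJSON(rhdf5::h5read(path, paste0(name, "_meta")))
  g <- grid_spec(meta$image_height, meta$image_width,
                 output_stride = meta$output_stride,
                 sigma_base = meta$sigma_base)
  out <- list(tensor = tensor, grid = g)
  if (!is.null(meta$node_names)) out$node_names <- meta$node_names
  if (!is.null(meta$edges)) {
    e <- matrix(as.integer(meta$edges), ncol = 2) + 1L
    colnames(e) <- c("source", "dest")
    out$edges <- e
  }
  if (!is.null(meta$paf_sigma)) out$paf_sigma <- meta$paf_sigma
  if (!is.null(meta$radius)) out$radius <- meta$radius
  structure(out, class = meta$kind)
}
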