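#' Set of instance masks over one micrograph
#'
#' An `instance_set` holds one binary mask per particle (or antibody blob)
#' over a common pixel grid. Masks are stored sparsely as sorted linear
#' indices into the image matrix, which keeps hundreds of instances per
#' scene cheap; use [instance_mask()] to materialise a logical matrix.
#' Masks may overlap, which a flat label image cannot represent — the
#' canonical file format is therefore a multi-page TIFF with one binary
#' page per instance ([write_instance_masks()]), with flat label images
#' accepted as a convenience ([read_label_image()]).
#'
#' @param masks list of masks; each either a logical/0-1 matrix congruent
#'   with the image, or a sorted integer vector of linear pixel indices.
#' @param dim image dimensions `c(nrow, ncol)`; required when masks are
#'   index vectors.
#' @param scores optional numeric vector of per-mask confidences in
#'   \[0, 1\], aligned 1:1 with `masks`.
#' @param source one of `"annotation"`, `"prediction"`, `"simulation"`.
#' @return An object of class `instance_set`.
#' @export
instance_set <- function(masks, dim = NULL, scores = NULL,
                         source = c("annotation", "prediction", "simulation")) {
  source <- match.arg(source)
  if (length(masks) > 0 && is.matrix(masks[[1]])) {
    dims <- dim(masks[[1]])
    idx <- lapply(masks, function(m) {
      abort_if(!identical(base::dim(m), dims), "masks must share one shape")
      which(m != 0)
    })
  } else {
    abort_if(is.null(dim), "`dim` is required when masks are index vectors")
    dims <- as.integer(dim)
    npix <- prod(dims)
    idx <- lapply(masks, function(v) {
      v <- sort(unique(as.integer(v)))
      abort_if(length(v) > 0 && (v[1] < 1 || v[length(v)] > npix),
               "mask indices outside the image")
      v
    })
  }
  abort_if(any(vapply(idx, length, 1L) == 0L) && length(idx) > 0,
           "every mask must be non-empty")
  if (!is.null(scores)) {
    abort_if(length(scores) != length(idx),
             "`scores` must align 1:1 with masks")
    abort_if(any(!is.finite(scores)) || any(scores < 0 | scores > 1),
             "`scores` must lie in [0, 1]")
    scores <- as.numeric(scores)
  }
  structure(list(masks = idx, dim = dims, scores = scores, source = source),
            class = "instance_set")
}

#' @export
print.instance_set <- function(x, ...) {
  cat(sprintf("<instance_set: %d masks on %d x %d grid, source=%s%s>\n",
              length(x$masks), x$dim[1], x$dim[2], x$source,
              if (is.null(x$scores)) "" else ", scored"))
  invisible(x)
}

#' @export
length.instance_set <- function(x) length(x$masks)

#' Number of instances in a set
#' @param x an [instance_set()].
#' @return integer count.
#' @export
n_instances <- function(x) length(x$masks)

#' Pixel areas of all masks
#' @param x an [instance_set()].
#' @return integer vector of mask areas in pixels^2.
#' @export
instance_areas <- function(x) vapply(x$masks, length, 1L)

#' Materialise one mask as a logical matrix
#' @param x an [instance_set()].
#' @param i mask index.
#' @return logical matrix congruent with the parent image.
#' @export
instance_mask <- function(x, i) {
  m <- matrix(FALSE, x$dim[1], x$dim[2])
  m[x$masks[[i]]] <- TRUE
  m
}

#' Subset an instance set
#'
#' Keeps masks `i` (and their scores), preserving order.
#' @param x an [instance_set()].
#' @param i integer or logical index vector.
#' @return An [instance_set()].
#' @export
instance_subset <- function(x, i) {
  structure(list(masks = x$masks[i], dim = x$dim,
                 scores = if (is.null(x$scores)) NULL else x$scores[i],
                 source = x$source),
            class = "instance_set")
}

#' Flatten an instance set to a label matrix
#'
#' Pixels of mask `k` are set to `k`; background is 0. Overlapping masks
#' cannot be represented this way, so overlaps raise an error unless
#' `overlap = "last"`, in which case later masks win.
#' @param x an [instance_set()].
#' @param overlap `"error"` or `"last"`.
#' @return integer label matrix.
#' @export
instance_labels <- function(x, overlap = c("error", "last")) {
  overlap <- match.arg(overlap)
  lab <- matrix(0L, x$dim[1], x$dim[2])
  for (k in seq_along(x$masks)) {
    if (overlap == "error" && any(lab[x$masks[[k]]] != 0L)) {
      stop("masks overlap; a flat label image cannot represent them",
           call. = FALSE)
    }
    lab[x$masks[[k]]] <- k
  }
  lab
}

#' Build an instance set from an integer label matrix
#'
#' One mask per distinct positive label, in increasing label order.
#' An all-zero label matrix yields an empty set.
#' @param lab integer matrix, 0 = background, k = instance k.
#' @inheritParams instance_set
#' @return An [instance_set()].
#' @export
labels_to_instances <- function(lab, source = "annotation") {
  abort_if(!is.matrix(lab), "`lab` must be a matrix")
  abort_if(any(lab < 0), "label images must not contain negative labels")
  labs <- sort(unique(lab[lab > 0]))
  masks <- lapply(labs, function(l) which(lab == l))
  instance_set(masks, dim = dim(lab), source = source)
}

#' Read instance masks from a flat label image
#'
#' Expects an integer-valued TIFF or PNG where 0 is background and each
#' positive value labels one instance. Label order is preserved.
#' @param path file path.
#' @inheritParams instance_set
#' @return An [instance_set()] (possibly empty).
#' @export
read_label_image <- function(path, source = "annotation") {
  ext <- tolower(tools::file_ext(path))
  lab <- switch(ext,
    "tif" = ,
    "tiff" = tiff::readTIFF(path, as.is = TRUE),
    "png" = round(png::readPNG(path) * 255),
    stop("unsupported label image format: ", ext, call. = FALSE)
  )
  abort_if(length(dim(lab)) != 2, "label image is not 2-D")
  labels_to_instances(matrix(as.integer(round(lab)), nrow(lab), ncol(lab)),
                      source = source)
}

#' Write an instance set as a flat label image
#' @param x an [instance_set()] with non-overlapping masks.
#' @param path output path (TIFF or PNG; 16-bit to allow many labels).
#' @return `path`, invisibly.
#' @export
write_label_image <- function(x, path) {
  lab <- instance_labels(x)
  abort_if(max(lab) > 65535, "more than 65535 instances")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "tif" = ,
    "tiff" = tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L),
    "png" = png::writePNG(lab / 65535, path),
    stop("unsupported label image format: ", ext, call. = FALSE)
  )
  invisible(path)
}

#' Read instance masks from a multi-page TIFF
#'
#' One binary page per instance; this is the canonical mask format since
#' it can represent overlapping instances.
#' @param path multi-page TIFF path.
#' @inheritParams instance_set
#' @return An [instance_set()].
#' @export
read_instance_masks <- function(path, source = "annotation") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  masks <- lapply(pages, function(p) {
    abort_if(length(dim(p)) != 2, "mask pages must be single-channel")
    p != 0
  })
  instance_set(masks, source = source)
}

#' Write an instance set as a multi-page TIFF (one binary page per mask)
#' @param x an [instance_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instance_masks <- function(x, path) {
  abort_if(length(x$masks) == 0, "cannot write an empty instance set")
  pages <- lapply(seq_along(x$masks), function(i) {
    m <- matrix(0, x$dim[1], x$dim[2])
    m[x$masks[[i]]] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
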