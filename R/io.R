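#' Load a single-channel image from PNG or TIFF
#'
#' 8/16-bit images are mapped to `[0, 1]` (the png and tiff readers divide
#' by 255 / 65535); multi-channel images are converted to luma with
#' [rgb_to_gray()].
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return gray image matrix.
#' @export
load_gray_image <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read missing file ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("I/O error: unsupported image format '", ext, "' for ", path))
  as_gray_image(img)
}

#' Write a gray image as PNG
#'
#' @param img gray image matrix with values in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Load a labeled image dataset
#'
#' Accepts either a directory with one sub-directory per class, or a CSV
#' manifest with columns `path,label`. Ordering is deterministic
#' (lexicographic); labels are assigned by sorted class-name order, starting
#' at 0. Empty class directories are excluded with a warning; a manifest row
#' pointing to a missing file is an error naming that path.
#'
#' @param root class-directory root, or path to a CSV manifest.
#' @param split `"train"` or `"test"` (metadata only).
#' @return a `labeled_dataset` (see [gen_texture_dataset()]).
#' @export
load_image_dataset <- function(root, split = c("train", "test")) {
  split <- match.arg(split)
  exts <- "\\.(png|tif|tiff)$"
  if (dir.exists(root)) {
    classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
    files <- list(); class_names <- character()
    for (cl in classes) {
      fs <- sort(list.files(file.path(root, cl), pattern = exts,
                            ignore.case = TRUE, full.names = TRUE))
      if (length(fs) == 0L) {
        warning("excluding empty class directory: ", cl)
        next
      }
      class_names <- c(class_names, cl)
      files[[cl]] <- fs
    }
    if (length(files) == 0L) stop("no images found under ", root)
    paths <- unlist(files, use.names = FALSE)
    labels <- rep(seq_along(files) - 1L, lengths(files))
  } else if (file.exists(root)) {
    man <- utils::read.csv(root, stringsAsFactors = FALSE)
    if (!all(c("path", "label") %in% names(man))) {
      stop("manifest must have columns 'path' and 'label'")
    }
    man$path <- ifelse(file.exists(man$path), man$path,
                       file.path(dirname(root), man$path))
    class_names <- sort(unique(as.character(man$label)))
    labels <- match(as.character(man$label), class_names) - 1L
    paths <- man$path
  } else {
    stop("I/O error: no such dataset root or manifest: ", root)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("I/O error: manifest references missing file ", missing[1L])
  }
  images <- lapply(paths, load_gray_image)
  structure(list(images = images, labels = labels, paths = paths,
                 class_names = class_names, split = split),
            class = "labeled_dataset")
}

#' Task-profile preprocessing
#'
#' Standard input conventions: profile `"cell"` resizes to 128 x 128
#' (fluorescence cell images); `"cloud"` converts to luma and resizes to
#' 280 x 280 (all-sky images, to allow 256 x 256 training crops);
#' `"mouth"` center-crops to 88 x 88 (lip-reading frames). A custom profile
#' is a list with optional `resize` and `center_crop` side lengths.
#' Resizing is bilinear.
#'
#' @param img gray matrix or RGB array.
#' @param profile `"cell"`, `"cloud"`, `"mouth"`, or a list.
#' @return gray image matrix.
#' @export
preprocess_image <- function(img, profile = c("cell", "cloud", "mouth")) {
  if (is.character(profile)) {
    profile <- switch(match.arg(profile),
      cell = list(resize = 128L),
      cloud = list(resize = 280L),
      mouth = list(center_crop = 88L))
  }
  img <- as_gray_image(img)
  if (!is.null(profile$resize)) {
    s <- as.integer(profile$resize)
    if (nrow(img) != s || ncol(img) != s) {
      img <- resize_bilinear(img, s, s)
    }
  }
  if (!is.null(profile$center_crop)) {
    cs <- as.integer(profile$center_crop)
    if (cs > nrow(img) || cs > ncol(img)) {
      stop("range error: crop ", cs, " exceeds image size")
    }
    r0 <- (nrow(img) - cs) %/% 2L + 1L
    c0 <- (ncol(img) - cs) %/% 2L + 1L
    img <- img[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L), drop = FALSE]
  }
  img
}

#' Bilinear resize
#'
#' Thin wrapper over `EBImage::resize` (bilinear filter).
#'
#' @param img gray image matrix.
#' @param h,w target rows and columns.
#' @return resized matrix.
#' @export
resize_bilinear <- function(img, h, w) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("EBImage is required for resizing")
  }
  out <- EBImage::resize(img, w = h, h = w)   # EBImage's first dim = rows here
  matrix(as.numeric(out), h, w)
}

#' Map a frame sequence to a SIFT-image sequence
#'
#' Applies [compute_sift_image()] to every frame; the sequence length is
#' preserved.
#'
#' @param frames list of gray image matrices (a fixed-length grayscale frame
#'   sequence, e.g. 29 frames for word-level lip reading), or a list with a
#'   `frames` element.
#' @param cfg a [dense_sift_config()].
#' @return list of `sift_image` arrays.
#' @export
sequence_to_sift <- function(frames, cfg = dense_sift_config()) {
  if (!is.null(frames$frames)) frames <- frames$frames
  if (length(frames) == 0L) stop("empty input: no frames")
  lapply(frames, compute_sift_image, cfg = cfg)
}

## ---- SIFT-image cache container ------------------------------------------

config_id <- function(cfg) {
  paste(cfg$patch_size, cfg$cells_per_side, cfg$orientation_bins, cfg$stride,
        cfg$boundary_mode, cfg$normalization, cfg$clip_threshold,
        as.integer(cfg$orientation_normalized), as.integer(cfg$soft_binning),
        sep = "|")
}

#' Write SIFT images to a cache container
#'
#' Stores named SIFT images as float32 payloads in a single file, together
#' with the descriptor configuration; a round trip through the container is
#' bitwise stable at float32 precision.
#'
#' @param sift_images named list of `sift_image` arrays (or plain numeric
#'   arrays).
#' @param path output file.
#' @param cfg the [dense_sift_config()] the images were computed with.
#' @return `path`, invisibly.
#' @export
write_sift_container <- function(sift_images, path, cfg = dense_sift_config()) {
  stopifnot(is.list(sift_images), length(names(sift_images)) == length(sift_images))
  entries <- lapply(sift_images, function(s) {
    list(dim = dim(s), bytes = writeBin(as.vector(s), raw(), size = 4L,
                                        endian = "little"))
  })
  obj <- list(format = "siftcnn-container-v1", config = unclass(cfg),
              config_id = config_id(cfg), entries = entries)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a SIFT-image cache container
#'
#' @param path container file written by [write_sift_container()].
#' @return list with `config` (a `dense_sift_config`), `config_id`, and
#'   `images` (named list of float32-precision arrays).
#' @export
read_sift_container <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "siftcnn-container-v1")) {
    stop("I/O error: ", path, " is not a SIFT-image container")
  }
  images <- lapply(obj$entries, function(e) {
    array(readBin(e$bytes, numeric(), n = prod(e$dim), size = 4L,
                  endian = "little"), dim = e$dim)
  })
  cfg <- obj$config
  class(cfg) <- "dense_sift_config"
  list(config = cfg, config_id = obj$config_id, images = images)
}

#' Write a dataset as PNG files plus a CSV manifest
#'
#' @param dataset a `labeled_dataset`.
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_dataset_png <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- data.frame(path = character(), label = character())
  for (i in seq_along(dataset$images)) {
    cl <- dataset$class_names[dataset$labels[i] + 1L]
    sub <- file.path(dir, cl)
    dir.create(sub, showWarnings = FALSE)
    fn <- file.path(sub, sprintf("img_%04d.png", i))
    write_gray_png(dataset$images[[i]], fn)
    rows <- rbind(rows, data.frame(path = fn, label = cl))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(rows, manifest, row.names = FALSE)
  invisible(manifest)
}
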