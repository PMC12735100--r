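# Reading image-folder datasets. Layout: one subfolder per class, named
# "<classId>_<species>", holding PNG (or JPEG, via EBImage) files.

.readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG reading requires the EBImage package: ", path)
    }
    a <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(a)) == 2L) a else aperm(a, c(2L, 1L, 3L))
  } else {
    stop("unsupported image format '", ext, "': ", path)
  }
  d <- dim(img)
  if (length(d) == 2L) img <- array(rep(img, 3L), dim = c(d, 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3L] == 1L) {
    img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  }
  img
}

.resizeNearest <- function(img, height, width) {
  d <- dim(img)
  if (d[1L] == height && d[2L] == width) return(img)
  ri <- pmin(d[1L], pmax(1L, round((seq_len(height) - 0.5) * d[1L] / height + 0.5)))
  ci <- pmin(d[2L], pmax(1L, round((seq_len(width) - 0.5) * d[2L] / width + 0.5)))
  img[ri, ci, , drop = FALSE]
}

#' List a class-per-folder image dataset
#'
#' Scans `root` for class subfolders, orders folders and files
#' lexicographically (so repeated listings are identical), and parses the
#' `<classId>_<species>` folder naming convention; folders without a
#' numeric prefix get sequential ids in folder order. Optionally writes the
#' stable class-index assignment to a labels JSON.
#'
#' @param root dataset root directory.
#' @param labelsOut optional path for a JSON file mapping class ids to
#'   species names.
#' @return a data.frame with columns `path` (relative to `root`),
#'   `classId`, `speciesName`.
#' @export
loadImageFolder <- function(root, labelsOut = NULL) {
  if (!dir.exists(root)) stop("dataset root not found: ", root)
  dirs <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  dirs <- dirs[vapply(dirs, function(d) {
    length(list.files(file.path(root, d),
                      pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)) > 0
  }, logical(1))]
  if (!length(dirs)) stop("no class folders with images under: ", root)
  rows <- list()
  for (i in seq_along(dirs)) {
    d <- dirs[i]
    m <- regmatches(d, regexec("^([0-9]+)_(.*)$", d))[[1L]]
    if (length(m) == 3L) {
      cid <- as.integer(m[2L])
      species <- gsub("_", " ", m[3L])
    } else {
      cid <- i
      species <- d
    }
    files <- sort(list.files(file.path(root, d),
                             pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE))
    rows[[i]] <- data.frame(
      path = file.path(d, files), classId = cid, speciesName = species,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  if (!is.null(labelsOut)) {
    lab <- unique(df[, c("classId", "speciesName")])
    lab <- lab[order(lab$classId), ]
    jsonlite::write_json(
      stats::setNames(as.list(lab$speciesName), lab$classId),
      labelsOut, auto_unbox = TRUE
    )
  }
  df
}

#' Load images into a tensor
#'
#' Reads the listed image files into an `height x width x 3 x N` array of
#' values linearly scaled to `[0, 1]`, resizing (nearest neighbour) when an
#' image does not match the requested size. In strict mode an unreadable
#' file aborts with its path; otherwise it is skipped with a warning and
#' the kept row indices are attached as attribute `kept`.
#'
#' @param paths image file paths.
#' @param height,width target size.
#' @param strict abort on unreadable files?
#' @return the image array, with attribute `kept` (indices of `paths`
#'   actually loaded).
#' @export
loadImages <- function(paths, height = 64L, width = 64L, strict = TRUE) {
  imgs <- vector("list", length(paths))
  kept <- logical(length(paths))
  for (i in seq_along(paths)) {
    img <- tryCatch(.readImageFile(paths[i]), error = function(e) e)
    if (inherits(img, "error")) {
      if (strict) {
        stop("unreadable image file: ", paths[i], " (",
             conditionMessage(img), ")")
      }
      warning("skipping unreadable image file: ", paths[i])
      next
    }
    imgs[[i]] <- .resizeNearest(img, height, width)
    kept[i] <- TRUE
  }
  imgs <- imgs[kept]
  if (!length(imgs)) stop("no readable images")
  out <- array(0, dim = c(height, width, 3L, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  attr(out, "kept") <- which(kept)
  out
}
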