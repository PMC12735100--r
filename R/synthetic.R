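# Deterministic synthetic agar-plate colony images.
#
# The generator emulates the *structure* of the clinical collection the
# package targets -- 24 species classes with strongly imbalanced per-class
# counts (max 2562, min 177, total 18,221) and colony-on-blood-agar
# photographs -- not the appearance of any particular species. Colony
# morphology parameters (color, size, density, hemolysis halo, border
# roughness, texture) are invented, chosen once so that classes are
# pairwise separable and images look plate-like.

.table1Species <- c(
  "Acinetobacter baumannii", "Burkholderia cepacia", "Citrobacter freundii",
  "Hemolytic Escherichia coli", "Non-hemolytic Escherichia coli",
  "Enterobacter aerogenes", "Enterobacter cloacae",
  "Enterococcus gallinarum", "Enterococcus faecalis",
  "Enterococcus faecium", "Klebsiella oxytoca", "Klebsiella pneumoniae",
  "Morganella morganii", "Proteus mirabilis",
  "Staphylococcus saprophyticus", "Staphylococcus aureus",
  "Staphylococcus epidermidis", "Staphylococcus haemolyticus",
  "Staphylococcus hominis", "Stenotrophomonas maltophilia",
  "Streptococcus pyogenes", "Streptococcus agalactiae",
  "Streptococcus anginosus", "Streptococcus mitis"
)

.table1Counts <- c(
  535L, 272L, 337L, 1860L, 2562L, 292L, 208L, 215L, 2214L, 1013L, 882L,
  1378L, 177L, 387L, 209L, 1364L, 2078L, 311L, 527L, 306L, 199L, 265L,
  256L, 374L
)

#' Reference dataset manifest
#'
#' Per-class image counts of the 24-species clinical collection, scalable
#' for desk-size experiments. At `scale = 1` the counts are reproduced
#' verbatim (class 5 has 2562 samples, class 13 has 177; total 18,221).
#' Scaled counts use round-half-even with a floor of `minPerClass` so rare
#' classes never vanish.
#'
#' @param scale positive multiplier applied to every class count.
#' @param minPerClass lower bound on each scaled count.
#' @param seed integer seed recorded in the manifest and used by
#'   [generateDataset()] to derive per-image seeds.
#' @return a data.frame with columns `classId`, `speciesName`,
#'   `sampleCount` and attributes `scale` and `seed`.
#' @examples
#' m <- table1Manifest()
#' sum(m$sampleCount) # 18221
#' @export
table1Manifest <- function(scale = 1, minPerClass = 1L, seed = 0L) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("scale must be a positive number")
  }
  counts <- pmax(as.integer(round(scale * .table1Counts)),
                 as.integer(minPerClass))
  m <- data.frame(
    classId = seq_along(.table1Counts),
    speciesName = .table1Species,
    sampleCount = counts,
    stringsAsFactors = FALSE
  )
  attr(m, "scale") <- scale
  attr(m, "seed") <- as.integer(seed)
  m
}

#' Default colony morphology specifications
#'
#' One row per class: colony color (RGB in `[0, 1]`), mean/spread of colony
#' radius (pixels on a 224-pixel reference canvas; scaled linearly with
#' image size), mean/spread of colonies per plate, hemolysis-halo flag with
#' ring width and color, border roughness amplitude and texture grain. The
#' 24 rows are pairwise distinct in at least two parameters so every pair
#' of classes carries a learnable signal.
#'
#' @return a 26-column data.frame with 24 rows.
#' @export
defaultClassSpecs <- function() {
  col <- matrix(c(
    0.82, 0.80, 0.74,   # 1 pale gray
    0.95, 0.90, 0.58,   # 2 yellow cream
    0.70, 0.72, 0.66,   # 3 olive gray
    0.93, 0.88, 0.82,   # 4 off-white, strong beta halo
    0.75, 0.62, 0.48,   # 5 tan brown
    0.88, 0.84, 0.55,   # 6 dull yellow
    0.86, 0.77, 0.68,   # 7 beige
    0.68, 0.60, 0.58,   # 8 taupe
    0.60, 0.66, 0.60,   # 9 gray green
    0.92, 0.92, 0.88,   # 10 bright white
    0.78, 0.70, 0.40,   # 11 mustard
    0.85, 0.82, 0.78,   # 12 mucoid gray white
    0.66, 0.55, 0.45,   # 13 brown
    0.80, 0.74, 0.62,   # 14 pale tan, spreading
    0.97, 0.95, 0.90,   # 15 porcelain white
    0.95, 0.85, 0.45,   # 16 golden, beta halo
    0.90, 0.88, 0.84,   # 17 white
    0.87, 0.80, 0.72,   # 18 cream, beta halo
    0.84, 0.86, 0.80,   # 19 greenish white
    0.62, 0.70, 0.55,   # 20 green gray
    0.89, 0.86, 0.66,   # 21 tiny pale, wide halo
    0.93, 0.80, 0.70,   # 22 pinkish, halo
    0.72, 0.68, 0.50,   # 23 olive
    0.67, 0.74, 0.68    # 24 alpha greenish
  ), ncol = 3L, byrow = TRUE)
  radius <- c(14, 12, 13, 16, 18, 12, 11, 9, 15, 16, 20, 24,
              10, 26, 8, 15, 12, 11, 10, 13, 6, 9, 7, 8)
  radiusSd <- c(2, 2, 2, 3, 3, 2, 2, 1.5, 2.5, 3, 3, 4,
                2, 4, 1.5, 2.5, 2, 2, 1.5, 2, 1, 1.5, 1, 1.5)
  count <- c(6, 7, 6, 5, 4, 8, 8, 9, 5, 5, 4, 3,
             9, 3, 12, 6, 8, 9, 10, 7, 14, 11, 13, 12)
  countSd <- c(1.5, 2, 1.5, 1, 1, 2, 2, 2, 1, 1, 1, 0.8,
               2, 0.8, 3, 1.5, 2, 2, 2.5, 2, 3, 2.5, 3, 3)
  halo <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
            FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
            FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  haloWidth <- c(0, 0, 0, 7, 0, 0, 0, 0, 0, 0, 0, 0,
                 0, 0, 0, 5, 0, 4, 0, 0, 9, 5, 0, 4)
  # beta hemolysis clears the agar to a translucent amber; alpha greens it
  haloCol <- matrix(rep(c(0.72, 0.45, 0.30), 24L), ncol = 3L, byrow = TRUE)
  haloCol[24L, ] <- c(0.42, 0.50, 0.30)
  rough <- c(0.10, 0.05, 0.18, 0.08, 0.06, 0.22, 0.12, 0.05, 0.08, 0.06,
             0.04, 0.03, 0.25, 0.35, 0.05, 0.07, 0.06, 0.10, 0.08, 0.15,
             0.05, 0.06, 0.20, 0.12)
  grain <- c(0.03, 0.02, 0.05, 0.02, 0.06, 0.04, 0.03, 0.05, 0.02, 0.03,
             0.01, 0.01, 0.06, 0.04, 0.02, 0.03, 0.02, 0.04, 0.03, 0.07,
             0.02, 0.03, 0.05, 0.04)
  data.frame(
    classId = 1:24, speciesName = .table1Species,
    radiusMean = radius, radiusSd = radiusSd,
    countMean = count, countSd = countSd,
    colR = col[, 1L], colG = col[, 2L], colB = col[, 3L],
    halo = halo, haloWidth = haloWidth,
    haloR = haloCol[, 1L], haloG = haloCol[, 2L], haloB = haloCol[, 3L],
    borderRoughness = rough, textureGrain = grain,
    stringsAsFactors = FALSE
  )
}

.clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Render one synthetic agar-plate image
#'
#' A pure function of `(spec, height, width, seed)`: the same arguments
#' always produce byte-identical images. The scene is a blood-agar dish on
#' a dark bench with a mild illumination gradient; colonies are placed
#' quasi-uniformly inside the dish with per-colony radius jitter, a
#' radially perturbed border, dome shading, optional hemolysis ring and
#' multiplicative texture grain, plus additive sensor noise. Pixel values
#' are quantized to the 8-bit grid so a PNG round trip is exact.
#'
#' @param spec one row of [defaultClassSpecs()] (or a list with the same
#'   fields).
#' @param height,width image sides in pixels, at least 32.
#' @param seed integer seed.
#' @return an `height x width x 3` array in `[0, 1]`.
#' @export
renderPlateImage <- function(spec, height = 224L, width = 224L, seed = 1L) {
  if (height < 32L || width < 32L) {
    stop("image sides must be at least 32 pixels")
  }
  spec <- as.list(spec)
  old <- .saveRNG()
  on.exit(.restoreRNG(old), add = TRUE)
  set.seed(seed)

  h <- as.integer(height)
  w <- as.integer(width)
  sc <- min(h, w) / 224
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  pr <- 0.47 * min(h, w)

  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  dplate <- sqrt((yy - cy)^2 + (xx - cx)^2)

  ang <- stats::runif(1, 0, 2 * pi)
  illum <- 1 + 0.12 * (((xx - cx) / w) * cos(ang) + ((yy - cy) / h) * sin(ang))
  rim <- 1 - 0.18 * .clip01((dplate / pr)^6)
  agar <- c(0.55, 0.17, 0.15)
  bench <- c(0.10, 0.10, 0.11)

  img <- array(0, dim = c(h, w, 3L))
  inplate <- .clip01((pr - dplate) / 1.5)
  for (ch in 1:3) {
    img[, , ch] <- bench[ch] * (1 - inplate) + agar[ch] * illum * rim * inplate
  }

  ncol <- max(1L, as.integer(round(stats::rnorm(1, spec$countMean,
                                                spec$countSd))))
  baseCol <- c(spec$colR, spec$colG, spec$colB)
  haloCol <- c(spec$haloR %||% 0.7, spec$haloG %||% 0.45,
               spec$haloB %||% 0.3)
  hw <- (spec$haloWidth %||% 0) * sc

  for (k in seq_len(ncol)) {
    rc <- pr * 0.72 * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    py <- cy + rc * sin(th)
    px <- cx + rc * cos(th)
    r0 <- max(2, stats::rnorm(1, spec$radiusMean * sc, spec$radiusSd * sc))
    ph <- stats::runif(3, 0, 2 * pi)
    jit <- stats::rnorm(3, 1, 0.04)

    ext <- ceiling(r0 * (1 + spec$borderRoughness) +
                     (if (isTRUE(spec$halo)) hw else 0) + 3)
    r1 <- max(1L, floor(py - ext)); r2 <- min(h, ceiling(py + ext))
    c1 <- max(1L, floor(px - ext)); c2 <- min(w, ceiling(px + ext))
    if (r1 > r2 || c1 > c2) next
    ly <- matrix(r1:r2, r2 - r1 + 1L, c2 - c1 + 1L)
    lx <- matrix(c1:c2, r2 - r1 + 1L, c2 - c1 + 1L, byrow = TRUE)
    dd <- sqrt((ly - py)^2 + (lx - px)^2)
    aa <- atan2(ly - py, lx - px)
    redge <- r0 * (1 + spec$borderRoughness *
                     (0.6 * sin(3 * aa + ph[1]) + 0.3 * sin(5 * aa + ph[2]) +
                        0.1 * sin(7 * aa + ph[3])))

    sub <- img[r1:r2, c1:c2, , drop = FALSE]
    if (isTRUE(spec$halo) && hw > 0) {
      ha <- 0.55 * .clip01((redge + hw - dd) / (0.3 * hw + 0.5)) *
        .clip01((dd - redge) / (0.2 * hw + 0.5))
      for (ch in 1:3) {
        sub[, , ch] <- sub[, , ch] * (1 - ha) + haloCol[ch] * ha
      }
    }
    alpha <- 0.95 * .clip01((redge - dd) / (0.12 * r0 + 0.5))
    dome <- 1 + 0.25 * .clip01(1 - (dd / pmax(redge, 1e-6))^2)
    spk <- 1 + spec$textureGrain *
      matrix(stats::rnorm(length(dd)), nrow(dd), ncol(dd))
    for (ch in 1:3) {
      colcol <- .clip01(baseCol[ch] * jit[ch])
      sub[, , ch] <- sub[, , ch] * (1 - alpha) +
        (colcol * dome * spk) * alpha
    }
    img[r1:r2, c1:c2, ] <- sub
  }

  img <- img + array(stats::rnorm(h * w * 3L, 0, 0.008), dim = c(h, w, 3L))
  round(.clip01(img) * 255) / 255
}

.stableSeed <- function(globalSeed, classId, index) {
  m <- 2147483647
  s <- ((globalSeed %% m) * 48271) %% m
  s <- (s + classId * 69621 + index * 7919) %% m
  as.integer(s)
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes a class-per-folder PNG layout
#' (`<outDir>/<classId>_<species>/<index>.png`) plus a `manifest.csv` with
#' columns `path`, `class_id`, `species_name`, `seed`. Each image's seed is
#' derived deterministically from `(attr(manifest, "seed"), classId,
#' index)`, so regeneration is byte-identical and adding classes never
#' perturbs existing images.
#'
#' @param manifest a [table1Manifest()]-style data.frame (its `seed`
#'   attribute drives all randomness).
#' @param specs a [defaultClassSpecs()]-style data.frame covering every
#'   manifest class.
#' @param outDir output directory (created if needed).
#' @param imageSize side length of the square images, >= 32.
#' @return the manifest data.frame that was written, invisibly.
#' @export
generateDataset <- function(manifest, specs, outDir, imageSize = 64L) {
  missing <- setdiff(manifest$classId, specs$classId)
  if (length(missing)) {
    stop("no morphology spec for class id(s): ",
         paste(missing, collapse = ", "))
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  gseed <- attr(manifest, "seed") %||% 0L
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    cid <- manifest$classId[i]
    species <- manifest$speciesName[i]
    spec <- specs[specs$classId == cid, , drop = FALSE][1L, ]
    folder <- sprintf("%02d_%s", cid, gsub("[^A-Za-z0-9]+", "_", species))
    dir.create(file.path(outDir, folder), showWarnings = FALSE)
    for (j in seq_len(manifest$sampleCount[i])) {
      s <- .stableSeed(gseed, cid, j)
      img <- renderPlateImage(spec, imageSize, imageSize, s)
      rel <- file.path(folder, sprintf("%05d.png", j))
      png::writePNG(img, file.path(outDir, rel))
      rows[[length(rows) + 1L]] <- data.frame(
        path = rel, class_id = cid, species_name = species, seed = s,
        stringsAsFactors = FALSE
      )
    }
  }
  mf <- do.call(rbind, rows)
  utils::write.csv(mf, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(mf)
}
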