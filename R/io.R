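# On-disk formats.
#
# Images are 8-bit grayscale PNG ([0,1] mapped to [0,255]).  Each image has
# a CSV annotation (columns point_index, x, y; 0-based pixel coordinates)
# and a JSON sidecar with label, seed and the generating spec.  Datasets
# carry a JSON manifest.  All rectangles written to disk use the package's
# 0-based half-open convention.

#' Write an annotated image to disk
#'
#' Emits `<name>.png`, `<name>.csv` (ordered boundary points) and
#' `<name>.json` (label, seed, generating spec) into `dir`.
#'
#' @param img an [AnnotatedImage-class].
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @return invisibly, the paths written.
#' @seealso [readAnnotatedImage()]
#' @export
writeAnnotatedImage <- function(img, dir, name) {
  stopifnot(methods::is(img, "AnnotatedImage"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pngPath <- file.path(dir, paste0(name, ".png"))
  csvPath <- file.path(dir, paste0(name, ".csv"))
  jsonPath <- file.path(dir, paste0(name, ".json"))
  png::writePNG(img@pixels, pngPath)
  # full 17-significant-digit rendering so coordinates survive the text
  # round-trip bit-exactly
  bp <- data.frame(point_index = seq_len(nrow(img@boundaryPoints)) - 1L,
                   x = sprintf("%.17g", img@boundaryPoints[, 1]),
                   y = sprintf("%.17g", img@boundaryPoints[, 2]))
  utils::write.csv(bp, csvPath, row.names = FALSE, quote = FALSE)
  sidecar <- list(label = img@label, seed = img@seed, spec = img@spec)
  jsonlite::write_json(sidecar, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(png = pngPath, csv = csvPath, json = jsonPath))
}

#' Read an annotated image written by [writeAnnotatedImage()]
#'
#' @param dir directory holding the triplet of files.
#' @param name file stem.
#' @return an [AnnotatedImage-class].  Pixel values are the 8-bit
#'   quantisation stored in the PNG; boundary points and the sidecar are
#'   restored bit-exactly from CSV/JSON.
#' @export
readAnnotatedImage <- function(dir, name) {
  px <- png::readPNG(file.path(dir, paste0(name, ".png")))
  if (length(dim(px)) == 3L) px <- px[, , 1]
  ann <- utils::read.csv(file.path(dir, paste0(name, ".csv")))
  ann <- ann[order(ann$point_index), , drop = FALSE]
  side <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  methods::new("AnnotatedImage",
    pixels = px,
    boundaryPoints = cbind(x = ann$x, y = ann$y),
    label = side$label, seed = as.integer(side$seed),
    spec = if (is.null(side$spec)) list() else as.list(side$spec))
}

#' Write a dataset of annotated images plus a manifest
#'
#' Images are written as `img_0001` ... with [writeAnnotatedImage()]; a
#' `manifest.json` records the dataset name, per-class counts, the file
#' list and the master seed.
#'
#' @param images list of [AnnotatedImage-class].
#' @param dir output directory.
#' @param datasetName name recorded in the manifest.
#' @param seed master seed recorded in the manifest (provenance only).
#' @return invisibly, the manifest path.
#' @export
writeDataset <- function(images, dir, datasetName = "synthetic", seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- vapply(images, lesionLabel, character(1))
  stems <- sprintf("img_%04d", seq_along(images))
  for (i in seq_along(images)) writeAnnotatedImage(images[[i]], dir, stems[i])
  manifest <- list(datasets = list(list(
    name = datasetName,
    benign = sum(labels == "benign"),
    malignant = sum(labels == "malignant"),
    source = "synthetic",
    files = stems)), seed = seed)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a dataset manifest
#'
#' @param name character vector of dataset names.
#' @param benign,malignant per-dataset class counts.
#' @param source optional source tags.
#' @param fileLists optional named list of per-dataset file vectors; when
#'   given, each length must equal the dataset total.
#' @return a [DatasetManifest-class].
#' @examples
#' m <- datasetManifest(c("A", "B"), benign = c(732, 146),
#'                      malignant = c(576, 141))
#' poolManifest(m, c("A", "B"))
#' @export
datasetManifest <- function(name, benign, malignant,
                            source = rep("unspecified", length(name)),
                            fileLists = list()) {
  methods::new("DatasetManifest",
    datasets = data.frame(name = as.character(name),
                          benign = as.integer(benign),
                          malignant = as.integer(malignant),
                          source = as.character(source),
                          stringsAsFactors = FALSE),
    fileLists = fileLists)
}

#' Pool image counts over named datasets
#'
#' Element-wise sums of the benign and malignant counts of the named
#' datasets, e.g. to size a pooled training collection.
#'
#' @param manifest a [DatasetManifest-class].
#' @param names datasets to pool; every name must exist in the manifest.
#' @return named numeric vector `c(total, benign, malignant)`.
#' @export
poolManifest <- function(manifest, names) {
  stopifnot(methods::is(manifest, "DatasetManifest"))
  d <- manifest@datasets
  if (length(names) == 0L) return(c(total = 0L, benign = 0L, malignant = 0L))
  idx <- match(names, d$name)
  if (anyNA(idx))
    stop("unknown dataset name(s): ",
         paste(names[is.na(idx)], collapse = ", "))
  b <- sum(d$benign[idx]); m <- sum(d$malignant[idx])
  c(total = b + m, benign = b, malignant = m)
}

#' Read / write a manifest as JSON
#'
#' @param manifest a [DatasetManifest-class].
#' @param path JSON file path.
#' @return `writeManifest` returns the path invisibly; `readManifest`
#'   returns a [DatasetManifest-class].
#' @export
writeManifest <- function(manifest, path) {
  d <- manifest@datasets
  entries <- lapply(seq_len(nrow(d)), function(i) {
    e <- list(name = d$name[i], benign = d$benign[i],
              malignant = d$malignant[i], source = d$source[i])
    if (d$name[i] %in% names(manifest@fileLists))
      e$files <- manifest@fileLists[[d$name[i]]]
    e
  })
  jsonlite::write_json(list(datasets = entries), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  ds <- raw$datasets
  fileLists <- list()
  for (e in ds)
    if (!is.null(e$files))
      fileLists[[e$name]] <- unlist(e$files)
  datasetManifest(
    name = vapply(ds, `[[`, character(1), "name"),
    benign = vapply(ds, function(e) as.integer(e$benign), integer(1)),
    malignant = vapply(ds, function(e) as.integer(e$malignant), integer(1)),
    source = vapply(ds, function(e)
      if (is.null(e$source)) "unspecified" else e$source, character(1)),
    fileLists = fileLists)
}
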