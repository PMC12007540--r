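#' Streamline bundle
#'
#' A bundle is an ordered set of streamlines (3D polylines in world mm, RAS)
#' representing one white matter pathway, together with the reference grid of
#' the space it lives in.
#'
#' @param streamlines list of N x 3 numeric matrices (N >= 2 per streamline),
#'   world mm coordinates.
#' @param grid a [reference_grid()], or `NULL` if no grid is attached yet.
#' @param name pathway label.
#' @param metadata optional named list carried along (e.g. analytic geometry
#'   of synthetic bundles).
#' @return An object of class `streamline_bundle`.
#' @export
streamline_bundle <- function(streamlines, grid = NULL, name = "bundle",
                              metadata = list()) {
  if (!is.list(streamlines) || length(streamlines) == 0L)
    stop("empty bundle: at least one streamline is required")
  streamlines <- lapply(streamlines, as_points_matrix)
  for (i in seq_along(streamlines)) {
    s <- streamlines[[i]]
    if (nrow(s) < 2L) stop("streamline ", i, " has fewer than 2 points")
    if (!all(is.finite(s))) stop("streamline ", i, " has non-finite points")
    if (polyline_length(s) <= 0) stop("streamline ", i, " has zero arc length")
  }
  if (!is.null(grid) && !inherits(grid, "reference_grid"))
    stop("grid must be a reference_grid")
  structure(list(streamlines = streamlines, grid = grid, name = name,
                 metadata = metadata),
            class = "streamline_bundle")
}

#' @export
print.streamline_bundle <- function(x, ...) {
  npts <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("Streamline bundle '%s': %d streamlines, %d points\n",
              x$name, length(x$streamlines), sum(npts)))
  invisible(x)
}

polyline_length <- function(pts) {
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

#' Load a tractogram (TRK or TCK)
#'
#' Reads a TrackVis `.trk` or MRtrix `.tck` tractogram and returns the
#' streamlines in world mm RAS. TRK files store coordinates in voxel-scaled
#' ("voxmm") space with a half-voxel corner offset; these are converted
#' through the file's stored voxel-to-world affine at load, so the internal
#' representation is always world mm. TCK files already store world mm but
#' carry no grid, so a `grid_hint` is attached when given.
#'
#' @param path file path ending in `.trk` or `.tck`.
#' @param grid_hint a [reference_grid()] to attach when the format does not
#'   carry one (TCK), or to override an unusable stored affine.
#' @param name pathway label; defaults to the file name.
#' @return A [streamline_bundle()].
#' @export
load_tractogram <- function(path, grid_hint = NULL, name = NULL) {
  if (!file.exists(path)) stop("cannot read tractogram: ", path)
  if (is.null(name)) name <- sub("\\.(trk|tck)$", "", basename(path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = read_trk(path, grid_hint = grid_hint, name = name),
         tck = read_tck(path, grid_hint = grid_hint, name = name),
         stop("unsupported tractogram format: .", ext, " (need .trk or .tck)"))
}

#' Write a tractogram
#'
#' @param bundle a [streamline_bundle()].
#' @param path output path ending in `.trk` or `.tck`. TRK requires the
#'   bundle to carry a grid (the affine is stored in the header).
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(bundle, path) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = write_trk(bundle, path),
         tck = write_tck(bundle, path),
         stop("unsupported tractogram format: .", ext))
  invisible(path)
}

## ---- TCK (MRtrix): ASCII header, float32 LE triples, NaN-separated ----

read_tck <- function(path, grid_hint = NULL, name = "bundle") {
  raw <- readBin(path, "raw", n = file.size(path))
  hdr_end <- grepRaw("END\n", raw, fixed = TRUE)
  if (length(hdr_end) == 0L) stop("truncated TCK header (no END): ", path)
  head_txt <- rawToChar(raw[seq_len(hdr_end + 3L)])
  if (!startsWith(head_txt, "mrtrix tracks"))
    stop("not a TCK file (missing 'mrtrix tracks' magic): ", path)
  m <- regmatches(head_txt, regexpr("file:\\s*\\.\\s*[0-9]+", head_txt))
  if (length(m) == 0L) stop("truncated TCK header (no file offset): ", path)
  offset <- as.integer(sub(".*?([0-9]+)$", "\\1", m))
  if (grepl("datatype:", head_txt) && !grepl("datatype:\\s*Float32LE", head_txt))
    stop("unsupported TCK datatype (only Float32LE)")
  nfl <- (length(raw) - offset) %/% 4L
  if (nfl < 3L) stop("truncated TCK file: ", path)
  vals <- readBin(raw[(offset + 1L):(offset + 4L * nfl)], "numeric",
                  n = nfl, size = 4L, endian = "little")
  pts <- matrix(vals[seq_len(3L * (length(vals) %/% 3L))], ncol = 3,
                byrow = TRUE)
  is_sep <- is.nan(pts[, 1])
  is_end <- is.infinite(pts[, 1])
  stream_id <- cumsum(is_sep) + 1L
  keep <- !is_sep & !is_end & !cumsum(is_end)
  if (!any(keep)) stop("empty bundle: ", path)
  sl <- split.data.frame(pts[keep, , drop = FALSE], stream_id[keep])
  sl <- lapply(unname(sl), function(p) {
    rownames(p) <- NULL
    p
  })
  streamline_bundle(sl, grid = grid_hint, name = name)
}

write_tck <- function(bundle, path) {
  n <- length(bundle$streamlines)
  base <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n,
                 "\nfile: . ")
  offset <- nchar(base) + 8L
  repeat {
    total <- nchar(base) + nchar(as.character(offset)) + nchar("\nEND\n")
    if (total == offset) break
    offset <- total
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(base, offset, "\nEND\n")), con)
  sep <- c(NaN, NaN, NaN)
  dat <- unlist(lapply(bundle$streamlines,
                       function(s) c(t(s), sep)), use.names = FALSE)
  dat <- c(dat, c(Inf, Inf, Inf))
  writeBin(dat, con, size = 4L, endian = "little")
  invisible(path)
}

## ---- TRK (TrackVis v2): 1000-byte header, voxmm coordinates ----

read_trk <- function(path, grid_hint = NULL, name = "bundle") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (rawToChar(magic[1:5]) != "TRACK")
    stop("not a TRK file (missing TRACK magic): ", path)
  dims <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  voxel_size <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")  # origin, unused
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  n_properties <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  vox2ras <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                    4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L)
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # version
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(hdr_size, 1000L)) stop("corrupt TRK header (hdr_size != 1000)")

  if (all(vox2ras == 0)) {
    if (is.null(grid_hint))
      stop("TRK file stores no voxel-to-world affine; supply grid_hint")
    grid <- grid_hint
  } else {
    grid <- reference_grid(vox2ras, pmax(dims, 1L))
  }
  vs <- grid$voxel_sizes
  sl <- list()
  repeat {
    npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(npts) == 0L) break
    if (npts < 1L) stop("truncated TRK body: ", path)
    vals <- readBin(con, "numeric", npts * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (length(vals) < npts * (3L + n_scalars)) stop("truncated TRK body: ", path)
    if (n_properties > 0L) readBin(con, "numeric", n_properties, size = 4L,
                                   endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    # voxmm -> continuous voxel (corner origin, half-voxel shift) -> world
    vox <- sweep(m, 2L, vs, "/") - 0.5
    sl[[length(sl) + 1L]] <- voxel_to_world(grid, vox)
    if (n_count > 0L && length(sl) == n_count) break
  }
  if (length(sl) == 0L) stop("empty bundle: ", path)
  streamline_bundle(sl, grid = grid, name = name)
}

write_trk <- function(bundle, path) {
  grid <- bundle$grid
  if (is.null(grid))
    stop("TRK output requires a bundle with a reference grid")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)
  writeBin(as.integer(grid$dims), con, size = 2L, endian = "little")
  writeBin(as.numeric(grid$voxel_sizes), con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")        # origin
  writeBin(0L, con, size = 2L, endian = "little")                 # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L, endian = "little")                 # n_properties
  writeBin(raw(200L), con)
  writeBin(as.numeric(t(grid$affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                        # reserved
  writeBin(c(charToRaw("RAS"), as.raw(0L)), con)                  # voxel_order
  writeBin(raw(4L), con)                                          # pad2
  writeBin(numeric(6L), con, size = 4L, endian = "little")        # IOP
  writeBin(raw(2L), con)                                          # pad1
  writeBin(raw(6L), con)                                          # invert/swap
  writeBin(length(bundle$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")                 # version
  writeBin(1000L, con, size = 4L, endian = "little")
  vs <- grid$voxel_sizes
  for (s in bundle$streamlines) {
    writeBin(nrow(s), con, size = 4L, endian = "little")
    vox <- world_to_voxel(grid, s)
    voxmm <- sweep(vox + 0.5, 2L, vs, "*")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

## ---- NIfTI scalar volumes ----

#' Scalar volume
#'
#' A 3D scalar map (e.g. FA, MD, or a voxelized cortical-feature map) on a
#' reference grid. Missing values are encoded as `NA` and propagate through
#' every sampling operation.
#'
#' @param values 3D numeric array with `dim(values) == grid$dims`.
#' @param grid a [reference_grid()].
#' @param feature_name label for the mapped quantity.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, grid, feature_name = "scalar") {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (!identical(as.integer(dim(values)), grid$dims))
    stop("values shape ", paste(dim(values), collapse = "x"),
         " does not match grid dims ", paste(grid$dims, collapse = "x"))
  structure(list(values = values, grid = grid, feature_name = feature_name),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("Scalar volume '%s': %s voxels, range [%g, %g]\n",
              x$feature_name, paste(dim(x$values), collapse = " x "),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Load a 3D NIfTI scalar volume
#'
#' Values and the stored voxel-to-world affine are exposed unchanged; no
#' resampling is performed. 4D inputs and non-invertible affines are errors.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param feature_name label; defaults to the file name.
#' @return A [scalar_volume()].
#' @export
load_scalar_volume <- function(path, feature_name = NULL) {
  if (is.null(feature_name))
    feature_name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D: ", path)
  aff <- unclass(RNifti::xform(img))
  if (abs(det(aff)) < .Machine$double.eps * 100)
    stop("non-invertible affine in ", path)
  grid <- reference_grid(aff, d)
  scalar_volume(array(as.numeric(img), dim = d), grid, feature_name)
}

#' Write a scalar volume to NIfTI
#'
#' @param volume a [scalar_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @export
write_scalar_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  img <- RNifti::asNifti(volume$values)
  img <- RNifti::`sform<-`(img, structure(volume$grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---- Feature tables ----

COHORT_LEVELS <- c("infant", "development", "young_adult", "aging")

FEATURE_TABLE_COLUMNS <- c("subject_id", "session_id", "cohort", "age",
                           "sex", "pathway", "feature", "value")

#' Validate a long-format lifespan feature table
#'
#' The canonical tabular exchange format: one row per
#' (session, pathway, feature) with columns `subject_id, session_id, cohort,
#' age, sex, pathway, feature, value`. Cohorts are restricted to
#' `infant`, `development`, `young_adult`, `aging`; sex to `F`/`M`; ages are
#' non-negative; the (session, pathway, feature) key is unique. Missing
#' feature values are `NA`.
#'
#' @param table data.frame with the columns above.
#' @return the validated data.frame (character columns normalised).
#' @export
validate_feature_table <- function(table) {
  missing_cols <- setdiff(FEATURE_TABLE_COLUMNS, names(table))
  if (length(missing_cols) > 0L)
    stop("feature table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  table <- as.data.frame(table)
  for (col in c("subject_id", "session_id", "cohort", "sex", "pathway",
                "feature"))
    table[[col]] <- as.character(table[[col]])
  bad <- setdiff(unique(table$cohort), COHORT_LEVELS)
  if (length(bad) > 0L)
    stop("unknown cohort label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(COHORT_LEVELS, collapse = ", "))
  bad_sex <- setdiff(unique(table$sex), c("F", "M"))
  if (length(bad_sex) > 0L)
    stop("sex must be F or M, got: ", paste(bad_sex, collapse = ", "))
  if (is.character(table$value)) table$value[!nzchar(table$value)] <- NA
  table$age <- as.numeric(table$age)
  if (any(!is.finite(table$age)) || any(table$age < 0))
    stop("ages must be finite and >= 0")
  table$value <- as.numeric(table$value)
  key <- paste(table$session_id, table$pathway, table$feature, sep = "\r")
  if (anyDuplicated(key)) {
    d <- table[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (session, pathway, feature) key: (",
         d$session_id, ", ", d$pathway, ", ", d$feature, ")")
  }
  table
}

#' Read a feature table from CSV
#'
#' @param path CSV file with header
#'   `subject_id,session_id,cohort,age,sex,pathway,feature,value`.
#' @return validated data.frame (see [validate_feature_table()]).
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  validate_feature_table(tab)
}

#' Write a feature table to CSV
#'
#' @param table a feature table (validated on write).
#' @param path output CSV path.
#' @export
write_feature_table <- function(table, path) {
  table <- validate_feature_table(table)
  utils::write.csv(table[, FEATURE_TABLE_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}
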