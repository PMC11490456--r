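#' Write a mesh as ASCII PLY
#'
#' @param mesh An [fstd_mesh()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0", "comment fstdkit surface (mm)",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, trim = TRUE, digits = 9),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' Supports the ASCII profile with vertex x/y/z leading properties and
#' triangular faces.
#'
#' @param path PLY file path.
#' @return An [fstd_mesh()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != "ply") stop("not a PLY file")
  end <- match("end_header", lines)
  if (is.na(end)) stop("PLY header not terminated")
  header <- lines[seq_len(end)]
  if (!any(grepl("^format ascii", header)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", header, value = TRUE)))
  body <- lines[(end + 1L):length(lines)]
  vtx <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                               function(x) as.numeric(x[1:3])))
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fl, function(x) {
    if (as.integer(x[1]) != 3L) stop("only triangular faces are supported")
    as.integer(x[2:4]) + 1L
  }))
  fstd_mesh(vtx, faces)
}

#' Write an intensity volume as NRRD
#'
#' Raw little-endian encoding with spacing and origin metadata.
#'
#' @param volume An [fstd_volume()].
#' @param path Output file path (`.nrrd`).
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(volume, path) {
  d <- dim(volume$data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004", "type: double", "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %.9g %.9g %.9g",
            volume$spacing[1], volume$spacing[2], volume$spacing[3]),
    sprintf("space origin: (%.9g,%.9g,%.9g)",
            volume$origin[1], volume$origin[2], volume$origin[3]),
    "endian: little", "encoding: raw", "")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an NRRD intensity volume
#'
#' Supports raw-encoded attached-data NRRD with float/double types.
#'
#' @param path NRRD file path.
#' @return An [fstd_volume()].
#' @export
read_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  # header ends at the first blank line
  nl <- which(raw_all == as.raw(10L))
  blank <- nl[c(diff(nl) == 1L, FALSE)]
  if (length(blank) == 0L) stop("NRRD header not terminated by blank line")
  data_start <- blank[1] + 2L # byte after the two newlines
  header <- strsplit(rawToChar(raw_all[seq_len(blank[1] - 1L)]), "\n")[[1]]
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ": "), header, value = TRUE)
    if (length(ln) == 0L) return(NULL)
    sub(paste0("^", key, ": "), "", ln[1])
  }
  sizes <- as.integer(strsplit(get_field("sizes"), "\\s+")[[1]])
  type <- get_field("type")
  if (!identical(get_field("encoding"), "raw")) stop("only raw encoding supported")
  spc <- get_field("spacings")
  spacing <- if (is.null(spc)) c(1, 1, 1) else as.numeric(strsplit(spc, "\\s+")[[1]])
  org <- get_field("space origin")
  origin <- if (is.null(org)) c(0, 0, 0) else
    as.numeric(strsplit(gsub("[()]", "", org), ",")[[1]])
  size_bytes <- switch(type, double = 8L, float = 4L,
                       stop("unsupported NRRD type: ", type))
  vals <- readBin(raw_all[data_start:length(raw_all)], "double",
                  n = prod(sizes), size = size_bytes, endian = "little")
  fstd_volume(array(vals, dim = sizes), spacing, origin)
}

#' Read or write landmark coordinate files
#'
#' Landmarks travel as JSON (an array of objects with `code`, `side`,
#' `xyz_mm`) or CSV (`code, side, x_mm, y_mm, z_mm`).
#'
#' @param path File path; format chosen by extension (`.json` or `.csv`).
#' @return A landmark tibble with columns `code`, `side`, `x`, `y`, `z`.
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    xyz <- do.call(rbind, rec$xyz_mm)
    out <- tibble::tibble(code = rec$code, side = rec$side,
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    out <- tibble::tibble(code = df$code, side = df$side,
                          x = df$x_mm, y = df$y_mm, z = df$z_mm)
  }
  validate_landmark_table(out)
}

#' @rdname read_landmarks
#' @param landmarks A landmark tibble (`code`, `side`, `x`, `y`, `z`).
#' @export
write_landmarks <- function(landmarks, path) {
  landmarks <- validate_landmark_table(landmarks)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- lapply(seq_len(nrow(landmarks)), function(i)
      list(code = landmarks$code[i], side = landmarks$side[i],
           xyz_mm = c(landmarks$x[i], landmarks$y[i], landmarks$z[i])))
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(
      data.frame(code = landmarks$code, side = landmarks$side,
                 x_mm = landmarks$x, y_mm = landmarks$y, z_mm = landmarks$z),
      path, row.names = FALSE)
  }
  invisible(path)
}

validate_landmark_table <- function(landmarks) {
  need <- c("code", "side", "x", "y", "z")
  if (!all(need %in% names(landmarks)))
    stop("landmark table needs columns ", paste(need, collapse = ", "))
  if (!all(landmarks$side %in% c("L", "R", "mid")))
    stop("landmark `side` must be one of L, R, mid")
  if (!all(is.finite(landmarks$x) & is.finite(landmarks$y) & is.finite(landmarks$z)))
    stop("landmark coordinates must be finite")
  tibble::as_tibble(landmarks)
}

#' Read or write an intensity volume as NIfTI
#'
#' Thin wrappers over the RNifti reader/writer mapping voxel dimensions to
#' spacing; requires the suggested RNifti package.
#'
#' @param path NIfTI file path (`.nii` / `.nii.gz`).
#' @return [read_nifti_volume()]: an [fstd_volume()].
#' @export
read_nifti_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support needs the RNifti package")
  img <- RNifti::readNifti(path)
  fstd_volume(array(as.numeric(img), dim = dim(img)),
              spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_nifti_volume
#' @param volume An [fstd_volume()].
#' @export
write_nifti_volume <- function(volume, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support needs the RNifti package")
  img <- RNifti::asNifti(volume$data, pixdim = volume$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
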