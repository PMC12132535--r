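#' Read a threshold table from columnar text
#'
#' Reads a long-format threshold table (one row per participant, condition
#' and hemifield) from a delimited text file with header columns
#' \code{participant}, \code{condition}, \code{hemifield},
#' \code{session_order}, \code{threshold}, validates it, and reports
#' malformed rows by number.
#'
#' @param path Path to a comma- or tab-separated text file.
#' @param sep Field separator; default \code{","}.
#' @return A validated \code{threshold_table}.
#' @seealso [write_threshold_table()], [validate_threshold_table()]
#' @export
read_threshold_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  needed <- c("participant", "condition", "hemifield", "session_order",
              "threshold")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(suppressWarnings(as.numeric(tab$threshold))))
  if (length(bad))
    stop("non-numeric threshold in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  tab$threshold <- as.numeric(tab$threshold)
  tab$session_order <- as.integer(tab$session_order)
  validate_threshold_table(tab)
}

#' Write a threshold table to columnar text
#'
#' @param table A threshold table.
#' @param path Output path.
#' @param sep Field separator; default \code{","}.
#' @return \code{path}, invisibly.
#' @export
write_threshold_table <- function(table, path, sep = ",") {
  table <- validate_threshold_table(table)
  utils::write.table(as.data.frame(table)[, c("participant", "condition",
                                              "hemifield", "session_order",
                                              "threshold")],
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single 3-D volume from NIfTI
#'
#' Reads one scalar volume in NIfTI-1 format and returns the voxel data
#' with its voxel-to-world affine and voxel sizes. 4-D inputs are
#' rejected; a mask of finite voxels is derived automatically.
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @return List with \code{data} (3-D array), \code{affine} (4 x 4
#'   voxel-to-world, MNI mm), \code{voxel_size} (length-3 mm), and
#'   \code{mask} (finite-value support).
#' @seealso [read_volume_pair()], [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a single 3-D volume, got ", length(d), "-D data",
         call. = FALSE)
  data <- array(as.numeric(img), d)
  list(data = data, affine = unclass(RNifti::xform(img)),
       voxel_size = RNifti::pixdim(img)[seq_len(3)],
       mask = is.finite(data))
}

#' Read a co-registered t-map / e-field pair
#'
#' Reads two NIfTI volumes, checks that their shapes and affines agree,
#' and assembles a [volume_pair()] whose mask is the intersection of the
#' two finite-value supports (no statistical threshold is applied to
#' either map).
#'
#' @param tmap_path,efield_path NIfTI file paths.
#' @param affine_tol Tolerance for the affine agreement check. Default
#'   1e-4.
#' @return A [volume_pair()].
#' @export
read_volume_pair <- function(tmap_path, efield_path, affine_tol = 1e-4) {
  a <- read_volume(tmap_path)
  b <- read_volume(efield_path)
  if (!identical(dim(a$data), dim(b$data)))
    stop("volume shapes differ: ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"), call. = FALSE)
  if (max(abs(a$affine - b$affine)) > affine_tol)
    stop("volume affines differ beyond tolerance", call. = FALSE)
  volume_pair(a$data, b$data, mask = a$mask & b$mask,
              voxel_size = a$voxel_size, affine = a$affine)
}

#' Write a 3-D volume to NIfTI
#'
#' @param data 3-D numeric array.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @param voxel_size Length-3 voxel sizes, mm. Default 2.5 mm isotropic.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(data, path, voxel_size = c(2.5, 2.5, 2.5)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
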