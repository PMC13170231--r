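# File-format interfaces: NIfTI-1 volumes (via RNifti), tab-separated tables,
# GMT gene-set collections, and 3-column edge lists.

#' Write a VoxelMap (or Parcellation) as NIfTI-1
#'
#' @param x a [VoxelMap-class] or [Parcellation-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return the path, invisibly.
#' @export
writeNIfTI1 <- function(x, path) {
  if (is(x, "VoxelMap")) {
    arr <- x@data; arr[!x@mask] <- 0
    vs <- x@voxelSize
  } else if (is(x, "Parcellation")) {
    arr <- x@labels
    vs <- x@voxelSize
  } else stop("unsupported object")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a VoxelMap
#'
#' @param path NIfTI file.
#' @param kind value kind for the resulting map.
#' @param mask optional logical array; default: non-zero, finite voxels.
#' @return a [VoxelMap-class].
#' @export
readNIfTI1 <- function(path, kind = "alff", mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  vs <- RNifti::pixdim(img)[1:3]
  if (is.null(mask)) mask <- array(is.finite(arr) & arr != 0, dim(arr))
  VoxelMap(arr, mask = mask, voxelSize = vs, kind = kind)
}

#' Read/write gene-set collections in GMT format
#'
#' One set per line: name, description, then tab-separated members.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    stats::setNames(list(unique(f[-(1:2)])), f[1])
  })
  sets <- unlist(out, recursive = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @param description description field (recycled).
#' @export
writeGMT <- function(sets, path, description = "synthetic") {
  lines <- vapply(names(sets), function(n)
    paste(c(n, description, sets[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a data.frame as tab-separated UTF-8 with header
#'
#' @param x data.frame.
#' @param path output path.
#' @export
writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path file path.
#' @export
readTSV <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a 3-column weighted edge list (node_a, node_b, weight)
#'
#' @param path TSV file.
#' @return data.frame suitable for [interactionGraph()].
#' @export
readEdgeList <- function(path) {
  df <- readTSV(path)
  stopifnot(all(c("node_a", "node_b", "weight") %in% names(df)))
  df
}
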