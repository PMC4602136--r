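# Volume and table I/O plus the packaged cohort fixture.

#' Read a NIfTI-1 volume
#'
#' @param path file path (.nii or .nii.gz).
#' @param name optional label for the returned map.
#' @return A \linkS4class{VolumeMap}; voxel size and origin are taken from
#'   the header.
#' @export
readVolume <- function(path, name = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop("malformed NIfTI file '", path, "': ",
                         conditionMessage(e))
                  })
  pd <- RNifti::pixdim(img)
  a <- array(as.numeric(img), dim(img)[1:3])
  VolumeMap(a, voxelSize = pd[1], origin = .readOrigin(img), name = name)
}

.readOrigin <- function(img) {
  h <- RNifti::niftiHeader(img)
  c(h$qoffset_x, h$qoffset_y, h$qoffset_z)
}

#' Write a VolumeMap as NIfTI-1
#'
#' @param map a \linkS4class{VolumeMap}.
#' @param path target path.
#' @param datatype on-disk datatype (default "float", 32-bit).
#' @return the path, invisibly.
#' @export
writeVolume <- function(map, path, datatype = "float") {
  img <- RNifti::asNifti(map@data)
  RNifti::pixdim(img) <- rep(map@voxelSize, 3)
  hdr <- list(qoffset_x = map@origin[1], qoffset_y = map@origin[2],
              qoffset_z = map@origin[3], qform_code = 2L)
  img <- RNifti::asNifti(img, hdr)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# frozen md5 of the packaged cohort fixture (verbatim transcription of the
# published 28-patient table)
.TABLE1_MD5 <- "e895c023abd9844b95cfdf47702feded"

#' Load the packaged 28-patient cohort fixture
#'
#' Clinical and demographic data of the 28 stroke patients (age, gender,
#' lesion side, etiology, and NIHSS, modified Rankin, hand dynamometry,
#' picking-small-objects and tactile-object-recognition scores at baseline,
#' month 3 and month 9), transcribed verbatim from the published table,
#' including apparent oddities in the printed values. The file is frozen by
#' an md5 checksum.
#'
#' @return data.frame of 28 rows.
#' @examples
#' t1 <- loadTable1Fixture()
#' descriptives(t1$age)$median  # 65.5
#' @export
loadTable1Fixture <- function() {
  path <- system.file("extdata", "table1.csv", package = "strokecov")
  if (!nzchar(path)) stop("packaged fixture table1.csv not found")
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .TABLE1_MD5)) {
    stop("checksum mismatch for table1.csv: expected ", .TABLE1_MD5,
         ", got ", sum)
  }
  read.csv(path, stringsAsFactors = FALSE)
}
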