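# File interfaces: 16-bit TIFF channel files and plain-text tables.
#
# On disk, a field is a pair of single-channel 16-bit grayscale TIFFs named
# <well>_f<field>_hoechst.tif and <well>_f<field>_caspase.tif; the plate
# map is a CSV with columns well, cell_line, inhibitor_id, role, replicate.

#' Write / read a field as 16-bit TIFF channel files
#'
#' @param image a \linkS4class{FieldImage}.
#' @param dir directory for the channel files.
#' @return \code{writeFieldImage}: invisibly, the two file paths;
#'   \code{readFieldImage}: a \linkS4class{FieldImage}.
#' @export
writeFieldImage <- function(image, dir) {
  stopifnot(is(image, "FieldImage"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, sprintf("%s_f%d", image@well, image@fieldIndex))
  paths <- paste0(stem, "_", c("hoechst", "caspase"), ".tif")
  tiff::writeTIFF(image@hoechst / 65535, paths[1], bits.per.sample = 16L)
  tiff::writeTIFF(image@caspase / 65535, paths[2], bits.per.sample = 16L)
  invisible(paths)
}

#' @rdname writeFieldImage
#' @param well,fieldIndex identify the field to read.
#' @export
readFieldImage <- function(dir, well, fieldIndex = 1L) {
  stem <- file.path(dir, sprintf("%s_f%d", well, fieldIndex))
  paths <- paste0(stem, "_", c("hoechst", "caspase"), ".tif")
  if (!all(file.exists(paths)))
    stop("missing channel file(s): ",
         paste(paths[!file.exists(paths)], collapse = ", "))
  rd <- function(p) round(tiff::readTIFF(p) * 65535)
  fieldImage(rd(paths[1]), rd(paths[2]), well = well,
             fieldIndex = as.integer(fieldIndex))
}

#' Read a plate map CSV
#'
#' @param path CSV with header \code{well, cell_line, inhibitor_id, role,
#'   replicate}; \code{role} is one of sample, mock, neg_ctrl, death_ctrl.
#' @return data.frame with those columns.
#' @export
readPlateMap <- function(path) {
  pm <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "cell_line", "inhibitor_id", "role", "replicate")
  if (!all(need %in% colnames(pm)))
    stop("plate map must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(pm$role), c("sample", "mock", "neg_ctrl", "death_ctrl"))
  if (length(bad))
    stop("unknown plate-map role(s): ", paste(bad, collapse = ", "))
  pm
}

#' Read per-source target gene lists from a directory of TSV files
#'
#' One TSV per evidence source, a single gene-symbol column with header;
#' the source is named by the file name (without extension).
#'
#' @param dir directory of \code{<source>.tsv} files.
#' @return named list of character vectors, ready for
#'   \code{\link{buildTargetUnion}}.
#' @export
readTargetSources <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no .tsv source files found in ", dir)
  out <- lapply(files, function(f)
    read.csv(f, sep = "\t", stringsAsFactors = FALSE)[[1]])
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}

#' Read a dose-response matrix CSV
#'
#' First column holds agent-A doses, the header row holds agent-B doses
#' (first cell ignored); body cells are the readings.
#'
#' @param path CSV file.
#' @return list with \code{dosesA}, \code{dosesB} and \code{raw} matrix.
#' @export
readDoseMatrix <- function(path) {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  list(dosesA = as.numeric(rownames(m)),
       dosesB = as.numeric(colnames(m)),
       raw = unname(m))
}
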