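# Minimal GIFTI functional-data codec.
#
# GIFTI is XML with per-array binary payloads; no installed package reads it,
# so the subset needed here (FLOAT32/FLOAT64/INT32 DataArrays in ASCII,
# Base64Binary or GZipBase64Binary encoding, little-endian) is implemented
# directly on xml2. Surface geometry (coordinates/topology) is out of scope:
# only the data arrays are read, one column per array.

gifti_type <- function(code) {
  switch(code,
    "NIFTI_TYPE_FLOAT32" = list(what = "double", size = 4L),
    "NIFTI_TYPE_FLOAT64" = list(what = "double", size = 8L),
    "NIFTI_TYPE_INT32" = list(what = "integer", size = 4L),
    abort(sprintf("unsupported GIFTI data type: %s", code))
  )
}

#' Read and write GIFTI functional data arrays
#'
#' `read_gifti_data()` parses the DataArray elements of a GIFTI file into a
#' vertices x arrays matrix (for a functional time-series file, arrays are
#' time points). ASCII, Base64Binary and GZipBase64Binary encodings are
#' supported, little-endian only. `write_gifti_data()` writes a matrix as a
#' GIFTI file with one FLOAT32 ASCII-encoded DataArray per column; writing
#' then reading reproduces the values to single precision.
#'
#' @param path A `.gii` file path.
#' @return `read_gifti_data()`: numeric matrix, vertices x arrays.
#' @export
read_gifti_data <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) == 0) abort(sprintf("no DataArray elements in %s", path))
  cols <- lapply(arrays, function(node) {
    enc <- xml2::xml_attr(node, "Encoding")
    typ <- gifti_type(xml2::xml_attr(node, "DataType"))
    endian <- xml2::xml_attr(node, "Endian")
    if (!is.na(endian) && !endian %in% c("LittleEndian", "")) {
      abort("only little-endian GIFTI payloads are supported.")
    }
    dims <- as.integer(xml2::xml_attr(
      node, paste0("Dim", 0:(as.integer(xml2::xml_attr(node, "Dimensionality") %||% "1") - 1))
    ))
    n <- prod(dims)
    data_node <- xml2::xml_find_first(node, ".//Data")
    txt <- xml2::xml_text(data_node)
    vals <- switch(enc,
      "ASCII" = as.numeric(strsplit(trimws(txt), "\\s+")[[1]]),
      "Base64Binary" = readBin(jsonlite::base64_dec(gsub("\\s", "", txt)),
                               typ$what, n = n, size = typ$size,
                               endian = "little"),
      "GZipBase64Binary" = readBin(
        memDecompress(jsonlite::base64_dec(gsub("\\s", "", txt)), type = "gzip"),
        typ$what, n = n, size = typ$size, endian = "little"
      ),
      abort(sprintf("unsupported GIFTI encoding: %s", enc))
    )
    if (length(vals) != n) {
      abort(sprintf("DataArray payload has %d values, header promises %d.",
                    length(vals), n))
    }
    vals
  })
  lens <- vapply(cols, length, integer(1))
  if (length(unique(lens)) != 1) abort("DataArrays have inconsistent lengths.")
  do.call(cbind, cols)
}

#' @rdname read_gifti_data
#' @param x Vertices x arrays numeric matrix.
#' @param intent NIfTI intent label per array (default time series).
#' @export
write_gifti_data <- function(x, path, intent = "NIFTI_INTENT_TIME_SERIES") {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  arrays <- paste0(vapply(seq_len(ncol(x)), function(j) {
    sprintf(
      paste0(
        '  <DataArray Intent="%s" DataType="NIFTI_TYPE_FLOAT32" ',
        'ArrayIndexingOrder="RowMajorOrder" Dimensionality="1" Dim0="%d" ',
        'Encoding="ASCII" Endian="LittleEndian" ExternalFileName="" ',
        'ExternalFileOffset="">\n    <Data>%s</Data>\n  </DataArray>\n'
      ),
      intent, nrow(x), paste(format(x[, j], digits = 9, trim = TRUE,
                                    scientific = TRUE), collapse = " ")
    )
  }, character(1)), collapse = "")
  xml <- sprintf(
    '<?xml version="1.0" encoding="UTF-8"?>\n<GIFTI Version="1.0" NumberOfDataArrays="%d">\n%s</GIFTI>\n',
    ncol(x), arrays
  )
  writeLines(xml, path)
  invisible(path)
}
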