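# Stable CSV writer: fixed 6-significant-digit formatting for doubles so
# that identical runs produce byte-identical files across platforms.
writeCsvStable <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), "NA",
                          sprintf("%.6g", out[[nm]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

pkgVersionString <- function() {
  as.character(utils::packageVersion("seedlingHealth"))
}

# 16-bit label map in an 8-bit RGB PNG: label = R * 256 + G
writeLabelPNG <- function(lab, path) {
  arr <- array(0, c(nrow(lab), ncol(lab), 3))
  arr[, , 1] <- (lab %/% 256L) / 255
  arr[, , 2] <- (lab %% 256L) / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a label map written by the pipeline
#'
#' Inverse of the label PNG encoding (instance id = R * 256 + G on 8-bit
#' channels).
#'
#' @param path a `*_labels.png` file.
#' @return integer matrix of instance labels.
#' @export
readLabelPNG <- function(path) {
  arr <- png::readPNG(path)
  matrix(as.integer(round(arr[, , 1] * 255) * 256L +
                    round(arr[, , 2] * 255)), nrow(arr))
}
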