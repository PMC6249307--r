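# imzML-dialect I/O: processed-mode imzML XML plus an external .ibd binary
# holding float64 m/z and intensity arrays. File coordinates are 1-based per
# the imzML convention (x = column, y = row); in-memory indices follow R's
# 1-based matrix convention, so file (x=1, y=1) is pixel [row 1, col 1].

#' Write an MSI dataset as imzML + ibd
#'
#' Writes a processed-mode imzML dialect: per-pixel m/z and intensity arrays
#' stored as little-endian float64 in a sidecar `.ibd` file referenced by
#' byte offset and length from the XML. Pixel size, section index, z-spacing,
#' polarity and m/z range are carried in the XML header.
#'
#' @param dataset an [msi_dataset][new_msi_dataset].
#' @param path output path ending in `.imzML`; the `.ibd` is written next to
#'   it with the same stem.
#' @return Invisibly, `path`.
#' @export
write_imzml <- function(dataset, path) {
  assert_that(inherits(dataset, "msi_dataset"), "`dataset` must be an msi_dataset")
  assert_that(grepl("\\.imzML$", path, ignore.case = TRUE),
              "`path` must end in .imzML")
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

  n <- length(dataset$spectra)
  uuid <- as.raw(rep(0L, 16))
  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16
  mz_off <- mz_len <- int_off <- int_len <- integer(n)
  for (i in seq_len(n)) {
    s <- dataset$spectra[[i]]
    mz_off[i] <- offset
    mz_len[i] <- length(s$mz)
    writeBin(as.double(s$mz), con, size = 8, endian = "little")
    offset <- offset + 8 * length(s$mz)
    int_off[i] <- offset
    int_len[i] <- length(s$intensity)
    writeBin(as.double(s$intensity), con, size = 8, endian = "little")
    offset <- offset + 8 * length(s$intensity)
  }

  mzr <- dataset$metadata$mz_range %||% c(NA_real_, NA_real_)
  head <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '  <fileDescription>',
    '    <fileContent>',
    '      <cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>',
    sprintf('      <userParam name="polarity" value="%s"/>',
            dataset$metadata$polarity %||% "positive"),
    sprintf('      <userParam name="mz_range_min" value="%.6f"/>', mzr[1]),
    sprintf('      <userParam name="mz_range_max" value="%.6f"/>', mzr[2]),
    sprintf('      <userParam name="section_index" value="%d"/>',
            dataset$section_index),
    sprintf('      <userParam name="z_spacing_um" value="%.6f"/>',
            dataset$z_spacing),
    '    </fileContent>',
    '  </fileDescription>',
    '  <scanSettingsList count="1">',
    '    <scanSettings id="scanSettings1">',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>',
            dataset$grid_shape[2]),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>',
            dataset$grid_shape[1]),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="%.6f"/>',
            dataset$pixel_size),
    '    </scanSettings>',
    '  </scanSettingsList>',
    '  <run id="run1">',
    sprintf('    <spectrumList count="%d">', n)
  )

  xcol <- dataset$coords[, 2]
  yrow <- dataset$coords[, 1]
  body <- sprintf(paste0(
    '      <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">\n',
    '        <scanList count="1"><scan>\n',
    '          <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
    '          <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
    '        </scan></scanList>\n',
    '        <binaryDataArrayList count="2">\n',
    '          <binaryDataArray arrayType="mz">\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
    '          </binaryDataArray>\n',
    '          <binaryDataArray arrayType="intensity">\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
    '          </binaryDataArray>\n',
    '        </binaryDataArrayList>\n',
    '      </spectrum>'),
    seq_len(n) - 1L, seq_len(n), mz_len, xcol, yrow,
    mz_off, mz_len, int_off, int_len)

  tail <- c('    </spectrumList>', '  </run>', '</mzML>')
  writeLines(c(head, body, tail), path)
  invisible(path)
}

#' Read an imzML-dialect file
#'
#' Parses the processed-mode imzML written by [write_imzml()] (or any file
#' following the same external-offset layout with float64 arrays) and its
#' `.ibd` sidecar. A write-then-read round trip reproduces coordinates, m/z
#' and intensities to float precision.
#'
#' @param path path to the `.imzML` file.
#' @return An [msi_dataset][new_msi_dataset].
#' @export
read_imzml <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              "msipk_format_error")
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  assert_that(file.exists(ibd_path),
              sprintf("ibd sidecar not found: %s", ibd_path),
              "msipk_format_error")

  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort_msipk(sprintf("malformed imzML XML in %s: %s", path,
                        conditionMessage(e)), "msipk_format_error")
  })
  ns <- c(d1 = "http://psi.hupo.org/ms/mzml")

  mode_node <- xml2::xml_find_first(
    doc, "//d1:fileContent/d1:cvParam[@accession='IMS:1000031']", ns)
  assert_that(!inherits(mode_node, "xml_missing"),
              "imzML file does not declare processed mode",
              "msipk_format_error")

  up <- function(name) {
    node <- xml2::xml_find_first(
      doc, sprintf("//d1:userParam[@name='%s']", name), ns)
    if (inherits(node, "xml_missing")) NA else xml2::xml_attr(node, "value")
  }
  cvq <- function(acc) {
    node <- xml2::xml_find_first(
      doc, sprintf("//d1:scanSettings/d1:cvParam[@accession='%s']", acc), ns)
    if (inherits(node, "xml_missing")) NA else
      as.numeric(xml2::xml_attr(node, "value"))
  }
  ncols <- cvq("IMS:1000042"); nrows <- cvq("IMS:1000043")
  pixel_size <- cvq("IMS:1000046")

  spectra_nodes <- xml2::xml_find_all(doc, "//d1:spectrum", ns)
  n <- length(spectra_nodes)
  assert_that(n > 0, "no spectra in imzML file", "msipk_format_error")

  ibd_size <- file.size(ibd_path)
  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)

  spectra <- vector("list", n)
  coords <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    sp <- spectra_nodes[[i]]
    id <- xml2::xml_attr(sp, "id") %||% sprintf("index %d", i)
    get1 <- function(xpath) {
      v <- xml2::xml_attr(xml2::xml_find_first(sp, xpath, ns), "value")
      as.numeric(v)
    }
    x <- get1(".//d1:cvParam[@accession='IMS:1000050']")
    y <- get1(".//d1:cvParam[@accession='IMS:1000051']")
    assert_that(is.finite(x) && is.finite(y) && x >= 1 && y >= 1,
                sprintf("missing/invalid position for %s", id),
                "msipk_format_error")
    arr_nodes <- xml2::xml_find_all(sp, ".//d1:binaryDataArray", ns)
    assert_that(length(arr_nodes) == 2,
                sprintf("expected 2 binary arrays for %s", id),
                "msipk_format_error")
    read_arr <- function(node) {
      off <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
        node, ".//d1:cvParam[@accession='IMS:1000102']", ns), "value"))
      len <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
        node, ".//d1:cvParam[@accession='IMS:1000103']", ns), "value"))
      if (!is.finite(off) || !is.finite(len)) {
        abort_msipk(sprintf("missing external offset/length for %s", id),
                    "msipk_format_error")
      }
      if (off + 8 * len > ibd_size) {
        abort_msipk(sprintf(
          "truncated ibd stream for %s: need %d bytes at offset %d but file has %d",
          id, as.integer(8 * len), as.integer(off), as.integer(ibd_size)),
          "msipk_format_error")
      }
      seek(con, where = off, origin = "start")
      readBin(con, "double", n = len, size = 8, endian = "little")
    }
    mz <- read_arr(arr_nodes[[1]])
    intensity <- read_arr(arr_nodes[[2]])
    if (length(mz) != length(intensity)) {
      abort_msipk(sprintf("mz/intensity length mismatch for %s (%d vs %d)",
                          id, length(mz), length(intensity)),
                  "msipk_format_error")
    }
    # file x (column), y (row), 1-based -> in-memory [row, col], 1-based
    coords[i, ] <- c(as.integer(y), as.integer(x))
    spectra[[i]] <- list(mz = mz, intensity = intensity)
  }

  if (!is.finite(nrows)) nrows <- max(coords[, 1])
  if (!is.finite(ncols)) ncols <- max(coords[, 2])
  num <- function(s) {
    if (is.na(s) || s %in% c("NA", "NaN")) NA_real_ else as.numeric(s)
  }
  mzr <- c(num(up("mz_range_min")), num(up("mz_range_max")))
  z_sp <- num(up("z_spacing_um"))
  sec <- suppressWarnings(as.integer(up("section_index")))

  new_msi_dataset(
    spectra = spectra, coords = coords,
    grid_shape = c(as.integer(nrows), as.integer(ncols)),
    pixel_size = if (is.finite(pixel_size)) pixel_size else 1,
    z_spacing = z_sp,
    section_index = if (is.na(sec)) 1L else sec,
    metadata = list(
      polarity = if (is.na(up("polarity"))) "positive" else up("polarity"),
      mz_range = if (all(is.finite(mzr))) mzr else NULL
    )
  )
}
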