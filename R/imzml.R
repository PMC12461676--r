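# Minimal imzML 1.1 reader/writer.
#
# imzML stores spectra metadata in an mzML-flavoured XML file plus a sibling
# binary ".ibd" file holding the m/z and intensity arrays. Two storage modes
# exist: "continuous" (one shared m/z axis, a full-length intensity vector per
# pixel) and "processed" (a private peak list per pixel). Only uncompressed
# 32/64-bit float external arrays are supported, which covers the files the
# common converters emit.

IMS_CONTINUOUS <- "IMS:1000030"
IMS_PROCESSED <- "IMS:1000031"
IMS_POS_X <- "IMS:1000050"
IMS_POS_Y <- "IMS:1000051"
IMS_EXT_OFFSET <- "IMS:1000102"
IMS_EXT_LENGTH <- "IMS:1000103"

ibdPathFor <- function(path) {
  sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
}

# -- writer -------------------------------------------------------------------

imzmlHeaderTemplate <- function(mode, uuid, X, Y, nspec, spectra_xml) {
  paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '  <cvList count="3">\n',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>\n',
    '    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
    '    <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>\n',
    '  </cvList>\n',
    '  <fileDescription>\n',
    '    <fileContent>\n',
    sprintf('      <cvParam cvRef="IMS" accession="%s" name="%s"/>\n',
      if (mode == "continuous") IMS_CONTINUOUS else IMS_PROCESSED, mode),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>\n', uuid),
    '      <cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum"/>\n',
    '    </fileContent>\n',
    '  </fileDescription>\n',
    '  <referenceableParamGroupList count="2">\n',
    '    <referenceableParamGroup id="mzArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '    <referenceableParamGroup id="intensityArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '  </referenceableParamGroupList>\n',
    '  <softwareList count="1">\n',
    '    <software id="MSIdenoise" version="0.1.0"/>\n',
    '  </softwareList>\n',
    '  <scanSettingsList count="1">\n',
    '    <scanSettings id="scanSettings1">\n',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n', X),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n', Y),
    '    </scanSettings>\n',
    '  </scanSettingsList>\n',
    '  <instrumentConfigurationList count="1">\n',
    '    <instrumentConfiguration id="IC1"/>\n',
    '  </instrumentConfigurationList>\n',
    '  <dataProcessingList count="1">\n',
    '    <dataProcessing id="dp1">\n',
    '      <processingMethod order="1" softwareRef="MSIdenoise">\n',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>\n',
    '      </processingMethod>\n',
    '    </dataProcessing>\n',
    '  </dataProcessingList>\n',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    sprintf('    <spectrumList count="%d" defaultDataProcessingRef="dp1">\n', nspec),
    spectra_xml,
    '    </spectrumList>\n',
    '  </run>\n',
    '</mzML>\n'
  )
}

spectrumXml <- function(index, x, y, n_mz, mz_off, n_int, int_off) {
  paste0(
    sprintf('      <spectrum id="spectrum=%d" defaultArrayLength="%d" index="%d">\n',
      index, n_int, index - 1L),
    '        <scanList count="1">\n',
    '          <scan>\n',
    sprintf('            <cvParam cvRef="IMS" accession="%s" name="position x" value="%d"/>\n', IMS_POS_X, x),
    sprintf('            <cvParam cvRef="IMS" accession="%s" name="position y" value="%d"/>\n', IMS_POS_Y, y),
    '          </scan>\n',
    '        </scanList>\n',
    '        <binaryDataArrayList count="2">\n',
    sprintf('          <binaryDataArray encodedLength="%d">\n', n_mz * 8L),
    '            <referenceableParamGroupRef ref="mzArray"/>\n',
    sprintf('            <cvParam cvRef="IMS" accession="%s" name="external array length" value="%d"/>\n', IMS_EXT_LENGTH, n_mz),
    sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', n_mz * 8L),
    sprintf('            <cvParam cvRef="IMS" accession="%s" name="external offset" value="%.0f"/>\n', IMS_EXT_OFFSET, mz_off),
    '            <binary/>\n',
    '          </binaryDataArray>\n',
    sprintf('          <binaryDataArray encodedLength="%d">\n', n_int * 8L),
    '            <referenceableParamGroupRef ref="intensityArray"/>\n',
    sprintf('            <cvParam cvRef="IMS" accession="%s" name="external array length" value="%d"/>\n', IMS_EXT_LENGTH, n_int),
    sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', n_int * 8L),
    sprintf('            <cvParam cvRef="IMS" accession="%s" name="external offset" value="%.0f"/>\n', IMS_EXT_OFFSET, int_off),
    '            <binary/>\n',
    '          </binaryDataArray>\n',
    '        </binaryDataArrayList>\n',
    '      </spectrum>\n'
  )
}

writeImzML <- function(cube, path, mode = c("continuous", "processed")) {
  mode <- match.arg(mode)
  d <- dim(cube@intensities)
  X <- d[1]; Y <- d[2]; H <- d[3]
  mask <- cube@pixelMask
  ibd <- ibdPathFor(path)

  uuid_raw <- as.raw(withSeed(
    sum(utf8ToInt(basename(path))) + X * 1000L + Y,
    sample.int(256L, 16L, replace = TRUE) - 1L
  ))
  uuid <- paste0(
    paste(format(uuid_raw[1:4]), collapse = ""), "-",
    paste(format(uuid_raw[5:6]), collapse = ""), "-",
    paste(format(uuid_raw[7:8]), collapse = ""), "-",
    paste(format(uuid_raw[9:10]), collapse = ""), "-",
    paste(format(uuid_raw[11:16]), collapse = "")
  )

  con <- tryCatch(file(ibd, "wb"),
    error = function(e) stop("cannot write imzML binary file ", ibd, ": ", conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  writeBin(uuid_raw, con)
  offset <- 16

  specs <- character()
  idx <- 0L
  if (mode == "continuous") {
    writeBin(as.double(cube@mzAxis), con, size = 8, endian = "little")
    mz_off <- offset
    offset <- offset + 8 * H
    for (y in seq_len(Y)) for (x in seq_len(X)) {
      if (!mask[x, y]) next
      idx <- idx + 1L
      writeBin(as.double(cube@intensities[x, y, ]), con, size = 8, endian = "little")
      specs[idx] <- spectrumXml(idx, x, y, H, mz_off, H, offset)
      offset <- offset + 8 * H
    }
  } else {
    for (y in seq_len(Y)) for (x in seq_len(X)) {
      if (!mask[x, y]) next
      idx <- idx + 1L
      spec <- cube@intensities[x, y, ]
      keep <- which(spec > 0)
      writeBin(as.double(cube@mzAxis[keep]), con, size = 8, endian = "little")
      mz_off <- offset
      offset <- offset + 8 * length(keep)
      writeBin(as.double(spec[keep]), con, size = 8, endian = "little")
      specs[idx] <- spectrumXml(idx, x, y, length(keep), mz_off, length(keep), offset)
      offset <- offset + 8 * length(keep)
    }
  }
  xml <- imzmlHeaderTemplate(mode, uuid, X, Y, idx, paste(specs, collapse = ""))
  writeLines(xml, path, sep = "")
  invisible(path)
}

# -- reader -------------------------------------------------------------------

cvValue <- function(node, accession) {
  p <- xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) return(NA_character_)
  xml2::xml_attr(p, "value")
}

readImzML <- function(path, ppm = 10) {
  doc <- tryCatch(xml2::read_xml(path),
    error = function(e) stop("cannot parse imzML file ", path, ": ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  ibd <- ibdPathFor(path)
  if (!file.exists(ibd)) stop("missing imzML binary file: ", ibd)

  mode <- if (!inherits(xml2::xml_find_first(
    doc, sprintf("//fileContent/cvParam[@accession='%s']", IMS_PROCESSED)), "xml_missing"))
    "processed" else "continuous"

  # data type per referenceable param group
  sizeFor <- function(group_id) {
    g <- xml2::xml_find_first(doc, sprintf("//referenceableParamGroup[@id='%s']", group_id))
    if (inherits(g, "xml_missing")) return(8L)
    if (!inherits(xml2::xml_find_first(g, ".//cvParam[@accession='MS:1000521']"), "xml_missing"))
      return(4L)
    8L
  }
  sizes <- c(mzArray = sizeFor("mzArray"), intensityArray = sizeFor("intensityArray"))

  spectra <- xml2::xml_find_all(doc, "//spectrum")
  if (length(spectra) == 0L) stop("empty imzML cube: no spectra in ", path)

  parseSpec <- function(s) {
    x <- as.integer(cvValue(s, IMS_POS_X))
    y <- as.integer(cvValue(s, IMS_POS_Y))
    arrays <- xml2::xml_find_all(s, ".//binaryDataArray")
    info <- list(x = x, y = y)
    for (a in arrays) {
      ref <- xml2::xml_attr(xml2::xml_find_first(a, ".//referenceableParamGroupRef"), "ref")
      if (is.na(ref)) {
        ref <- if (!inherits(xml2::xml_find_first(a, ".//cvParam[@accession='MS:1000514']"),
          "xml_missing")) "mzArray" else "intensityArray"
      }
      entry <- list(
        offset = as.numeric(cvValue(a, IMS_EXT_OFFSET)),
        n = as.integer(cvValue(a, IMS_EXT_LENGTH))
      )
      if (ref == "mzArray") info$mz <- entry else info$int <- entry
    }
    info
  }
  infos <- lapply(spectra, parseSpec)

  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  readArr <- function(entry, size) {
    if (entry$n == 0L) return(numeric(0))
    seek(con, where = entry$offset, origin = "start")
    readBin(con, "numeric", n = entry$n, size = size, endian = "little")
  }

  xs <- vapply(infos, `[[`, integer(1), "x")
  ys <- vapply(infos, `[[`, integer(1), "y")
  X <- max(xs); Y <- max(ys)
  mask <- matrix(FALSE, X, Y)

  if (mode == "continuous") {
    mz <- readArr(infos[[1]]$mz, sizes["mzArray"])
    H <- length(mz)
    cube <- array(0, c(X, Y, H))
    for (info in infos) {
      if (info$int$n != H)
        stop(sprintf(
          "inconsistent spectrum length in continuous imzML: pixel (%d, %d) has %d values, expected %d",
          info$x, info$y, info$int$n, H))
      cube[info$x, info$y, ] <- readArr(info$int, sizes["intensityArray"])
      mask[info$x, info$y] <- TRUE
    }
  } else {
    peaks <- lapply(infos, function(info) {
      list(
        mz = readArr(info$mz, sizes["mzArray"]),
        int = readArr(info$int, sizes["intensityArray"]),
        x = info$x, y = info$y
      )
    })
    all_mz <- unlist(lapply(peaks, `[[`, "mz"))
    if (length(all_mz) == 0L) stop("empty imzML cube: no peaks in ", path)
    all_int <- unlist(lapply(peaks, `[[`, "int"))
    all_pix <- unlist(lapply(peaks, function(p) rep((p$y - 1L) * X + p$x, length(p$mz))))
    ord <- order(all_mz)
    all_mz <- all_mz[ord]; all_int <- all_int[ord]; all_pix <- all_pix[ord]

    # greedy merge: a peak joins the open bin while it lies within `ppm` of
    # the running bin center (mean m/z of members); otherwise a new bin opens
    bin_id <- integer(length(all_mz))
    centers <- numeric()
    cur <- 0L; csum <- 0; cn <- 0L
    for (i in seq_along(all_mz)) {
      if (cur == 0L || (all_mz[i] - csum / cn) > (csum / cn) * ppm * 1e-6) {
        cur <- cur + 1L; csum <- 0; cn <- 0L
      }
      csum <- csum + all_mz[i]; cn <- cn + 1L
      bin_id[i] <- cur
      centers[cur] <- csum / cn
    }
    H <- cur
    cube <- array(0, c(X, Y, H))
    flat <- (bin_id - 1L) * (X * Y) + all_pix
    agg <- rowsum(all_int, flat)
    cube[as.numeric(rownames(agg))] <- agg[, 1]
    mz <- centers
    for (p in peaks) mask[p$x, p$y] <- TRUE
  }
  MSIDataCube(cube, mz, mask = mask,
    meta = list(source_file = path, imzml_mode = mode))
}
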