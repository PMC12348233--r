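# All exchange formats are plain tab-delimited text with '.' decimals.
# Numbers are written with 17 significant digits so read(write(x)) is
# bitwise identical.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

# reject localized decimal-comma numerics instead of silently misparsing
check_decimal_comma <- function(lines, path) {
  hit <- grep("(^|\t| )[-+]?[0-9]+,[0-9]", lines)
  if (length(hit))
    fail("%s line %d: decimal commas are not supported; use '.' as the decimal separator",
         path, hit[1])
}

parse_numeric_field <- function(x, path, line_no, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    fail("%s line %d: cannot parse %s value '%s'", path, line_no[bad[1]], what, x[bad[1]])
  v
}

#' Read / write a 1-D NMR spectrum as two-column delimited text
#'
#' Format: optional `#` comment lines, a `ppm<TAB>intensity` header, then
#' one `ppm<TAB>intensity` pair per line.
#'
#' @param path File path.
#' @param sample_id,replicate_id Identifiers attached on read.
#' @return [read_spectrum()] returns an [nmr_spectrum()];
#'   [write_spectrum()] returns `path` invisibly.
#' @export
read_spectrum <- function(path, sample_id = NULL, replicate_id = 1L) {
  if (!file.exists(path)) fail("spectrum file not found: %s", path)
  lines <- readLines(path)
  check_decimal_comma(lines, path)
  keep <- !grepl("^\\s*(#|$)", lines)
  ln <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) && identical(tolower(fields[[1]][1]), "ppm")) {
    fields <- fields[-1]; ln <- ln[-1]
  }
  nf <- lengths(fields)
  if (any(nf != 2))
    fail("%s line %d: expected 2 tab-separated fields, found %d",
         path, ln[which(nf != 2)[1]], nf[which(nf != 2)[1]])
  ppm <- parse_numeric_field(vapply(fields, `[`, "", 1), path, ln, "ppm")
  intensity <- parse_numeric_field(vapply(fields, `[`, "", 2), path, ln, "intensity")
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  nmr_spectrum(ppm, intensity, sample_id, replicate_id)
}

#' @rdname read_spectrum
#' @param spectrum An [nmr_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  writeLines(c("ppm\tintensity",
               paste(fmt_num(spectrum$ppm), fmt_num(spectrum$intensity), sep = "\t")),
             path)
  invisible(path)
}

#' Read / write a bucket table
#'
#' Tab-delimited: `#`-prefixed header lines record the bucket width,
#' exclusion regions, normalization state and per-row full-range totals;
#' the table has `id`, `sample_id`, `replicate_id` columns followed by one
#' column per bucket labelled with its center ppm to 3 decimals.
#'
#' @param path File path.
#' @return [read_bucket_table()] returns a [bucket()] table;
#'   [write_bucket_table()] returns `path` invisibly.
#' @export
read_bucket_table <- function(path) {
  if (!file.exists(path)) fail("bucket table not found: %s", path)
  lines <- readLines(path)
  check_decimal_comma(lines, path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    h <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(h)) fail("%s: missing '# %s:' header line", path, key)
    sub(paste0("^# ", key, ": "), "", h[1])
  }
  width <- as.numeric(get_hdr("width"))
  excl <- lapply(strsplit(get_hdr("excluded"), ";", fixed = TRUE)[[1]],
                 function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
  normalized <- as.logical(get_hdr("normalized"))
  totals <- as.numeric(strsplit(get_hdr("row_total_full"), "\t")[[1]])
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.delim(con, check.names = FALSE, stringsAsFactors = FALSE)
  centers <- as.numeric(colnames(df)[-(1:3)])
  mat <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(mat) <- df$id
  colnames(mat) <- sprintf("%.3f", centers)
  structure(list(
    matrix = mat,
    bucket_edges = data.frame(lower = centers - width / 2,
                              upper = centers + width / 2, center = centers),
    excluded_regions = excl, row_ids = df$id, row_total_full = totals,
    sample_id = df$sample_id, replicate_id = df$replicate_id,
    normalized = normalized
  ), class = "bucket_table")
}

#' @rdname read_bucket_table
#' @param bt A [bucket()] table.
#' @export
write_bucket_table <- function(bt, path) {
  stopifnot(inherits(bt, "bucket_table"))
  width <- bt$bucket_edges$upper[1] - bt$bucket_edges$lower[1]
  excl <- paste(vapply(bt$excluded_regions,
                       function(e) paste(fmt_num(e), collapse = ","), ""),
                collapse = ";")
  hdr <- c(sprintf("# width: %s", fmt_num(width)),
           sprintf("# excluded: %s", excl),
           sprintf("# normalized: %s", bt$normalized),
           sprintf("# row_total_full: %s", paste(fmt_num(bt$row_total_full), collapse = "\t")))
  header_row <- paste(c("id", "sample_id", "replicate_id", colnames(bt$matrix)),
                      collapse = "\t")
  rows <- vapply(seq_len(nrow(bt$matrix)), function(i)
    paste(c(bt$row_ids[i], bt$sample_id[i], bt$replicate_id[i],
            fmt_num(bt$matrix[i, ])), collapse = "\t"), "")
  writeLines(c(hdr, header_row, rows), path)
  invisible(path)
}

#' Read / write one EEM matrix with embedded wavelength axes
#'
#' Tab-delimited, one header row of excitation wavelengths (first cell
#' `em_nm`) and one header column of emission wavelengths. Masked (missing)
#' values are written as `NA`.
#'
#' @param path File path.
#' @return [read_eem_matrix()] returns a list `(data, em_axis, ex_axis)`;
#'   [write_eem_matrix()] returns `path` invisibly.
#' @export
read_eem_matrix <- function(path) {
  if (!file.exists(path)) fail("EEM matrix file not found: %s", path)
  lines <- readLines(path)
  check_decimal_comma(lines, path)
  fields <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  ex_axis <- as.numeric(fields[[1]][-1])
  nf <- lengths(fields[-1])
  if (any(nf != length(ex_axis) + 1))
    fail("%s line %d: expected %d fields, found %d", path,
         which(nf != length(ex_axis) + 1)[1] + 1, length(ex_axis) + 1,
         nf[which(nf != length(ex_axis) + 1)[1]])
  em_axis <- vapply(fields[-1], function(f) as.numeric(f[1]), numeric(1))
  data <- t(vapply(fields[-1],
                   function(f) suppressWarnings(as.numeric(f[-1])),
                   numeric(length(ex_axis))))
  list(data = data, em_axis = em_axis, ex_axis = ex_axis)
}

#' @rdname read_eem_matrix
#' @param data Emission x excitation matrix.
#' @param em_axis,ex_axis Wavelength axes (nm).
#' @export
write_eem_matrix <- function(data, em_axis, ex_axis, path) {
  hdr <- paste(c("em_nm", fmt_num(ex_axis)), collapse = "\t")
  rows <- vapply(seq_along(em_axis), function(i)
    paste(c(fmt_num(em_axis[i]),
            ifelse(is.na(data[i, ]), "NA", fmt_num(data[i, ]))), collapse = "\t"), "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read / write an EEM cube as a directory of per-sample matrices
#'
#' The directory holds one `<sample_id>.tsv` per slab (see
#' [write_eem_matrix()]) and a `manifest.yaml` naming the sample files and
#' the shared axes. Missing values are stored as `NA` and restored into the
#' cube mask.
#'
#' @param dir Directory path.
#' @return [read_eem_cube()] returns an [eem_cube()]; [write_eem_cube()]
#'   returns `dir` invisibly.
#' @export
read_eem_cube <- function(dir) {
  manifest <- file.path(dir, "manifest.yaml")
  if (!file.exists(manifest)) fail("expected manifest file not found: %s", manifest)
  mf <- yaml::read_yaml(manifest)
  n <- length(mf$samples)
  data <- NULL
  for (i in seq_len(n)) {
    f <- file.path(dir, mf$samples[[i]]$file)
    if (!file.exists(f)) fail("expected EEM file not found: %s", f)
    m <- read_eem_matrix(f)
    if (is.null(data))
      data <- array(NA_real_, c(n, length(m$em_axis), length(m$ex_axis)))
    data[i, , ] <- m$data
  }
  mask <- is.na(data)
  data[mask] <- NA_real_
  eem_cube(data, m$em_axis, m$ex_axis,
           sample_ids = vapply(mf$samples, `[[`, "", "id"), mask = mask)
}

#' @rdname read_eem_cube
#' @param cube An [eem_cube()].
#' @export
write_eem_cube <- function(cube, dir) {
  stopifnot(inherits(cube, "eem_cube"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(gsub("[^A-Za-z0-9_.-]", "_", cube$sample_ids), ".tsv")
  for (i in seq_along(cube$sample_ids)) {
    slab <- cube$data[i, , ]
    slab[cube$mask[i, , ]] <- NA_real_
    write_eem_matrix(slab, cube$em_axis, cube$ex_axis, file.path(dir, files[i]))
  }
  yaml::write_yaml(list(
    samples = lapply(seq_along(files), function(i)
      list(id = cube$sample_ids[i], file = files[i]))),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read / write a sample metadata table
#'
#' Tab-delimited with columns `measurement_id`, `sample_id`, `class`,
#' `replicate_id`.
#'
#' @param path File path.
#' @return [read_metadata()] returns a data frame; [write_metadata()]
#'   returns `path` invisibly.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) fail("metadata file not found: %s", path)
  lines <- readLines(path)
  check_decimal_comma(lines, path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("measurement_id", "sample_id", "class", "replicate_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) fail("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  df
}

#' @rdname read_metadata
#' @param metadata Data frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
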