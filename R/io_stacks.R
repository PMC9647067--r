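#' Read a two-channel 3D stack from TIFF
#'
#' Reads a multi-page TIFF (channels interleaved plane-by-plane, channel
#' fastest) or a directory of per-plane TIFFs. In the directory case, files
#' whose names contain a channel label (case-insensitive) are assigned to that
#' channel; otherwise planes are de-interleaved by index. Pixel data become a
#' `(z, y, x)` array per channel with plane order preserved as z order.
#'
#' Voxel size and bit depth are taken from the embedded metadata block written
#' by [write_stack()] when present; absent metadata falls back to the typical
#' confocal acquisition (12-bit, 189 x 189 x 500 nm voxels) with a warning.
#'
#' @param path a TIFF file or a directory of per-plane TIFF files.
#' @param channel_map named integer vector mapping channel names to 0-based
#'   page-interleave indices, e.g. `c(DAPI = 0, "5mC" = 1)`. Must resolve
#'   both `"DAPI"` and `"5mC"`.
#' @param bit_depth override for the dynamic range in bits; `NULL` uses
#'   metadata (or the 12-bit default).
#' @param voxel_size_nm override for the voxel size `(x, y, z)` in nm.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map = c(DAPI = 0L, `5mC` = 1L),
                       bit_depth = NULL, voxel_size_nm = NULL) {
  if (is.null(names(channel_map)) || any(names(channel_map) == ""))
    stop("channel_map must be a named vector of 0-based channel indices",
         call. = FALSE)
  for (ch in c("DAPI", "5mC"))
    if (!ch %in% names(channel_map))
      stop(sprintf("channel_map does not resolve required channel '%s'", ch),
           call. = FALSE)

  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop(sprintf("no TIFF files in '%s'", path), call. = FALSE)
    by_name <- lapply(names(channel_map), function(ch)
      files[grepl(ch, basename(files), ignore.case = TRUE, fixed = FALSE)])
    names(by_name) <- names(channel_map)
    if (any(lengths(by_name) > 0L)) {
      # filename-tagged planes: every mapped channel must have files
      missing <- names(by_name)[lengths(by_name) == 0L]
      if (length(missing))
        stop(sprintf("missing channel '%s': no matching plane files in '%s'",
                     missing[1], path), call. = FALSE)
      if (length(unique(lengths(by_name))) != 1L)
        stop("channels have unequal plane counts", call. = FALSE)
      per_chan <- lapply(by_name, function(fs)
        unlist(lapply(fs, function(f) read_tiff(f)$pages), recursive = FALSE))
      meta <- parse_description(read_tiff(files[1])$description)
      return(assemble_stack(per_chan, meta, bit_depth, voxel_size_nm))
    }
    pages <- unlist(lapply(files, function(f) read_tiff(f)$pages),
                    recursive = FALSE)
    meta <- parse_description(read_tiff(files[1])$description)
  } else {
    if (!file.exists(path)) stop(sprintf("'%s' does not exist", path), call. = FALSE)
    tf <- read_tiff(path)
    pages <- tf$pages
    meta <- parse_description(tf$description)
  }

  n_chan <- if (!is.null(meta$channels)) length(meta$channels)
            else max(channel_map) + 1L
  if (length(pages) %% n_chan != 0L)
    stop(sprintf("page count %d is not a multiple of %d channels; a mapped channel is missing or the stack is ragged",
                 length(pages), n_chan), call. = FALSE)
  if (any(channel_map >= n_chan)) {
    bad <- names(channel_map)[channel_map >= n_chan][1]
    stop(sprintf("missing channel '%s': stack has only %d channel(s)",
                 bad, n_chan), call. = FALSE)
  }
  per_chan <- lapply(channel_map, function(ci)
    pages[seq.int(ci + 1L, length(pages), by = n_chan)])
  if (n_chan > length(channel_map))
    qdmi_log(sprintf("%d extra channel(s) present; only %s are consumed",
                     n_chan - length(channel_map),
                     paste(names(channel_map), collapse = "/")))
  assemble_stack(per_chan, meta, bit_depth, voxel_size_nm)
}

assemble_stack <- function(per_chan, meta, bit_depth, voxel_size_nm) {
  dims <- unique(unlist(lapply(per_chan, function(ps) lapply(ps, dim)),
                        recursive = FALSE))
  if (length(dims) != 1L)
    stop("ragged plane dimensions across pages", call. = FALSE)
  ny <- dims[[1]][1]; nx <- dims[[1]][2]
  nz <- length(per_chan[[1]])
  vox <- lapply(per_chan, function(ps) {
    a <- array(0, c(nz, ny, nx))
    for (z in seq_len(nz)) a[z, , ] <- ps[[z]]
    a
  })
  bd <- bit_depth %||% meta$bit_depth
  if (is.null(bd)) {
    warning("no bit-depth metadata; assuming 12-bit dynamic range", call. = FALSE)
    bd <- 12L
  }
  vs <- voxel_size_nm %||% meta$voxel_size_nm %||% c(189, 189, 500)
  image_stack(vox, voxel_size_nm = vs, bit_depth = bd)
}

#' Write an ImageStack as a multi-page TIFF
#'
#' Planes are written channel-interleaved (channel fastest within each z),
#' 16-bit unsigned, with a metadata block carrying channel names, voxel size
#' and bit depth so [read_stack()] round-trips losslessly.
#'
#' @param stack an [image_stack()]; intensities must be integral.
#' @param path output file path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- stack_dims_zyx(stack)
  pages <- vector("list", d[1] * length(stack$voxels))
  k <- 0L
  for (z in seq_len(d[1]))
    for (ch in stack$channel_names) {
      k <- k + 1L
      pages[[k]] <- stack$voxels[[ch]][z, , ]
    }
  write_tiff(pages, path, bits = 16L, description = stack_description(stack))
}

#' Write / read a label volume as 16-bit TIFF
#'
#' @param labels a `LabelVolume` or a 3D integer `(z, y, x)` array.
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  arr <- if (inherits(labels, "LabelVolume")) labels$labels else labels
  if (max(arr) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
  pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ])
  write_tiff(pages, path, bits = 16L, description = "qdmi\nkind=labels\n")
}

#' @rdname write_labels
#' @return `read_labels()` returns a `LabelVolume`.
#' @export
read_labels <- function(path) {
  tf <- read_tiff(path)
  ny <- nrow(tf$pages[[1]]); nx <- ncol(tf$pages[[1]])
  arr <- array(0L, c(length(tf$pages), ny, nx))
  for (z in seq_along(tf$pages)) arr[z, , ] <- tf$pages[[z]]
  label_volume(arr, params_digest = "external")
}

# ---- result tables ---------------------------------------------------------

RESULT_COLUMNS <- c("nucleus_id", "voxel_count", "volume_um3", "dapi_total",
                    "mc5_total", "mc5_mean", "slope", "delta_deg",
                    "kl_score", "similarity_class")

#' Write a per-nucleus result table
#'
#' Tab-separated, one row per nucleus, fixed `%.6g` float formatting so
#' identical inputs produce byte-identical files. Provenance (source path,
#' parameter digest, package version) is carried in `#`-prefixed header lines.
#' The `"dat"` dialect writes the identical content with a `.dat` extension.
#'
#' @param table data.frame with the columns listed in the package docs
#'   (`nucleus_id` ... `similarity_class`); may be empty.
#' @param path output path; extension is forced to match `dialect`.
#' @param dialect `"tsv"` or `"dat"`.
#' @param provenance optional named list recorded in the header.
#' @return The path written, invisibly.
#' @export
write_results <- function(table, path, dialect = c("tsv", "dat"),
                          provenance = list()) {
  dialect <- match.arg(dialect)
  path <- sub("\\.(tsv|dat)$", "", path)
  path <- paste0(path, ".", dialect)
  missing <- setdiff(RESULT_COLUMNS, names(table))
  if (length(missing))
    stop(sprintf("result table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  table <- table[RESULT_COLUMNS]
  prov <- c(list(software = paste0("qdmi ", as.character(utils::packageVersion("qdmi")))),
            provenance)
  hdr <- sprintf("# %s: %s", names(prov), vapply(prov, as.character, ""))
  fmt_num <- function(x) ifelse(x == floor(x) & abs(x) < 1e15,
                                sprintf("%d", as.integer(x)),
                                sprintf("%.6g", x))
  body <- vapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    paste(c(sprintf("%d", as.integer(r$nucleus_id)),
            sprintf("%d", as.integer(r$voxel_count)),
            sprintf("%.6g", r$volume_um3),
            fmt_num(r$dapi_total), fmt_num(r$mc5_total),
            sprintf("%.6g", r$mc5_mean), sprintf("%.6g", r$slope),
            sprintf("%.6g", r$delta_deg),
            if (is.na(r$kl_score)) "NA" else sprintf("%.6g", r$kl_score),
            as.character(r$similarity_class)),
          collapse = "\t")
  }, "")
  lines <- c(hdr, paste(RESULT_COLUMNS, collapse = "\t"), body)
  con <- file(path, "wb")          # binary mode: byte-identical across OSes
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  df <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                   stringsAsFactors = FALSE)
  df$similarity_class <- as.character(df$similarity_class)
  df
}
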