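# File formats: multi-page TIFF stacks, versioned CSV tables, JSON/YAML
# configuration and metadata sidecars.

#' Write an image stack to TIFF
#'
#' Writes 16-bit multi-page TIFF. With `layout = "interleaved"` a single
#' file holds pages ordered frame-major, channel-minor (t1c1, t1c2, t2c1,
#' ...); with `layout = "per_channel"` one file per channel is written and
#' `path` must contain `%s`, replaced by the channel name. Intensities are
#' rounded and clamped to the 16-bit range.
#'
#' @param stack An [image_stack()].
#' @param path Output path (template for `per_channel`).
#' @param layout `"interleaved"` or `"per_channel"`.
#' @return Invisibly, the written file path(s).
#' @export
write_stack <- function(stack, path, layout = c("interleaved", "per_channel")) {
  layout <- match.arg(layout)
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  maxv <- 65535
  page <- function(t, ci)
    pmin(pmax(round(stack$data[t, , , ci]), 0), maxv) / maxv
  if (layout == "interleaved") {
    pages <- list()
    for (t in seq_len(d[1L])) for (ci in seq_len(d[4L]))
      pages[[length(pages) + 1L]] <- page(t, ci)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    invisible(path)
  } else {
    if (!grepl("%s", path, fixed = TRUE))
      stopf("per-channel layout needs a '%%s' placeholder in `path`")
    out <- character(d[4L])
    for (ci in seq_len(d[4L])) {
      pages <- lapply(seq_len(d[1L]), page, ci = ci)
      out[ci] <- sprintf(path, stack$channels[ci])
      tiff::writeTIFF(pages, out[ci], bits.per.sample = 16L)
    }
    invisible(out)
  }
}

#' Read a TIFF stack
#'
#' Reads a multi-page TIFF written by [write_stack()] (or any 8/16-bit
#' TIFF with the same page layout) into an [image_stack()]. Integer pixel
#' values are preserved exactly, so a write/read round trip is
#' bit-identical.
#'
#' @param path TIFF path, or a named character vector of per-channel paths.
#' @param channel_map Named integer vector mapping channel names to their
#'   page position within a frame, e.g. `c(actin = 1, abp = 2)`.
#' @param pixel_size,frame_interval Physical metadata to attach.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map = c(actin = 1L, abp = 2L),
                       pixel_size = 1, frame_interval = 2) {
  if (is.null(names(channel_map)) || any(!nzchar(names(channel_map))))
    stopf("`channel_map` must be a named vector")
  if (length(path) > 1L) {
    # one file per channel
    mats <- lapply(path, function(p) {
      pg <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
      lapply(pg, function(m) m * 1.0)
    })
    nT <- length(mats[[1L]])
    if (any(vapply(mats, length, 1L) != nT))
      stopf("per-channel files have differing frame counts")
    if (any(channel_map < 1L | channel_map > length(path)))
      stopf("channel_map entry '%s' refers to a missing channel file",
            names(channel_map)[which(channel_map < 1L |
                                     channel_map > length(path))[1L]])
    sh <- dim(mats[[1L]][[1L]])
    data <- array(0, dim = c(nT, sh[1L], sh[2L], length(channel_map)))
    for (ci in seq_along(channel_map))
      for (t in seq_len(nT))
        data[t, , , ci] <- mats[[channel_map[ci]]][[t]]
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    nC <- length(channel_map)
    if (length(pages) %% nC != 0L)
      stopf("%d pages are not divisible by %d channels", length(pages), nC)
    if (any(channel_map < 1L | channel_map > nC))
      stopf("channel_map entry '%s' refers to channel %d but the stack has %d",
            names(channel_map)[which.max(channel_map)],
            max(channel_map), nC)
    nT <- length(pages) %/% nC
    sh <- dim(pages[[1L]])
    data <- array(0, dim = c(nT, sh[1L], sh[2L], nC))
    for (t in seq_len(nT))
      for (ci in seq_len(nC))
        data[t, , , ci] <- pages[[(t - 1L) * nC + channel_map[ci]]] * 1.0
  }
  image_stack(data, channels = names(channel_map),
              pixel_size = pixel_size, frame_interval = frame_interval)
}

# versioned CSV tables: first line is a '#schema:' comment, then an
# RFC-4180 header row and data.
schema_line <- function(name) sprintf("#schema: bundlemech/%s v1", name)

#' Write a versioned CSV table
#'
#' Writes a data frame as UTF-8 CSV (header row) preceded by a one-line
#' `#schema:` comment identifying the table type and version.
#'
#' @param table Data frame.
#' @param path Output path.
#' @param schema Schema name embedded in the header comment.
#' @return Invisibly, `path`.
#' @export
write_table_csv <- function(table, path, schema = "table") {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(schema_line(schema), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read a versioned CSV table
#'
#' @param path CSV path written by [write_table_csv()].
#' @return The data frame, with the schema string as attribute `schema`.
#' @export
read_table_csv <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#schema:")) 1L else 0L
  out <- utils::read.csv(path, skip = skip, encoding = "UTF-8")
  attr(out, "schema") <- if (skip) sub("^#schema: *", "", first) else NA_character_
  out
}

#' Write a ground-truth scene to CSV + JSON sidecar
#'
#' The segment table (one row per segment, with path endpoints) goes to
#' CSV; generation parameters and the seed go to a JSON sidecar so a scene
#' is fully reproducible from its files.
#'
#' @param scene A [sample_network()] scene.
#' @param csv_path Segment table path.
#' @param json_path Sidecar path (default: `csv_path` with `.json`).
#' @return Invisibly, the CSV path.
#' @export
write_scene <- function(scene, csv_path,
                        json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(scene, "scene_ground_truth"))
  ends <- t(vapply(scene$paths, function(p)
    c(p[1L, ], p[nrow(p), ]), numeric(4)))
  tab <- cbind(scene$segments,
               data.frame(knot_row = ends[, 1L], knot_col = ends[, 2L],
                          end_row = ends[, 3L], end_col = ends[, 4L]))
  write_table_csv(tab, csv_path, schema = "scene_ground_truth")
  cfg <- scene$config
  cfg$binding <- unclass(cfg$binding)
  meta <- list(seed = scene$seed, shape = scene$shape,
               pattern = scene$pattern[c("stripe_width", "gap_width",
                                         "pixel_size", "orientation")],
               config = unclass(cfg))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(csv_path)
}

#' Read a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration file into a nested
#' list. The configuration fully determines a pipeline run (see
#' [run_pipeline()]); the resolved configuration is echoed next to every
#' run's outputs.
#'
#' @param path Configuration file path.
#' @return Nested list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}
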