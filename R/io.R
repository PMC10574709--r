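# Readers and writers for the plain-text interchange formats the pipeline
# uses: two-column spectrum CSV, a minimal JCAMP-DX dialect, bucket-table CSV
# with a JSON edge sidecar, and partition JSON.

#' Read a spectrum from a two-column CSV
#'
#' Expects a header line and columns `ppm,intensity`.
#'
#' @param path file path.
#' @param sample_id,label optional metadata; `sample_id` defaults to the file
#'   name without extension.
#' @return a `spectrum` object.
#' @export
read_spectrum_csv <- function(path, sample_id = NULL, label = NA_character_) {
  df <- utils::read.csv(path)
  if (!all(c("ppm", "intensity") %in% names(df))) {
    stop("expected columns 'ppm' and 'intensity' in ", path)
  }
  o <- order(df$ppm)
  structure(list(ppm = df$ppm[o], intensity = df$intensity[o],
                 sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
                 label = label),
            class = "spectrum")
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing per-sample CSVs and `labels.csv`.
#' @return list of `spectrum` objects in `labels.csv` order.
#' @export
read_cohort <- function(dir) {
  labels <- utils::read.csv(file.path(dir, "labels.csv"),
                            colClasses = "character")
  lapply(seq_len(nrow(labels)), function(i) {
    read_spectrum_csv(file.path(dir, paste0(labels$sample_id[i], ".csv")),
                      sample_id = labels$sample_id[i],
                      label = labels$label[i])
  })
}

#' Read a minimal JCAMP-DX 1D spectrum
#'
#' Supports the common fixed-abscissa dialect only: `##XUNITS=PPM`,
#' `##FIRSTX`, `##LASTX`, `##NPOINTS` (or `##DELTAX`) and an AFFN
#' `##XYDATA=(X++(Y..Y))` block where each line starts with an X value
#' followed by Y values.  Compressed (SQZ/DIF/DUP) encodings are out of scope.
#'
#' @param path file path.
#' @inheritParams read_spectrum_csv
#' @return a `spectrum` object.
#' @export
read_jcampdx <- function(path, sample_id = NULL, label = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(key) {
    hit <- grep(paste0("^##", key, "\\s*="), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  xunits <- grab("XUNITS")
  if (!is.null(xunits) && toupper(xunits) != "PPM") {
    stop("unsupported XUNITS '", xunits, "' (only PPM is handled)")
  }
  firstx <- as.numeric(grab("FIRSTX"))
  lastx <- as.numeric(grab("LASTX"))
  npoints <- as.numeric(grab("NPOINTS"))
  yfactor <- as.numeric(grab("YFACTOR") %||% "1")
  start <- grep("^##XYDATA", lines)
  if (length(start) == 0) stop("no ##XYDATA block in ", path)
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > start[1]]) else length(lines) + 1L
  body <- lines[(start[1] + 1L):(end - 1L)]
  ys <- unlist(lapply(body, function(ln) {
    toks <- strsplit(trimws(ln), "[ \t,]+")[[1]]
    as.numeric(toks[-1])          # first token is the line's X value
  }))
  if (is.na(npoints)) npoints <- length(ys)
  if (length(ys) != npoints) {
    stop("NPOINTS (", npoints, ") does not match Y count (", length(ys), ")")
  }
  ppm <- seq(firstx, lastx, length.out = npoints)
  o <- order(ppm)
  structure(list(ppm = ppm[o], intensity = (ys * yfactor)[o],
                 sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
                 label = label),
            class = "spectrum")
}

#' Write / read a bucket table as CSV plus a JSON edge sidecar
#'
#' The CSV holds `sample_id`, `label` and one column per bucket variable; the
#' sidecar `<path>.edges.json` records the bucket windows.
#'
#' @param table a `bucket_table`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_bucket_table <- function(table, path) {
  df <- data.frame(sample_id = table$sample_ids, label = table$labels,
                   table$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(table$edges, paste0(path, ".edges.json"),
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_bucket_table
#' @export
read_bucket_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  edges <- as.data.frame(jsonlite::read_json(paste0(path, ".edges.json"),
                                             simplifyVector = TRUE))
  values <- as.matrix(df[, edges$variable, drop = FALSE])
  rownames(values) <- df$sample_id
  structure(list(values = values, edges = edges,
                 sample_ids = df$sample_id, labels = df$label),
            class = "bucket_table")
}

#' Write / read a train-test partition as JSON
#'
#' @param partition a `partition` from [split_train_test()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  jsonlite::write_json(unclass(partition), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = as.integer(p$train), test = as.integer(p$test),
                 stratum_counts = p$stratum_counts, seed = as.integer(p$seed)),
            class = "partition")
}
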