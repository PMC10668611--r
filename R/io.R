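# Readers/writers and configuration. Images use the plain-text PGM (P2)
# format so synthetic fixtures stay text-only and dependency-free; scales
# and fovea metadata travel in PGM comment lines. Traces, measurements and
# cohort tables are CSV; reports are JSON.

#' Write a B-scan as plain-text PGM (P2)
#'
#' Metadata (pixel scales, fovea column and any scalar `meta` entries) is
#' stored in `# key=value` comment lines so a round trip through
#' [load_bscan] restores the full object.
#'
#' @param scan a [bscan].
#' @param path output path.
#' @param maxval gray levels minus one (255 for 8-bit, 65535 for 16-bit).
#' @export
write_bscan <- function(scan, path, maxval = 255L) {
  stopifnot(inherits(scan, "bscan"))
  px <- round(scan$pixels * maxval)
  meta <- c(lateral_scale = scan$lateral_scale,
            axial_scale = scan$axial_scale,
            fovea_column = scan$fovea_column)
  scal <- scan$meta[vapply(scan$meta, function(v)
    is.numeric(v) && length(v) == 1, logical(1))]
  meta <- c(meta, unlist(scal))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("P2", con)
  writeLines(sprintf("# %s=%.10g", names(meta), meta), con)
  writeLines(sprintf("%d %d", ncol(px), nrow(px)), con)
  writeLines(sprintf("%d", maxval), con)
  write(t(px), con, ncolumns = ncol(px))
  invisible(path)
}

#' Load a B-scan from plain-text PGM
#'
#' @param path PGM (P2) file.
#' @param metadata optional named list overriding/supplying
#'   `lateral_scale`, `axial_scale`, `fovea_column`; entries embedded in
#'   the file's comment lines are used otherwise.
#' @return a [bscan] with intensities normalized to `[0, 1]`.
#' @export
load_bscan <- function(path, metadata = list()) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1]) != "P2")
    stop_invalid("not a plain-text (P2) PGM file: ", path)
  comments <- grep("^#", lines, value = TRUE)
  kv <- regmatches(comments, regexec("#\\s*([A-Za-z_0-9]+)=([-0-9.eE+]+)",
                                     comments))
  embedded <- list()
  for (m in kv) if (length(m) == 3) embedded[[m[2]]] <- as.numeric(m[3])
  meta <- modifyList(embedded, metadata)
  body <- lines[!grepl("^#", lines)][-1]
  nums <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  wh <- nums[1:2]; maxval <- nums[3]
  px <- matrix(nums[-(1:3)], nrow = wh[2], ncol = wh[1], byrow = TRUE)
  for (req in c("lateral_scale", "axial_scale", "fovea_column"))
    if (is.null(meta[[req]]))
      stop_invalid("metadata error: missing ", req)
  extra <- meta[setdiff(names(meta),
                        c("lateral_scale", "axial_scale", "fovea_column"))]
  bscan(px / maxval, meta$lateral_scale, meta$axial_scale,
        meta$fovea_column, meta = extra)
}

#' Write / read a boundary trace as CSV
#'
#' Columns: `column`, `row_subpixel`, `sd_px`. Sub-pixel rows round-trip to
#' better than 1e-6.
#'
#' @param trace a [boundary_trace].
#' @param path CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "boundary_trace"))
  df <- data.frame(column = trace$columns,
                   row_subpixel = sprintf("%.8f", trace$rows),
                   sd_px = sprintf("%.8f", trace$sd))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  boundary_trace(df$column, df$row_subpixel, df$sd_px)
}

#' Write an agreement report as JSON
#'
#' @param report an `agreement_report` (or any named list of scalars and
#'   short vectors).
#' @param path JSON path.
#' @param seed optional seed recorded in the header block.
#' @export
write_report_json <- function(report, path, seed = NULL) {
  obj <- unclass(report)
  obj$software <- paste0("choroidtrace ",
                         as.character(utils::packageVersion("choroidtrace")))
  if (!is.null(seed)) obj$seed <- seed
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values are parsed
#' as numeric when possible, comma-separated values as vectors.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (any(is.na(num))) vals else num
  }
  out
}
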