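# Plain-text serialization of gridded layers. Fields round-trip through
# an annotated CSV: '#'-prefixed header lines carry the grid and
# provenance metadata, followed by one row per cell in canonical order.

#' Write and read a monthly climate field as annotated CSV
#'
#' @param field a [monthly_field()].
#' @param path output file path.
#' @return `read_climate_field()` returns a [monthly_field()];
#'   `write_climate_field()` returns `path` invisibly.
#' @export
write_climate_field <- function(field, path) {
  stopifnot(inherits(field, "monthly_climate_field"))
  g <- field$grid
  hdr <- c(
    sprintf("# variable: %s", field$variable),
    sprintf("# units: %s", field$units),
    sprintf("# scenario: %s", field$scenario),
    sprintf("# model_id: %s", field$model_id),
    sprintf("# resolution: %.10g", g$resolution),
    sprintf("# lon_range: %.10g %.10g", g$lon_range[1], g$lon_range[2]),
    sprintf("# lat_range: %.10g %.10g", g$lat_range[1], g$lat_range[2]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- cbind(grid_centers(g),
              setNames(as.data.frame(field$values), sprintf("m%02d", 1:12)))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_field
#' @export
read_climate_field <- function(path) {
  lines <- readLines(path, n = 20)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    sub(paste0("^# ", key, ": "), "", ln)
  }
  grid <- grid_spec(as.numeric(get("resolution")),
                    as.numeric(strsplit(get("lon_range"), " ")[[1]]),
                    as.numeric(strsplit(get("lat_range"), " ")[[1]]))
  df <- read.csv(path, comment.char = "#")
  monthly_field(as.matrix(df[, sprintf("m%02d", 1:12)]), grid,
                get("variable"), get("units"), get("scenario"),
                get("model_id"))
}

#' Write a bioclim stack or map layers as CSV
#'
#' One row per cell with the cell-centre coordinates, suitable for any
#' tabular GIS import.
#'
#' @param x a [compute_bioclim()] stack, or a named list of aligned
#'   numeric maps.
#' @param grid the [grid_spec()] (taken from the stack when omitted).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_layers_csv <- function(x, path, grid = NULL) {
  if (inherits(x, "bioclim_stack")) {
    grid <- attr(x, "grid")
    df <- as.data.frame(unclass(x))
  } else {
    stopifnot(!is.null(grid))
    df <- as.data.frame(x)
  }
  write.csv(cbind(grid_centers(grid), df), path, row.names = FALSE)
  invisible(path)
}

#' Write MSE benchmark results as CSV
#'
#' Long format: one row per (method, replicate) with its MSE.
#'
#' @param result an [mse_benchmark()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mse_csv <- function(result, path) {
  stopifnot(inherits(result, "mse_result"))
  df <- data.frame(
    method = rep(colnames(result$mse), each = nrow(result$mse)),
    replicate = rep(seq_len(nrow(result$mse)), ncol(result$mse)),
    mse = as.vector(result$mse))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
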