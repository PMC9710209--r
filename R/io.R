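#' Read plate-reader ThT traces
#'
#' Reads either the wide plate-reader export (a `time_min` column plus one
#' column per well) or the long tidy layout written by [write_tht_traces()].
#' Wide input is pivoted to the long layout; well names become the `well`
#' column and, lacking other metadata, the `condition`.
#'
#' @param path CSV file path.
#' @return A long tibble with columns `time_min`, `well`, `condition`,
#'   `replicate`, `signal`, `normalized` (plus any extra metadata columns
#'   present in long input).
#' @export
read_tht_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time_min" %in% names(df))
    stop_input("expected a `time_min` column.")
  if ("signal" %in% names(df)) {
    if (!"normalized" %in% names(df)) df$normalized <- FALSE
    return(tibble::as_tibble(df))
  }
  df |>
    tidyr::pivot_longer(-"time_min", names_to = "well", values_to = "signal") |>
    dplyr::mutate(condition = .data$well, replicate = 1L, normalized = FALSE) |>
    dplyr::relocate("time_min", "well", "condition", "replicate", "signal")
}

#' Write ThT traces as tidy CSV
#'
#' @param traces a long trace tibble (see [sim_tht_traces()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tht_traces <- function(traces, path) {
  check_trace(traces)
  readr::write_csv(traces, path)
  invisible(path)
}

#' Read and write localization tables
#'
#' `read_localizations()` accepts Thunderstorm-style exports (columns
#' `"x [nm]"`, `"y [nm]"`, `"frame"`, `"intensity [photon]"` or
#' `"intensity"`) as well as this package's plain `x_nm`/`y_nm` layout, and
#' returns the plain layout. `write_localizations()` writes
#' Thunderstorm-compatible headers so the files round-trip through other
#' tools.
#'
#' @param path CSV file path.
#' @return A tibble with columns `x_nm`, `y_nm`, `frame`, `intensity`.
#' @export
read_localizations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  nm <- names(df)
  pick <- function(...) {
    cand <- c(...)
    hit <- cand[cand %in% nm]
    if (!length(hit)) stop_input("missing localization column: ", cand[1])
    df[[hit[1]]]
  }
  tibble::tibble(
    x_nm = pick("x_nm", "x [nm]"),
    y_nm = pick("y_nm", "y [nm]"),
    frame = pick("frame"),
    intensity = pick("intensity", "intensity [photon]")
  )
}

#' @rdname read_localizations
#' @param locs a localization tibble (`x_nm`, `y_nm`, `frame`, `intensity`).
#' @export
write_localizations <- function(locs, path) {
  out <- tibble::tibble(
    "x [nm]" = locs$x_nm, "y [nm]" = locs$y_nm,
    frame = locs$frame, intensity = locs$intensity)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write multi-page TIFF image stacks
#'
#' Stacks are stored as 32-bit float multi-page TIFFs with intensities scaled
#' by `scale` into the unit range (TIFF writers expect \[0, 1\]); reading
#' applies the inverse. The physical pixel pitch rides along as an attribute
#' (it is not serialized; pass `pixel_nm` when reading if it differs from the
#' 105.4 nm default).
#'
#' @param path TIFF file path.
#' @param scale intensity scale factor (counts per unit).
#' @param pixel_nm physical pixel pitch in nm.
#' @return `read_image_stack()`: a `rows x cols x frames` `image_stack`
#'   array.
#' @export
read_image_stack <- function(path, scale = 65536, pixel_nm = PIXEL_NM_DEFAULT) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) * scale
  structure(stack, pixel_nm = pixel_nm, class = c("image_stack", "array"))
}

#' @rdname read_image_stack
#' @param stack a `rows x cols x frames` array.
#' @export
write_image_stack <- function(stack, path, scale = 65536) {
  if (length(dim(stack)) == 2L) stack <- array(stack, dim = c(dim(stack), 1L))
  pages <- purrr::map(seq_len(dim(stack)[3]), function(i) {
    pmin(pmax(stack[, , i] / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write per-aggregate shape metrics as CSV
#'
#' @param shapes a [shape_metrics()] result.
#' @param path output CSV path.
#' @export
write_shapes_csv <- function(shapes, path) {
  readr::write_csv(shapes, path)
  invisible(path)
}
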