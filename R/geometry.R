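#' Visual angle subtended by an extent
#'
#' Converts a physical extent on the screen to the visual angle it subtends
#' at the eye, using the exact (non-small-angle) formula
#' \eqn{2 \arctan(e / 2d)}.
#'
#' @param extent_mm Extent on the screen, mm. Non-negative.
#' @param distance_mm Viewing distance, mm. Must be positive.
#' @return Visual angle in degrees.
#' @examples
#' mm_to_deg(14.6, 650)   # inter-number spacing of the digital DEM
#' @export
mm_to_deg <- function(extent_mm, distance_mm) {
  if (any(distance_mm <= 0)) stop("invalid geometry: viewing distance must be positive")
  if (any(extent_mm < 0)) stop("invalid geometry: extent must be non-negative")
  2 * atan(extent_mm / (2 * distance_mm)) * 180 / pi
}

## signed angular position of a screen coordinate (origin = straight ahead)
.mm_to_deg_pos <- function(pos_mm, distance_mm) {
  atan(pos_mm / distance_mm) * 180 / pi
}

#' logMAR of an optotype
#'
#' Acuity demand of an optotype of a given physical height at a given
#' distance, on the logMAR scale. By convention the critical detail of an
#' optotype is one fifth of its height, so
#' logMAR = log10(angle subtended in arcmin / 5).
#'
#' @param height_mm Optotype height, mm (> 0).
#' @param distance_mm Viewing distance, mm (> 0).
#' @return logMAR value (0 corresponds to a 5-arcmin optotype).
#' @examples
#' logmar_of_optotype(4.9, 650)
#' @export
logmar_of_optotype <- function(height_mm, distance_mm) {
  if (any(height_mm <= 0) || any(distance_mm <= 0))
    stop("invalid geometry: height and distance must be positive")
  angle_arcmin <- mm_to_deg(height_mm, distance_mm) * 60
  log10(angle_arcmin / 5)
}

#' Michelson contrast
#'
#' \eqn{(L_{max} - L_{min}) / (L_{max} + L_{min})} for two luminances in
#' cd/m^2.
#'
#' @param lum_max Maximum luminance (cd/m^2).
#' @param lum_min Minimum luminance (cd/m^2).
#' @return Contrast as a fraction in \[0, 1\].
#' @examples
#' michelson_contrast(235.6, 2.1)
#' @export
michelson_contrast <- function(lum_max, lum_min) {
  if (any(lum_min > lum_max)) stop("argument order: lum_max must be >= lum_min")
  if (any(lum_min < 0) || any(lum_max <= 0)) stop("luminances must be non-negative, lum_max > 0")
  (lum_max - lum_min) / (lum_max + lum_min)
}

#' Build the digital DEM stimulus layout
#'
#' Constructs the number positions of one DEM subtest on screen, in mm
#' relative to the screen centre (x positive rightward, y positive upward).
#' Subtests A and B are two columns of 20 numbers each (columns 162.5 mm
#' apart, numbers 14.6 mm apart vertically); subtest C is 16 rows of 5
#' numbers whose first-to-last horizontal extent is 191.8 mm with
#' within-row gaps between 19.2 and 57.5 mm. The exact per-row gaps of the
#' published chart are not reproduced; gaps are drawn from a seeded,
#' deterministic scheme that respects the printed range and extent.
#'
#' @param subtest One of "A", "B", "C".
#' @param viewing_distance_mm Viewing distance in mm (default 650).
#' @param vertical_spacing_mm Vertical spacing between consecutive numbers
#'   within a column, and between C rows (default 14.6).
#' @param column_gap_mm Horizontal gap between the two A/B columns
#'   (default 162.5).
#' @param row_extent_mm First-to-last horizontal extent of a C row
#'   (default 191.8).
#' @param gap_range_mm Admissible range of within-row gaps for subtest C
#'   (default c(19.2, 57.5)).
#' @param symbol_height_mm Optotype height in mm (default 4.9).
#' @param gap_seed Seed for the deterministic within-row gap scheme
#'   (default 1).
#' @return An object of class \code{dem_layout}: a list with the geometry
#'   parameters and a data frame \code{positions} with columns
#'   \code{index} (reading order), \code{row}, \code{col}, \code{x_mm},
#'   \code{y_mm}, \code{x_deg}, \code{y_deg}.
#' @export
build_layout <- function(subtest = c("C", "A", "B"),
                         viewing_distance_mm = 650,
                         vertical_spacing_mm = 14.6,
                         column_gap_mm = 162.5,
                         row_extent_mm = 191.8,
                         gap_range_mm = c(19.2, 57.5),
                         symbol_height_mm = 4.9,
                         gap_seed = 1L) {
  subtest <- match.arg(subtest)
  if (viewing_distance_mm <= 0) stop("invalid geometry: viewing distance must be positive")
  n_gaps <- 4L
  mean_gap <- row_extent_mm / n_gaps
  if (subtest == "C" &&
      (mean_gap < gap_range_mm[1] || mean_gap > gap_range_mm[2]))
    stop("layout validation: row extent incompatible with gap range")

  if (subtest == "C") {
    n_rows <- 16L; n_cols <- 5L
    half_extent <- row_extent_mm / 2
    ## seeded deterministic gaps: uniform draws, deviations from the mean
    ## shrunk so that every gap stays inside gap_range_mm and each row sums
    ## to row_extent_mm exactly
    gaps <- local({
      rng <- .rng_stream(gap_seed)
      out <- matrix(0, n_rows, n_gaps)
      for (r in seq_len(n_rows)) {
        g <- gap_range_mm[1] + rng(n_gaps) * diff(gap_range_mm)
        d <- g - mean(g)
        sc <- 1
        if (max(d) > 0) sc <- min(sc, (gap_range_mm[2] - mean_gap) / max(d))
        if (min(d) < 0) sc <- min(sc, (mean_gap - gap_range_mm[1]) / (-min(d)))
        out[r, ] <- mean_gap + sc * d
      }
      out
    })
    pos <- do.call(rbind, lapply(seq_len(n_rows), function(r) {
      x <- -half_extent + c(0, cumsum(gaps[r, ]))
      y <- ((n_rows - 1) / 2 - (r - 1)) * vertical_spacing_mm
      data.frame(row = r, col = seq_len(n_cols), x_mm = x, y_mm = y)
    }))
  } else {
    n_per_col <- 20L
    y <- ((n_per_col - 1) / 2 - seq(0, n_per_col - 1)) * vertical_spacing_mm
    pos <- rbind(
      data.frame(row = seq_len(n_per_col), col = 1L,
                 x_mm = -column_gap_mm / 2, y_mm = y),
      data.frame(row = seq_len(n_per_col), col = 2L,
                 x_mm = column_gap_mm / 2, y_mm = y)
    )
  }
  pos$index <- seq_len(nrow(pos))
  pos$x_deg <- .mm_to_deg_pos(pos$x_mm, viewing_distance_mm)
  pos$y_deg <- .mm_to_deg_pos(pos$y_mm, viewing_distance_mm)
  pos <- pos[, c("index", "row", "col", "x_mm", "y_mm", "x_deg", "y_deg")]

  layout <- structure(list(
    subtest = subtest,
    viewing_distance_mm = viewing_distance_mm,
    vertical_spacing_mm = vertical_spacing_mm,
    column_gap_mm = column_gap_mm,
    row_extent_mm = row_extent_mm,
    gap_range_mm = gap_range_mm,
    symbol_height_mm = symbol_height_mm,
    positions = pos
  ), class = "dem_layout")
  .validate_layout(layout)
  layout
}

.validate_layout <- function(layout) {
  pos <- layout$positions
  if (layout$subtest == "C") {
    if (nrow(pos) != 80L) stop("layout validation: C must have 80 positions")
    for (r in unique(pos$row)) {
      x <- pos$x_mm[pos$row == r]
      g <- diff(x)
      if (any(g < layout$gap_range_mm[1] - 1e-9) ||
          any(g > layout$gap_range_mm[2] + 1e-9))
        stop("layout validation: within-row gap outside admissible range")
      if (abs((max(x) - min(x)) - layout$row_extent_mm) > 1e-9)
        stop("layout validation: row extent mismatch")
    }
  } else {
    if (nrow(pos) != 40L) stop("layout validation: A/B must have 40 positions")
    for (cc in unique(pos$col)) {
      y <- pos$y_mm[pos$col == cc]
      if (any(abs(diff(y) + layout$vertical_spacing_mm) > 1e-9))
        stop("layout validation: vertical spacing mismatch")
    }
  }
  invisible(layout)
}

#' @export
print.dem_layout <- function(x, ...) {
  cat(sprintf("<dem_layout> subtest %s: %d positions, viewing distance %.0f mm\n",
              x$subtest, nrow(x$positions), x$viewing_distance_mm))
  invisible(x)
}

#' Write / read a DEM layout as plain text
#'
#' Serialises a \code{dem_layout} to a small text file: `key: value` header
#' lines followed by a TSV position table.
#'
#' @param layout A \code{dem_layout}.
#' @param path File path.
#' @return \code{read_layout} returns a \code{dem_layout};
#'   \code{write_layout} returns \code{path} invisibly.
#' @export
write_layout <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dem_layout"),
    sprintf("subtest: %s", layout$subtest),
    sprintf("viewing_distance_mm: %.6g", layout$viewing_distance_mm),
    sprintf("vertical_spacing_mm: %.6g", layout$vertical_spacing_mm),
    sprintf("column_gap_mm: %.6g", layout$column_gap_mm),
    sprintf("row_extent_mm: %.6g", layout$row_extent_mm),
    sprintf("gap_range_mm: %.6g %.6g", layout$gap_range_mm[1], layout$gap_range_mm[2]),
    sprintf("symbol_height_mm: %.6g", layout$symbol_height_mm)
  ), con)
  utils::write.table(format(layout$positions, digits = 10), con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^[a-z_]+:", lines, value = TRUE)
  kv <- strsplit(hdr, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  get1 <- function(k) vals[match(k, keys)]
  tab_start <- grep("^index\t", lines)[1]
  pos <- utils::read.table(text = lines[tab_start:length(lines)],
                           header = TRUE, sep = "\t")
  structure(list(
    subtest = get1("subtest"),
    viewing_distance_mm = as.numeric(get1("viewing_distance_mm")),
    vertical_spacing_mm = as.numeric(get1("vertical_spacing_mm")),
    column_gap_mm = as.numeric(get1("column_gap_mm")),
    row_extent_mm = as.numeric(get1("row_extent_mm")),
    gap_range_mm = as.numeric(strsplit(get1("gap_range_mm"), " ")[[1]]),
    symbol_height_mm = as.numeric(get1("symbol_height_mm")),
    positions = pos
  ), class = "dem_layout")
}

## deterministic uniform stream independent of the global RNG,
## used only for the layout's within-row gap scheme
.rng_stream <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 16807) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}
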